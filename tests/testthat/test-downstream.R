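# Downstream inference: sex heterogeneity, conditional attenuation,
# sign-test replication concordance.

test_that("sex heterogeneity reproduces the dimorphic-gene z-test", {
  # the strongly female-biased gene: printed stratified estimates give
  # p_het ~= 2.46e-2
  het <- sex_heterogeneity(-1.710, 0.340, -0.177, 0.592)
  expect_equal(het$p, 2.46e-2, tolerance = 0.02)
  expect_true(het$dimorphic)
  # equal effects: z = 0, p = 1
  eq <- sex_heterogeneity(0.4, 0.1, 0.4, 0.2)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # symmetric in the strata
  sw <- sex_heterogeneity(-0.177, 0.592, -1.710, 0.340)
  expect_equal(sw$p, het$p)
  expect_equal(sw$z, -het$z)
  expect_error(sex_heterogeneity(1, 0, 1, 1), "positive")
})

test_that("heterogeneity p-values are uniform when both sexes share the effect", {
  ps <- vapply(1:120, function(s) {
    cfg <- sim_config(800, list(gene_spec("G", n_variants = 12, af = 3e-3,
                                          beta_fetal = -0.4)),
                      seed = 4000 + s)
    coh <- simulate_duos(cfg)
    tab <- analysis_table(coh, "fetal")
    cv <- true_carrier(coh, "G", "fetal")
    sf <- sex_stratified_fit(cv, tab)
    if (sf$female$status != "ok" || sf$male$status != "ok") return(NA_real_)
    sex_heterogeneity(sf$female$beta_sd, sf$female$se,
                      sf$male$beta_sd, sf$male$se)$p
  }, 0)
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 100)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("sign test gives the exact two-sided binomial p", {
  # 10 of 11 concordant pairs
  res <- sign_test(rep(1, 11), c(rep(1, 10), -1))
  expect_equal(res$k_concordant, 10L)
  expect_equal(res$p, 24 / 2048)              # = 0.0117, printed as 0.01
  expect_equal(round(res$p, 2), 0.01)
  # full concordance
  expect_equal(sign_test(rep(-1, 11), rep(-1, 11))$p, 2 / 2048)
  # central value
  expect_equal(sign_test(rep(1, 10), rep(c(1, -1), 5))$p, 1)
  # zero betas are dropped with a message
  expect_message(res0 <- sign_test(c(1, 0, -1), c(1, 1, -1)), "dropping")
  expect_equal(res0$n, 2L)
  expect_error(suppressMessages(sign_test(0, 1)), "no non-zero")
  expect_error(sign_test(1:3, 1:2), "paired")
})

test_that("sign test matches exhaustive enumeration for n <= 12", {
  # oracle: enumerate all 2^n equally likely concordance patterns
  for (n in 1:12) {
    ks <- 0:n
    counts <- choose(n, ks)
    for (k in ks) {
      p_oracle <- min(1, 2 * min(sum(counts[ks <= k]) / 2^n,
                                 sum(counts[ks >= k]) / 2^n))
      got <- sign_test(rep(1, n), c(rep(1, k), rep(-1, n - k)))$p
      expect_equal(got, p_oracle, tolerance = 1e-12)
      # symmetry p(k, n) = p(n-k, n)
      expect_equal(got, sign_test(rep(1, n), c(rep(-1, k), rep(1, n - k)))$p,
                   tolerance = 1e-15)
    }
  }
})

test_that("conditional fit is the identity for an orthogonal SNP", {
  # strong planted effect so chance correlation with an independent SNP is
  # negligible against the carrier signal
  cfg <- make_test_config(n = 2000, seed = 91,
                          genes = list(gene_spec("GCKL", n_variants = 12,
                                                 af = 2e-3,
                                                 beta_fetal = -1.5)))
  cfg$noise_sd <- 0.4
  coh <- simulate_duos(cfg)
  tab <- analysis_table(coh, "fetal")
  cv <- true_carrier(coh, "GCKL", "fetal")
  set.seed(12)
  dosage <- stats::setNames(sample(0:2, nrow(tab), replace = TRUE,
                                   prob = c(0.49, 0.42, 0.09)),
                            tab$person_id)
  res <- conditional_fit(cv, dosage, tab)
  expect_false(res$attenuated)
  expect_lt(res$relative_change, 0.10)
  # noiseless orthogonal case: exact identity
  tab2 <- tab[, c("person_id", "phenotype_sd")]
  x <- as.numeric(cv$status[tab2$person_id])
  tab2$phenotype_sd <- 0.5 * x                       # pure carrier signal
  d2 <- stats::setNames(rep(c(0, 1, 2, 1), length.out = nrow(tab2)),
                        tab2$person_id)
  d2[x == 1] <- 1                                    # constant within carriers
  res2 <- conditional_fit(cv, d2, tab2)
  expect_equal(res2$beta_conditional, res2$beta_unconditional,
               tolerance = 1e-8)
  expect_error(conditional_fit(cv, dosage + 5, tab), "0, 2")
})

test_that("a mediating GWAS sentinel attenuates the burden effect", {
  # the sentinel dosage carries the causal effect; carrier status is a
  # correlated proxy, so conditioning must shrink its coefficient by the
  # omitted-variable factor
  set.seed(77)
  n <- 4000
  ids <- sprintf("S%04d", 1:n)
  dosage <- rbinom(n, 2, 0.3)
  carrier <- as.integer(runif(n) < 0.15 + 0.35 * dosage / 2)  # corr with dosage
  y <- 0.3 * dosage + rnorm(n, 0, 0.5)
  tab <- data.frame(person_id = ids, phenotype_sd = y)
  names(carrier) <- ids; dosage <- stats::setNames(dosage, ids)
  res <- conditional_fit(carrier, dosage, tab)
  expect_true(res$attenuated)
  expect_gt(res$relative_change, 0.5)
  # closed-form omitted-variable value of the unconditional slope:
  # beta_u = 0.3 * cov(d, c)/var(c); conditional slope ~ 0
  beta_u_oracle <- 0.3 * stats::cov(as.numeric(dosage), carrier) /
    stats::var(carrier)
  expect_equal(res$beta_unconditional, beta_u_oracle,
               tolerance = 0.15)
  # the conditional estimate collapses towards zero (carrier has no direct
  # effect); allow its own sampling noise
  expect_lt(abs(res$beta_conditional), abs(res$beta_unconditional) / 2)
})

test_that("attenuation below a numerical floor is flagged undefined", {
  n <- 48
  tab <- data.frame(person_id = sprintf("S%d", 1:n),
                    phenotype_sd = rep(c(0.3, -0.3), n / 2))
  # period-4 carrier pattern is exactly orthogonal to the period-2 phenotype
  carrier <- stats::setNames(rep(c(1, 1, 0, 0), n / 4), tab$person_id)
  dosage <- stats::setNames(rep(c(0, 1, 2), n / 3), tab$person_id)
  res <- conditional_fit(carrier, dosage, tab)
  expect_true(is.na(res$relative_change))
  expect_true(is.na(res$attenuated))
})
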