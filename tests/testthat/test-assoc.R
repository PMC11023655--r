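# Burden regression and multiple-testing helpers.

test_that("burden fit matches the hand-solved normal equations", {
  # 8 samples, 4 carriers, fixed noise vector, no covariates
  carrier <- c(1, 1, 1, 1, 0, 0, 0, 0)
  noise <- c(0.21, -0.13, 0.05, -0.4, 0.33, -0.2, 0.11, 0.02)
  y <- 2 * carrier + noise
  tab <- data.frame(person_id = sprintf("S%d", 1:8), phenotype_sd = y,
                    stringsAsFactors = FALSE)
  names(carrier) <- tab$person_id
  fit <- fit_burden(carrier, tab, min_carriers = 1)
  # independent oracle: solve the normal equations directly
  X <- cbind(1, carrier)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)[2]
  expect_equal(fit$beta_sd, beta_oracle, tolerance = 1e-12)
  rss <- sum((y - X %*% solve(t(X) %*% X, t(X) %*% y))^2)
  se_oracle <- sqrt(rss / 6 * solve(t(X) %*% X)[2, 2])
  expect_equal(fit$se, se_oracle, tolerance = 1e-12)
  expect_equal(fit$p, 2 * pt(-abs(beta_oracle / se_oracle), df = 6),
               tolerance = 1e-12)
})

test_that("carrier orthogonal to the phenotype gives a null estimate", {
  set.seed(4)
  n <- 200
  carrier <- rep(c(1, 0), each = n / 2)
  y <- rep(c(1, -1), n / 2)           # orthogonal to carrier by construction
  tab <- data.frame(person_id = sprintf("S%d", 1:n), phenotype_sd = y)
  names(carrier) <- tab$person_id
  fit <- fit_burden(carrier, tab, min_carriers = 1)
  expect_equal(fit$beta_sd, 0, tolerance = 1e-12)
  expect_equal(fit$p, 1, tolerance = 1e-12)
})

test_that("effect is invariant to kg-scale changes and orthogonal covariates", {
  coh <- simulate_duos(make_test_config(n = 800, seed = 61))
  tab <- analysis_table(coh, "fetal")
  cv <- true_carrier(coh, "GCKL", "fetal")
  base <- fit_burden(cv, tab)
  # affine rescaling of the raw kg phenotype changes nothing after z-scoring
  coh2 <- coh
  coh2$own_reports$bw_kg <- 2.2 * coh2$own_reports$bw_kg + 0.4
  rules2 <- derivation_rules(min_bw_kg = 2.2 * 1 + 0.4, max_bw_kg = 2.2 * 7 + 0.4,
                             max_visit_discordance_kg = 2.2)
  tab2 <- analysis_table(coh2, "fetal", rules2)
  resc <- fit_burden(cv, tab2)
  expect_equal(resc$beta_sd, base$beta_sd, tolerance = 1e-10)
  # a covariate orthogonalised against the whole design leaves the
  # estimate unchanged to numerical precision (Frisch-Waugh-Lovell)
  tab3 <- tab
  set.seed(99)
  x <- as.numeric(cv$status[tab3$person_id])
  X <- stats::model.matrix(
    ~ ., data = data.frame(carrier = x,
                           tab3[, setdiff(names(tab3),
                                          c("person_id", "phenotype_sd"))]))
  tab3$junk <- stats::residuals(stats::lm(rnorm(nrow(tab3)) ~ X))
  with_junk <- fit_burden(cv, tab3)
  expect_equal(with_junk$beta_sd, base$beta_sd, tolerance = 1e-10)
  # and an exactly collinear covariate is dropped, not fatal
  tab4 <- tab
  tab4$age_copy <- tab4$age
  expect_message(fit4 <- fit_burden(cv, tab4), "collinear")
  expect_equal(fit4$beta_sd, base$beta_sd, tolerance = 1e-10)
})

test_that("sex-stratified fits recover sex-specific planted effects", {
  cfg <- sim_config(4000, list(gene_spec("PPARGL", n_variants = 10, af = 2e-3,
                                         beta_fetal_female = -1.7,
                                         beta_fetal_male = 0)),
                    noise_sd = 0.8, seed = 71)
  coh <- simulate_duos(cfg)
  tab <- analysis_table(coh, "fetal")
  cv <- true_carrier(coh, "PPARGL", "fetal")
  sf <- sex_stratified_fit(cv, tab)
  expect_equal(sf$female$arm, "fetal_female")
  k <- attr(tab, "sd_kg") / cfg$bw_sd_kg   # latent-SD units
  expect_equal(sf$female$beta_sd * k, -1.7, tolerance = 3 * sf$female$se * k / 1.7)
  expect_lt(abs(sf$male$beta_sd), 3 * sf$male$se)
})

test_that("a stratum without carriers is reported as not estimable", {
  coh <- simulate_duos(make_test_config(n = 300, seed = 83))
  tab <- analysis_table(coh, "fetal")
  cv <- true_carrier(coh, "GCKL", "fetal")
  # force every male carrier off
  cv$status[tab$person_id[tab$sex == "M"]] <- 0L
  sf <- sex_stratified_fit(cv, tab)
  expect_equal(sf$male$status, "not_estimable")
  expect_true(is.na(sf$male$beta_sd))
  expect_equal(sf$female$status, "ok")
})

test_that("Bonferroni thresholds reproduce the exome-wide cutoffs", {
  expect_equal(signif(bonferroni_threshold(16735 + 13684), 3), 1.64e-6)
  expect_equal(signif(bonferroni_threshold(17745 + 13968), 3), 1.58e-6)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), "positive count")
  # strictly decreasing in the number of tests
  expect_true(all(diff(bonferroni_threshold(c(1, 10, 100, 1e4))) < 0))
})

test_that("Benjamini-Hochberg matches the step-up recursion", {
  expect_equal(bh_adjust(0.04)$p_adjusted, 0.04)
  # hand recursion: p_(i) * n / i, cummin from the top
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$p_adjusted, rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5))$p_adjusted, rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(1.2), "0, 1")
})

test_that("null burden p-values are uniform", {
  # modest-scale calibration here; the deep 2000-gene run lives in the
  # acceptance suite
  ps <- c()
  for (s in 1:30) {
    cfg <- sim_config(600, list(gene_spec("N1", n_variants = 15, af = 3e-3),
                                gene_spec("N2", n_variants = 15, af = 3e-3)),
                      seed = 1000 + s)
    coh <- simulate_duos(cfg)
    tab <- analysis_table(coh, "fetal")
    for (g in c("N1", "N2")) {
      fit <- fit_burden(true_carrier(coh, g, "fetal"), tab)
      if (fit$status == "ok") ps <- c(ps, fit$p)
    }
  }
  expect_gt(length(ps), 40)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
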