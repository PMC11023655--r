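# Collapsing masks: qualification dialects, MAF filter, carrier collapsing,
# leave-one-out and custom masks.

ann_row <- function(consequence, loftee = "none", cadd = NA_real_,
                    key = "1:100:A:G", gene = "G1") {
  data.frame(variant_key = key, gene_id = gene, consequence = consequence,
             loftee = loftee, cadd = cadd, stringsAsFactors = FALSE)
}

test_that("mask qualification follows the dialect definitions", {
  disc <- builtin_masks("discovery")
  expect_true(mask_qualifies(ann_row("stop_gained", "HC"), disc$PTV))
  expect_false(mask_qualifies(ann_row("stop_gained", "LC"), disc$PTV))
  expect_false(mask_qualifies(ann_row("missense", cadd = 30), disc$PTV))
  # CADD threshold is inclusive (>= 25)
  expect_true(mask_qualifies(ann_row("missense", cadd = 25.0), disc$`Missense+PTV`))
  expect_false(mask_qualifies(ann_row("missense", cadd = 24.9), disc$`Missense+PTV`))
  expect_false(mask_qualifies(ann_row("synonymous", cadd = 50), disc$`Missense+PTV`))
  # missing CADD cannot qualify where the mask needs it
  expect_false(mask_qualifies(ann_row("missense"), disc$`Missense+PTV`))

  reg <- builtin_masks("regenie")
  expect_true(mask_qualifies(ann_row("inframe_indel", cadd = 30), reg$`Missense+PTV`))
  expect_false(mask_qualifies(ann_row("inframe_indel", cadd = 30), disc$`Missense+PTV`))

  dec <- builtin_masks("decode")
  expect_true(mask_qualifies(ann_row("start_lost", "HC"), dec$LOF))
  expect_true(mask_qualifies(ann_row("stop_lost", "HC"), dec$LOF))
  expect_false(mask_qualifies(ann_row("start_lost", "HC"), disc$PTV))
  # splice_region is never truncating-qualifying, only moderate-impact
  expect_false(mask_qualifies(ann_row("splice_region", "HC"), dec$LOF))
  expect_true(mask_qualifies(ann_row("splice_region", cadd = 26), dec$`LOF+MIS`))
})

test_that("PTV qualifying set is nested in the damaging-missense set", {
  coh <- make_read_cohort(n = 200, seed = 3)
  for (dialect in c("discovery", "regenie", "decode")) {
    mks <- builtin_masks(dialect)
    q1 <- mask_qualifies(coh$variants, mks[[1]])
    q2 <- mask_qualifies(coh$variants, mks[[2]])
    expect_true(all(q2[q1]), label = dialect)
  }
})

test_that("in-sample MAF folds to the minor allele with a strict cutoff", {
  # 2 het carriers among 1000 samples: maf = 0.001 exactly -> excluded
  gt <- c(rep(1L, 2), rep(0L, 998))
  expect_false(compute_maf(gt)$retained)
  expect_equal(compute_maf(gt)$maf, 0.001)
  # 1 het among 1000 -> retained
  expect_true(compute_maf(c(1L, rep(0L, 999)))$retained)
  # folding: 1999 alt alleles of 2000 is minor frequency 0.0005
  gt_major <- c(rep(2L, 999), 1L)
  res <- compute_maf(gt_major)
  expect_equal(res$maf, 1 / 2000)
  expect_true(res$retained)
  expect_false(compute_maf(rep(NA_integer_, 5))$retained)
})

test_that("collapsing emits binary carrier status with the >=10 rule", {
  samples <- sprintf("S%02d", 1:40)
  keys <- c("1:1:A:G", "1:2:A:G")
  gt <- matrix(0L, 2, 40, dimnames = list(keys, samples))
  gt[1, 1:9] <- 1L
  bs <- structure(list(gene_id = "G", mask_name = "m", variant_keys = keys),
                  class = "burden_set")
  cv9 <- collapse_burden(bs, gt)
  expect_equal(cv9$n_carriers, 9L)
  expect_false(cv9$testable)                     # 9 carriers: excluded
  gt[2, 10] <- 1L
  cv10 <- collapse_burden(bs, gt)
  expect_true(cv10$testable)
  # het at two qualifying variants is still status 1, not 2
  gt[2, 1] <- 1L
  expect_equal(unname(collapse_burden(bs, gt)$status[1]), 1L)
  # missing at all qualifying variants -> missing status, not a carrier
  gt[, 11] <- NA_integer_
  cvm <- collapse_burden(bs, gt)
  expect_true(is.na(cvm$status[11]))
  expect_equal(cvm$n_carriers, 10L)
})

test_that("carrier vectors are invariant to variant ordering and grow monotonically", {
  coh <- make_read_cohort(n = 300, seed = 21)
  cid <- coh$persons$person_id[coh$persons$role == "child"]
  gt <- coh$calls$gt[, cid, drop = FALSE]
  keys <- coh$variants$variant_key
  bs <- structure(list(gene_id = "GCKL", mask_name = "m", variant_keys = keys),
                  class = "burden_set")
  bs_rev <- bs; bs_rev$variant_keys <- rev(keys)
  expect_identical(collapse_burden(bs, gt)$status,
                   collapse_burden(bs_rev, gt)$status)
  # adding qualifying variants never decreases the carrier count
  counts <- vapply(seq_along(keys), function(k) {
    b <- bs; b$variant_keys <- keys[seq_len(k)]
    collapse_burden(b, gt)$n_carriers
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("leave-one-out removes exactly the named variant", {
  bs <- structure(list(gene_id = "G", mask_name = "m",
                       variant_keys = c("a", "b", "c")), class = "burden_set")
  expect_equal(leave_one_out(bs, "b")$variant_keys, c("a", "c"))
  expect_identical(leave_one_out(bs, "zz"), bs)              # absent: identity
  empty <- leave_one_out(leave_one_out(leave_one_out(bs, "a"), "b"), "c")
  expect_length(empty$variant_keys, 0)
  gt <- matrix(0L, 0, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  expect_false(collapse_burden(empty, gt)$testable)          # gene untestable
})

test_that("removing a dominant variant weakens but can preserve the burden signal", {
  # one large-effect splice variant plus many small-effect variants
  vt <- data.frame(af = c(3e-3, rep(2e-3, 9)),
                   consequence = c("splice_acceptor", rep("missense", 9)),
                   loftee = c("HC", rep("none", 9)),
                   cadd = c(34, rep(30, 9)))
  cfg <- sim_config(8000, list(gene_spec("INHBEL", variants = vt,
                                         beta_fetal = 0.5, beta_maternal = 0)),
                    noise_sd = 0.5, seed = 77)
  coh <- simulate_duos(cfg)
  tab <- analysis_table(coh, "fetal")
  cid <- coh$persons$person_id[coh$persons$role == "child"]
  gt <- coh$geno[, cid, drop = FALSE]
  keys <- coh$variants$variant_key
  bs <- structure(list(gene_id = "INHBEL", mask_name = "m", variant_keys = keys),
                  class = "burden_set")
  full <- fit_burden(collapse_burden(bs, gt), tab)
  loo <- fit_burden(collapse_burden(leave_one_out(bs, keys[1]), gt), tab)
  expect_lt(full$p, 1e-4)
  expect_lt(full$p, loo$p)          # weakens without the splice variant
  expect_lt(loo$p, 0.05)            # but persists
})

test_that("custom masks qualify exactly the listed variants", {
  keys <- c("1:1:A:G", "1:2:A:G", "1:3:A:G")
  mk <- build_custom_mask(c(keys, keys[1]), name = "pathogenic_panel")
  expect_length(mk$variant_list, 3)                          # duplicates collapse
  ann <- do.call(rbind, lapply(c(keys, "1:9:A:G"), function(k)
    ann_row("missense", cadd = 10, key = k)))
  expect_equal(mask_qualifies(ann, mk), c(TRUE, TRUE, TRUE, FALSE))
  expect_error(build_custom_mask(character()), "non-empty")
})

test_that("a custom pathogenic panel recovers the planted effect", {
  cfg <- sim_config(6000, list(gene_spec("GCKL", n_variants = 10, af = 2e-3,
                                         beta_fetal = -0.5, beta_maternal = 0)),
                    noise_sd = 0.5, seed = 55)
  coh <- simulate_duos(cfg)
  coh$calls <- list(gt = coh$geno)
  tab <- analysis_table(coh, "fetal")
  cid <- coh$persons$person_id[coh$persons$role == "child"]
  gt <- coh$geno[, cid, drop = FALSE]
  mk <- build_custom_mask(coh$variants$variant_key)
  bs <- build_burden_set("GCKL", mk, coh$variants, gt, maf_max = 0.01)
  fit <- fit_burden(collapse_burden(bs, gt), tab)
  # convert from observed-phenotype SD back to the generator's latent SD
  k <- attr(tab, "sd_kg") / cfg$bw_sd_kg
  expect_equal(fit$beta_sd * k, -0.5, tolerance = 3 * fit$se * k / 0.5)
})
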