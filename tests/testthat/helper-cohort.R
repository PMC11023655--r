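# Shared fixture builders: everything is generated in code under fixed seeds.

# One moderately-sized cohort with a GCK-like opposing-effect gene,
# reused across IO / QC / pipeline tests.
make_test_config <- function(n = 400, seed = 101,
                             genes = list(gene_spec("GCKL", n_variants = 12,
                                                    af = 2e-3,
                                                    beta_fetal = -0.311,
                                                    beta_maternal = 0.430))) {
  sim_config(n, genes, seed = seed)
}

make_read_cohort <- function(...) simulate_reads(simulate_duos(make_test_config(...)))

# Collapse every variant of a gene (no mask, no MAF filter) against the true
# genotypes of one arm; used where tests target the regression machinery
# rather than mask construction.
true_carrier <- function(cohort, gene, arm = c("fetal", "maternal")) {
  arm <- match.arg(arm)
  role <- if (arm == "fetal") "child" else "mother"
  ids <- cohort$persons$person_id[cohort$persons$role == role]
  keys <- cohort$variants$variant_key[cohort$variants$gene_id == gene]
  bs <- structure(list(gene_id = gene, mask_name = "all", variant_keys = keys),
                  class = "burden_set")
  collapse_burden(bs, cohort$geno[, ids, drop = FALSE])
}

# Simulate one replicate and return marginal + WLM-adjusted estimates.
wlm_replicate <- function(seed, beta_fetal, beta_maternal, n = 2000,
                          n_variants = 20, af = 5e-4) {
  cfg <- sim_config(n, list(gene_spec("G", n_variants = n_variants, af = af,
                                      beta_fetal = beta_fetal,
                                      beta_maternal = beta_maternal)),
                    seed = seed)
  coh <- simulate_duos(cfg)
  tabF <- analysis_table(coh, "fetal")
  tabM <- analysis_table(coh, "maternal")
  cvF <- true_carrier(coh, "G", "fetal")
  cvM <- true_carrier(coh, "G", "maternal")
  failed <- c(fetal_marg = NA_real_, maternal_marg = NA_real_,
              fetal_adj = NA_real_, maternal_adj = NA_real_)
  if (!cvF$testable || !cvM$testable) return(failed)
  rF <- fit_burden(cvF, tabF)
  rM <- fit_burden(cvM, tabM)
  if (rF$status != "ok" || rM$status != "ok") return(failed)
  # planted effects are in latent SD units (one latent SD = bw_sd_kg kg);
  # the fit reports observed-phenotype SD units, so convert back
  kF <- attr(tabF, "sd_kg") / cfg$bw_sd_kg
  kM <- attr(tabM, "sd_kg") / cfg$bw_sd_kg
  adj <- wlm_adjust(rF$beta_sd * kF, rF$se * kF, rM$beta_sd * kM, rM$se * kM)
  c(fetal_marg = rF$beta_sd * kF, maternal_marg = rM$beta_sd * kM,
    fetal_adj = adj$beta_fetal_adj, maternal_adj = adj$beta_maternal_adj)
}
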