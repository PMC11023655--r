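# End-to-end pipeline: read inputs -> genotype QC -> phenotype derivation ->
# masks and collapsing -> burden regression in both arms -> WLM partition ->
# downstream tests -> results TSVs plus a structured run log in which every
# exclusion is accounted for.

#' Pipeline configuration
#'
#' Collects input paths, thresholds, rules and analysis choices. May also
#' be loaded from a flat YAML file whose keys mirror the arguments
#' (`qc:` and `rules:` sub-maps are passed to [qc_thresholds()] and
#' [derivation_rules()]).
#'
#' @param vcf,annotations,covariates,own_bw,offspring_bw Input file paths
#'   (`own_bw` / `offspring_bw` may be `NULL` to skip an arm).
#' @param out_dir Output directory for the results TSVs.
#' @param thresholds A [qc_thresholds()].
#' @param rules A [derivation_rules()].
#' @param dialect Mask dialect for [builtin_masks()].
#' @param qc_rule Depth/GQ rule, `"or"` or `"and"`.
#' @param slope_filter Apply the AD-on-DP slope variant filter.
#' @param arms Analysis arms to run.
#' @param alpha Nominal level for the WLM classification.
#' @param min_carriers Minimum carriers per gene x mask, default 10.
#' @param maf_max Rare-variant MAF cutoff, default 0.001.
#' @param use_external_maf Use the annotation table's `maf_external` column
#'   (an external reference frequency) instead of the in-sample frequency.
#'   Recommended whenever the cohort is too small for the in-sample
#'   frequency to resolve the cutoff.
#' @param seed Seed recorded with the outputs (the pipeline itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, annotations, covariates,
                            own_bw = NULL, offspring_bw = NULL,
                            out_dir = NULL,
                            thresholds = qc_thresholds(),
                            rules = derivation_rules(),
                            dialect = "discovery",
                            qc_rule = "or", slope_filter = FALSE,
                            arms = c("fetal", "maternal"),
                            alpha = 0.05, min_carriers = 10,
                            maf_max = 0.001, use_external_maf = FALSE,
                            seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)", call. = FALSE)
  arms <- match.arg(arms, c("fetal", "maternal"), several.ok = TRUE)
  if (is.null(own_bw)) arms <- setdiff(arms, "fetal")
  if (is.null(offspring_bw)) arms <- setdiff(arms, "maternal")
  if (!length(arms)) stop("no analysis arm has a phenotype file", call. = FALSE)
  structure(list(vcf = vcf, annotations = annotations, covariates = covariates,
                 own_bw = own_bw, offspring_bw = offspring_bw,
                 out_dir = out_dir, thresholds = thresholds, rules = rules,
                 dialect = dialect, qc_rule = qc_rule,
                 slope_filter = slope_filter, arms = arms, alpha = alpha,
                 min_carriers = min_carriers, maf_max = maf_max,
                 use_external_maf = use_external_maf,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path Flat YAML file; top-level keys mirror [pipeline_config()]
#'   arguments, with optional `qc:` and `rules:` maps.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- do.call(qc_thresholds, y$qc %||% list())
  rl <- do.call(derivation_rules, y$rules %||% list())
  y$qc <- NULL; y$rules <- NULL
  do.call(pipeline_config, c(y, list(thresholds = thr, rules = rl)))
}

stage_log <- function(stage, n_in, n_out, reasons = integer()) {
  data.frame(stage = stage, n_in = n_in, n_out = n_out,
             reason = if (length(reasons)) names(reasons) else NA_character_,
             n_excluded = if (length(reasons)) as.integer(reasons) else
               as.integer(n_in - n_out),
             stringsAsFactors = FALSE)
}

#' Run the full burden analysis pipeline
#'
#' Sequences the stages: read inputs, genotype QC, per-arm phenotype
#' derivation, mask construction and collapsing, burden regression per
#' gene x mask in each arm, WLM partition of genes tested in both arms,
#' and sex-stratified heterogeneity tests for genes passing the arm's
#' Bonferroni threshold. Writes `assoc.tsv`, `partition.tsv`,
#' `dimorphism.tsv` and `runlog.tsv` to `out_dir` when set. The pipeline
#' is deterministic: identical inputs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List with `assoc` (all burden results), `partition`,
#'   `dimorphism`, `thresholds` (per-arm Bonferroni cutoffs), `log`
#'   (stage-by-stage record counts with exclusions by reason), and the
#'   post-QC `cohort`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()

  cohort <- read_cohort(vcf = config$vcf, annotations = config$annotations,
                        covariates = config$covariates,
                        own_bw = config$own_bw,
                        offspring_bw = config$offspring_bw)
  n_var0 <- nrow(cohort$variants)
  log$read <- stage_log("read_inputs", n_var0, n_var0)

  cohort <- apply_genotype_qc(cohort, config$thresholds,
                              rule = config$qc_rule,
                              slope_filter = config$slope_filter)
  ql <- cohort$qc_log
  vl <- ql[ql$unit == "variants", , drop = FALSE]
  log$qc <- stage_log("genotype_qc", n_var0, nrow(cohort$variants),
                      stats::setNames(vl$n_removed, vl$filter))

  persons <- cohort$persons
  samples_by_arm <- list(
    fetal = persons$person_id[persons$role == "child"],
    maternal = persons$person_id[persons$role == "mother"])

  tables <- list()
  for (arm in config$arms) {
    tab <- analysis_table(cohort, arm, config$rules)
    ex <- attr(tab, "exclusions")
    n_in <- nrow(tab) + sum(ex$n)
    log[[paste0("phenotype_", arm)]] <-
      stage_log(paste0("phenotype_", arm), n_in, nrow(tab),
                stats::setNames(ex$n, ex$reason))
    tables[[arm]] <- tab
  }

  masks <- builtin_masks(config$dialect)
  genes <- unique(cohort$variants$gene_id)
  gt <- cohort$calls$gt

  assoc <- list()
  n_attempted <- 0L; n_untestable <- 0L
  for (arm in config$arms) {
    arm_samples <- intersect(samples_by_arm[[arm]], colnames(gt))
    arm_gt <- gt[, arm_samples, drop = FALSE]
    for (mk in masks) {
      for (g in genes) {
        bset <- build_burden_set(g, mk, cohort$variants, arm_gt,
                                 maf_max = config$maf_max,
                                 use_external_maf = config$use_external_maf)
        if (!length(bset$variant_keys)) next
        n_attempted <- n_attempted + 1L
        cv <- collapse_burden(bset, arm_gt, config$min_carriers)
        if (!cv$testable) { n_untestable <- n_untestable + 1L; next }
        assoc[[length(assoc) + 1L]] <-
          fit_burden(cv, tables[[arm]], arm = arm,
                     min_carriers = config$min_carriers)
      }
    }
  }
  assoc <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame(gene_id = character(), mask_name = character(),
               arm = character(), beta_sd = numeric(), se = numeric(),
               p = numeric(), n = integer(), n_carriers = integer(),
               status = character(), stringsAsFactors = FALSE)
  log$burden <- stage_log("burden_tests", n_attempted, nrow(assoc),
                          c(fewer_than_min_carriers = n_untestable))

  thresholds <- stats::setNames(
    lapply(config$arms, function(a) {
      nt <- sum(assoc$arm == a & assoc$status == "ok")
      if (nt) bonferroni_threshold(nt) else NA_real_
    }), config$arms)

  partition <- NULL
  if (all(c("fetal", "maternal") %in% config$arms)) {
    partition <- wlm_partition(assoc[assoc$arm == "fetal", ],
                               assoc[assoc$arm == "maternal", ],
                               alpha = config$alpha)
    log$partition <- stage_log("wlm_partition",
                               sum(assoc$arm == "fetal" & assoc$status == "ok"),
                               nrow(partition))
  } else {
    log$partition <- stage_log("wlm_partition", 0L, 0L)
  }

  dimorphism <- NULL
  if ("fetal" %in% config$arms && !is.na(thresholds$fetal)) {
    fa <- assoc[assoc$arm == "fetal" & assoc$status == "ok", , drop = FALSE]
    hits <- fa[fa$p < thresholds$fetal, , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(hits))) {
      mk <- masks[[hits$mask_name[i]]]
      arm_samples <- intersect(samples_by_arm$fetal, colnames(gt))
      arm_gt <- gt[, arm_samples, drop = FALSE]
      bset <- build_burden_set(hits$gene_id[i], mk, cohort$variants, arm_gt,
                               maf_max = config$maf_max,
                               use_external_maf = config$use_external_maf)
      cv <- collapse_burden(bset, arm_gt, config$min_carriers)
      sf <- sex_stratified_fit(cv, tables$fetal)
      het <- if (sf$female$status == "ok" && sf$male$status == "ok")
        sex_heterogeneity(sf$female$beta_sd, sf$female$se,
                          sf$male$beta_sd, sf$male$se)
      else list(z = NA_real_, p = NA_real_, dimorphic = NA)
      rows[[i]] <- data.frame(
        gene_id = hits$gene_id[i], mask_name = hits$mask_name[i],
        beta_female = sf$female$beta_sd, se_female = sf$female$se,
        n_carriers_female = sf$female$n_carriers,
        beta_male = sf$male$beta_sd, se_male = sf$male$se,
        n_carriers_male = sf$male$n_carriers,
        z_het = het$z, p_het = het$p, dimorphic = het$dimorphic,
        stringsAsFactors = FALSE)
    }
    dimorphism <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  log_df <- do.call(rbind, log)
  rownames(log_df) <- NULL

  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    write_tsv(assoc, file.path(config$out_dir, "assoc.tsv"),
              num_cols = c("beta_sd", "se", "p"))
    if (!is.null(partition) && nrow(partition))
      write_tsv(partition, file.path(config$out_dir, "partition.tsv"),
                num_cols = grep("^(beta|se|p)", names(partition), value = TRUE))
    if (!is.null(dimorphism))
      write_tsv(dimorphism, file.path(config$out_dir, "dimorphism.tsv"),
                num_cols = grep("^(beta|se|z|p)", names(dimorphism), value = TRUE))
    write_tsv(log_df, file.path(config$out_dir, "runlog.tsv"))
  }

  list(assoc = assoc, partition = partition, dimorphism = dimorphism,
       thresholds = thresholds, log = log_df, cohort = cohort)
}
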