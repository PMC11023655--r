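# Variant collapsing masks: classify annotated variants into qualifying
# sets per gene, apply the rare-MAF filter, and collapse to per-sample
# carrier status ("dummy genotypes") with the minimum-carrier rule.

PTV_DISCOVERY <- c("stop_gained", "splice_donor", "splice_acceptor", "frameshift")
LOF_DECODE <- c("start_lost", "stop_gained", "stop_lost", "splice_donor",
                "splice_acceptor", "frameshift")

#' Define a variant collapsing mask
#'
#' A mask is the rule set deciding which annotated variants qualify for a
#' gene's burden: a consequence set, an optional LOFTEE high-confidence
#' requirement, an optional CADD lower bound, or (for `dialect = "custom"`)
#' an explicit variant list such as a clinically curated pathogenic panel.
#'
#' @param name Mask label used in results tables.
#' @param dialect One of `"discovery"`, `"regenie"`, `"decode"`, `"custom"`.
#' @param consequence_set Character vector of qualifying consequence classes.
#' @param require_loftee_hc Require LOFTEE high confidence for the
#'   truncating consequence classes.
#' @param cadd_min Minimum CADD score (inclusive, `>=`) applied to the
#'   non-truncating classes; `NULL` for none.
#' @param variant_list Explicit qualifying variant keys (custom dialect).
#' @return An object of class `collapsing_mask`.
#' @seealso [builtin_masks()] for the standard mask pairs per dialect.
#' @export
collapsing_mask <- function(name, dialect = c("discovery", "regenie", "decode",
                                              "custom"),
                            consequence_set = character(),
                            require_loftee_hc = FALSE, cadd_min = NULL,
                            variant_list = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "custom") {
    if (is.null(variant_list) || !length(variant_list))
      stop("a custom mask requires a non-empty explicit variant list",
           call. = FALSE)
    variant_list <- unique(as.character(variant_list))
  }
  if (!is.null(cadd_min) && cadd_min < 0)
    stop("'cadd_min' must be non-negative", call. = FALSE)
  structure(list(name = name, dialect = dialect,
                 consequence_set = consequence_set,
                 require_loftee_hc = require_loftee_hc,
                 cadd_min = cadd_min, variant_list = variant_list),
            class = "collapsing_mask")
}

#' Standard mask pairs by analysis dialect
#'
#' * `discovery`: `PTV` = LOFTEE high-confidence stop-gained, splice
#'   donor/acceptor, frameshift; `Missense+PTV` adds missense with
#'   CADD >= 25.
#' * `regenie` (confirmatory): as discovery, but the damaging set also
#'   admits in-frame indels with CADD >= 25.
#' * `decode` (replication): `LOF` adds start-lost and stop-lost to the
#'   truncating set; `LOF+MIS` adds the moderate-impact classes (missense,
#'   splice region, in-frame indels) with CADD >= 25.
#'
#' Splice-region variants never qualify as truncating in any dialect.
#'
#' @param dialect Dialect name.
#' @return Named list of two [collapsing_mask()] objects.
#' @export
builtin_masks <- function(dialect = c("discovery", "regenie", "decode")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    discovery = list(
      PTV = collapsing_mask("PTV", "discovery", PTV_DISCOVERY,
                            require_loftee_hc = TRUE),
      `Missense+PTV` = collapsing_mask("Missense+PTV", "discovery",
                                       c(PTV_DISCOVERY, "missense"),
                                       require_loftee_hc = TRUE, cadd_min = 25)),
    regenie = list(
      PTV = collapsing_mask("PTV", "regenie", PTV_DISCOVERY,
                            require_loftee_hc = TRUE),
      `Missense+PTV` = collapsing_mask("Missense+PTV", "regenie",
                                       c(PTV_DISCOVERY, "missense",
                                         "inframe_indel"),
                                       require_loftee_hc = TRUE, cadd_min = 25)),
    decode = list(
      LOF = collapsing_mask("LOF", "decode", LOF_DECODE,
                            require_loftee_hc = TRUE),
      `LOF+MIS` = collapsing_mask("LOF+MIS", "decode",
                                  c(LOF_DECODE, "missense", "splice_region",
                                    "inframe_indel"),
                                  require_loftee_hc = TRUE, cadd_min = 25)))
}

truncating_set <- function(mask) {
  switch(mask$dialect, decode = LOF_DECODE, PTV_DISCOVERY)
}

#' Does a variant qualify under a mask?
#'
#' Deterministic membership test for annotated variants. Truncating-class
#' variants must be LOFTEE high confidence when the mask requires it;
#' non-truncating classes in the consequence set must meet the CADD bound
#' (inclusive). Variants with a missing CADD score where the mask needs one
#' do not qualify.
#'
#' @param annotations Data frame with columns `consequence`, `loftee`,
#'   `cadd` and (for custom masks) `variant_key`.
#' @param mask A [collapsing_mask()].
#' @return Logical vector, one entry per annotation row.
#' @export
mask_qualifies <- function(annotations, mask) {
  stopifnot(inherits(mask, "collapsing_mask"))
  if (mask$dialect == "custom")
    return(annotations$variant_key %in% mask$variant_list)
  cons <- annotations$consequence
  trunc_set <- intersect(mask$consequence_set, truncating_set(mask))
  other_set <- setdiff(mask$consequence_set, trunc_set)
  q_trunc <- cons %in% trunc_set
  if (mask$require_loftee_hc) q_trunc <- q_trunc & annotations$loftee %in% "HC"
  q_other <- cons %in% other_set
  if (!is.null(mask$cadd_min))
    q_other <- q_other & !is.na(annotations$cadd) &
      annotations$cadd >= mask$cadd_min
  q_trunc | q_other
}

#' In-sample minor allele frequency
#'
#' Alternate-allele frequency over non-missing post-QC calls, folded to the
#' minor allele. A variant qualifies as rare iff `maf < maf_max` (strict).
#'
#' @param gt Dosage vector (0/1/2, `NA` missing) for one variant.
#' @param maf_max Rare-variant cutoff, default 0.001 (MAF < 0.1%).
#' @return List with `maf`, `retained` and `n_called`.
#' @export
compute_maf <- function(gt, maf_max = 0.001) {
  called <- !is.na(gt)
  n <- sum(called)
  if (n == 0L)
    return(list(maf = NA_real_, retained = FALSE, n_called = 0L))
  af <- sum(gt[called]) / (2 * n)
  maf <- min(af, 1 - af)
  list(maf = maf, retained = maf < maf_max, n_called = n)
}

#' Build a gene x mask burden set
#'
#' Selects the qualifying variants of one gene under a mask and the
#' in-sample rare-MAF filter (computed on the supplied genotype matrix,
#' i.e. per analysis arm, post-QC). An `maf_external` annotation column
#' overrides the in-sample frequency when `use_external_maf = TRUE`.
#'
#' @param gene_id Gene to collapse.
#' @param mask A [collapsing_mask()].
#' @param annotations Variant annotation data frame (must include
#'   `variant_key`, `gene_id`, `consequence`, `loftee`, `cadd`).
#' @param gt Genotype dosage matrix (variants x samples, rownames =
#'   variant keys) restricted to the analysis-arm samples.
#' @param maf_max Rare cutoff, default 0.001.
#' @param use_external_maf Use the `maf_external` column instead of the
#'   in-sample frequency.
#' @return An object of class `burden_set`: list with `gene_id`,
#'   `mask_name`, `variant_keys`.
#' @export
build_burden_set <- function(gene_id, mask, annotations, gt, maf_max = 0.001,
                             use_external_maf = FALSE) {
  ann <- annotations[annotations$gene_id == gene_id, , drop = FALSE]
  ann <- ann[ann$variant_key %in% rownames(gt), , drop = FALSE]
  qual <- ann$variant_key[mask_qualifies(ann, mask)]
  keep <- logical(length(qual))
  for (i in seq_along(qual)) {
    if (use_external_maf && !is.null(ann$maf_external)) {
      mafe <- ann$maf_external[match(qual[i], ann$variant_key)]
      keep[i] <- !is.na(mafe) && min(mafe, 1 - mafe) < maf_max
    } else {
      keep[i] <- compute_maf(gt[qual[i], ], maf_max)$retained
    }
  }
  structure(list(gene_id = gene_id, mask_name = mask$name,
                 variant_keys = sort(qual[keep])),
            class = "burden_set")
}

#' Collapse a burden set to per-sample carrier status
#'
#' Emits the "dummy genotype": status 1 for samples carrying at least one
#' alternate allele at at least one qualifying variant (non-missing), `NA`
#' for samples missing at every qualifying variant, 0 otherwise. The gene x
#' mask combination is testable only when it has at least `min_carriers`
#' carriers (the sex-combined rule; stratified fits inherit the gene list).
#'
#' @param bset A [build_burden_set()] result.
#' @param gt Genotype dosage matrix (variants x samples).
#' @param min_carriers Minimum carrier count for testability, default 10.
#' @return An object of class `carrier_vector`: list with `gene_id`,
#'   `mask_name`, `status` (named 0/1/`NA` vector over samples),
#'   `n_carriers`, `variant_keys`, `testable`.
#' @export
collapse_burden <- function(bset, gt, min_carriers = 10) {
  stopifnot(inherits(bset, "burden_set"))
  keys <- bset$variant_keys
  samples <- colnames(gt)
  if (!length(keys)) {
    status <- stats::setNames(rep(NA_integer_, length(samples)), samples)
    return(structure(list(gene_id = bset$gene_id, mask_name = bset$mask_name,
                          status = status, n_carriers = 0L,
                          variant_keys = character(), testable = FALSE),
                     class = "carrier_vector"))
  }
  sub <- gt[keys, , drop = FALSE]
  any_alt <- colSums(sub > 0L, na.rm = TRUE) > 0L
  all_missing <- colSums(!is.na(sub)) == 0L
  status <- ifelse(all_missing, NA_integer_, as.integer(any_alt))
  names(status) <- samples
  n_car <- sum(status == 1L, na.rm = TRUE)
  structure(list(gene_id = bset$gene_id, mask_name = bset$mask_name,
                 status = status, n_carriers = n_car, variant_keys = keys,
                 testable = n_car >= min_carriers),
            class = "carrier_vector")
}

#' Remove one variant from a burden set
#'
#' Leave-one-out sensitivity analysis: returns the burden set without the
#' named variant. Removing a key that is not in the set is the identity.
#'
#' @param bset A `burden_set`.
#' @param variant_key Key to remove.
#' @return The reduced `burden_set`.
#' @export
leave_one_out <- function(bset, variant_key) {
  stopifnot(inherits(bset, "burden_set"))
  bset$variant_keys <- setdiff(bset$variant_keys, variant_key)
  bset
}

#' Build a custom mask from an explicit variant list
#'
#' Used for curated panels (e.g. clinically classified pathogenic variants)
#' and score-defined subsets: exactly the listed variant keys qualify.
#' Duplicate keys collapse to one.
#'
#' @param variant_list Non-empty character vector of variant keys.
#' @param name Mask label.
#' @return A [collapsing_mask()] with `dialect = "custom"`.
#' @export
build_custom_mask <- function(variant_list, name = "custom") {
  collapsing_mask(name, "custom", variant_list = variant_list)
}
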