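# Genotype-level and variant-level sequencing QC applied ahead of any
# association analysis: depth/genotype-quality call filtering, the exact
# binomial allele-balance test for heterozygous SNVs, a per-variant
# missingness cutoff, the allele-depth-on-depth regression slope filter,
# and an optional pass-through variant score (AAscore) cutoff.

#' QC thresholds
#'
#' Container for the quality-control cutoffs. Defaults: SNV calls need
#' depth >= 7 and genotype quality >= 20, indel calls depth >= 10 and
#' GQ >= 20 (strict `<` comparisons fail); heterozygous SNVs with a
#' two-sided exact binomial allele-balance p-value <= 1e-3 are set missing;
#' variants with more than 50% missing genotypes are dropped; the
#' AD-on-DP regression drops variants with slope < 0.5; variants with an
#' AAscore annotation <= 0.8 are dropped when that column is present.
#'
#' @param snv_dp,snv_gq,indel_dp,indel_gq Minimum depth / genotype quality.
#' @param ab_p Allele-balance p-value cutoff (calls with p <= `ab_p` are
#'   set missing).
#' @param max_missing Maximum tolerated missing-genotype fraction (strictly
#'   greater drops the variant).
#' @param min_slope Minimum AD-on-DP regression slope.
#' @param min_aascore Minimum variant AAscore (strictly greater passes).
#' @param min_slope_carriers Minimum non-missing carrier calls required
#'   before the slope filter is attempted.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snv_dp = 7, snv_gq = 20, indel_dp = 10, indel_gq = 20,
                          ab_p = 1e-3, max_missing = 0.5, min_slope = 0.5,
                          min_aascore = 0.8, min_slope_carriers = 5) {
  vals <- c(snv_dp, snv_gq, indel_dp, indel_gq, ab_p, max_missing, min_slope,
            min_aascore, min_slope_carriers)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all QC thresholds must be positive and finite", call. = FALSE)
  if (max_missing > 1) stop("'max_missing' must lie in (0, 1]", call. = FALSE)
  structure(list(snv_dp = snv_dp, snv_gq = snv_gq, indel_dp = indel_dp,
                 indel_gq = indel_gq, ab_p = ab_p, max_missing = max_missing,
                 min_slope = min_slope, min_aascore = min_aascore,
                 min_slope_carriers = as.integer(min_slope_carriers)),
            class = "qc_thresholds")
}

#' Depth / genotype-quality call filter
#'
#' Sets genotype calls to missing when they fail the low-quality rule for
#' their variant class. The default rule is disjunctive: a call failing
#' *either* the depth or the genotype-quality cutoff is set missing
#' (`rule = "or"`); the conjunctive reading, where both must fail, is
#' available as `rule = "and"`. Comparisons are strict (`dp < snv_dp` fails;
#' an SNV call at exactly DP 7 / GQ 20 passes). Calls with missing DP or GQ
#' are left unchanged. The filter is idempotent.
#'
#' @param gt Integer dosage vector (0/1/2, `NA` = missing).
#' @param dp,gq Depth and genotype-quality vectors aligned with `gt`.
#' @param vclass `"SNV"` or `"indel"` (scalar or per-call vector).
#' @param thresholds A [qc_thresholds()].
#' @param rule `"or"` (default) or `"and"`.
#' @return `gt` with failing calls set to `NA`.
#' @export
filter_genotype <- function(gt, dp, gq, vclass, thresholds = qc_thresholds(),
                            rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (!all(vclass %in% c("SNV", "indel")))
    stop("unknown variant class: ", paste(setdiff(vclass, c("SNV", "indel")),
                                          collapse = ", "), call. = FALSE)
  min_dp <- ifelse(vclass == "SNV", thresholds$snv_dp, thresholds$indel_dp)
  min_gq <- ifelse(vclass == "SNV", thresholds$snv_gq, thresholds$indel_gq)
  low_dp <- !is.na(dp) & dp < min_dp
  low_gq <- !is.na(gq) & gq < min_gq
  fails <- if (rule == "or") low_dp | low_gq else low_dp & low_gq
  gt[fails] <- NA_integer_
  gt
}

#' Exact binomial allele-balance test for heterozygous calls
#'
#' Tests the observed alternate-allele read count against the 50% balance
#' expected at a true heterozygote: two-sided exact binomial p-value under
#' p0 = 0.5, defined as the doubled smaller tail capped at 1 (at p0 = 0.5
#' the pmf is symmetric, so all common two-sided definitions coincide).
#' The test is computed over `total = ad_ref + ad_alt`, not DP.
#'
#' @param ad_alt Alternate-allele read count(s).
#' @param total Total informative reads (`ad_ref + ad_alt`), >= 1. A total
#'   of 0 returns `NA` (the test is skipped and the call is left unchanged
#'   by [apply_genotype_qc()]).
#' @return Two-sided p-value(s) in (0, 1].
#' @examples
#' allele_balance_test(5, 10)   # perfect balance: p = 1
#' allele_balance_test(0, 20)   # 2 / 2^20 ~= 1.9e-6
#' @export
allele_balance_test <- function(ad_alt, total) {
  if (any(ad_alt < 0, na.rm = TRUE) || any(total < 0, na.rm = TRUE))
    stop("read counts must be non-negative", call. = FALSE)
  if (any(ad_alt > total, na.rm = TRUE))
    stop("ad_alt cannot exceed the total read count", call. = FALSE)
  lower <- stats::pbinom(ad_alt, total, 0.5)
  upper <- stats::pbinom(ad_alt - 1, total, 0.5, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[!is.na(total) & total == 0] <- NA_real_
  p
}

#' Per-variant missingness filter
#'
#' Drops a variant when the fraction of missing genotype calls (after the
#' call-level filters) is strictly greater than `max_missing`.
#'
#' @param gt Dosage vector for one variant across samples (`NA` = missing).
#' @param max_missing Cutoff fraction in (0, 1].
#' @return List with `keep` (logical) and `fraction` (missing fraction).
#' @export
missingness_filter <- function(gt, max_missing = 0.5) {
  if (length(gt) == 0L) stop("no samples: missingness undefined", call. = FALSE)
  frac <- mean(is.na(gt))
  list(keep = frac <= max_missing, fraction = frac)
}

#' Allele-depth on depth regression slope filter
#'
#' For a well-behaved variant the expected alternate allele count is 0,
#' DP/2 and DP for hom-ref, het and hom-alt calls respectively, i.e. AD
#' falls on the identity line against the genotype-expected fraction of DP.
#' This fits the single no-intercept slope `b` in
#' `AD_alt = b * (w(GT) * DP)` with weights w = 0 / 0.5 / 1 by least
#' squares, `b = sum(AD * wDP) / sum((wDP)^2)`; variants with `b <
#' min_slope` are flagged spurious.
#'
#' @param gt,dp,ad_alt Per-sample call vectors for one variant.
#' @param min_slope Drop threshold on the fitted slope.
#' @param min_carriers Minimum non-missing het/hom-alt calls; below it the
#'   filter is skipped (`status = "skipped"`).
#' @return List with `slope` (`NA` when skipped), `status` one of
#'   `"keep"`, `"drop"`, `"skipped"`, and `n_carriers`.
#' @export
ad_dp_slope <- function(gt, dp, ad_alt, min_slope = 0.5, min_carriers = 5) {
  ok <- !is.na(gt) & !is.na(dp) & !is.na(ad_alt)
  carriers <- ok & gt > 0L
  n_car <- sum(carriers)
  if (n_car < min_carriers)
    return(list(slope = NA_real_, status = "skipped", n_carriers = n_car))
  w <- c(0, 0.5, 1)[gt[ok] + 1L]
  wdp <- w * dp[ok]
  denom <- sum(wdp^2)
  if (denom == 0)
    return(list(slope = NA_real_, status = "skipped", n_carriers = n_car))
  b <- sum(ad_alt[ok] * wdp) / denom
  list(slope = b, status = if (b < min_slope) "drop" else "keep",
       n_carriers = n_car)
}

#' Apply the full genotype QC stage to a cohort
#'
#' Runs, in order: the depth/GQ call filter, the allele-balance test on
#' heterozygous SNV calls (p <= `ab_p` set missing; calls with zero
#' informative reads are skipped), the per-variant missingness filter, and
#' optionally the AD-on-DP slope filter and the AAscore cutoff (applied
#' when the cohort's variant table carries an `aascore` column). Variants
#' failing a variant-level filter are removed from the cohort.
#'
#' @param cohort A `duo_cohort` with read-level calls, or with genotypes
#'   only (call-level filters needing absent fields are skipped with a
#'   warning).
#' @param thresholds A [qc_thresholds()].
#' @param rule Depth/GQ rule, see [filter_genotype()].
#' @param slope_filter Apply the AD-on-DP slope filter (the replication
#'   dialect); default `FALSE`.
#' @return The cohort with filtered calls, dropped variants removed, and a
#'   `qc_log` element (data.frame of per-filter counts).
#' @export
apply_genotype_qc <- function(cohort, thresholds = qc_thresholds(),
                              rule = c("or", "and"), slope_filter = FALSE) {
  stopifnot(inherits(cohort, "duo_cohort"))
  rule <- match.arg(rule)
  calls <- cohort$calls
  if (is.null(calls)) calls <- list(gt = cohort$geno)
  gt <- calls$gt
  v <- cohort$variants
  log <- list()

  n_before <- sum(!is.na(gt))
  if (!is.null(calls$dp) && !is.null(calls$gq)) {
    for (j in seq_len(nrow(gt))) {
      gt[j, ] <- filter_genotype(gt[j, ], calls$dp[j, ], calls$gq[j, ],
                                 v$vclass[j], thresholds, rule)
    }
    log$dp_gq <- n_before - sum(!is.na(gt))
  } else {
    warning("DP/GQ fields absent; depth/quality filter skipped")
    log$dp_gq <- NA_integer_
  }

  if (!is.null(calls$ad_alt) && !is.null(calls$ad_ref)) {
    n_ab <- 0L
    for (j in seq_len(nrow(gt))) {
      if (v$vclass[j] != "SNV") next
      het <- which(!is.na(gt[j, ]) & gt[j, ] == 1L)
      if (!length(het)) next
      tot <- calls$ad_ref[j, het] + calls$ad_alt[j, het]
      p <- allele_balance_test(calls$ad_alt[j, het], tot)
      bad <- het[!is.na(p) & p <= thresholds$ab_p]
      gt[j, bad] <- NA_integer_
      n_ab <- n_ab + length(bad)
    }
    log$allele_balance <- n_ab
  } else {
    warning("AD field absent; allele-balance filter skipped")
    log$allele_balance <- NA_integer_
  }

  miss_frac <- rowMeans(is.na(gt))
  keep <- miss_frac <= thresholds$max_missing
  log$missingness <- sum(!keep)

  slope <- rep(NA_real_, nrow(gt))
  if (slope_filter) {
    if (is.null(calls$dp) || is.null(calls$ad_alt)) {
      warning("DP/AD absent; slope filter skipped")
      log$ad_dp_slope <- NA_integer_
    } else {
      n_slope <- 0L
      for (j in which(keep)) {
        res <- ad_dp_slope(gt[j, ], calls$dp[j, ], calls$ad_alt[j, ],
                           thresholds$min_slope, thresholds$min_slope_carriers)
        slope[j] <- res$slope
        if (res$status == "drop") { keep[j] <- FALSE; n_slope <- n_slope + 1L }
      }
      log$ad_dp_slope <- n_slope
    }
  }

  if (!is.null(v$aascore)) {
    low <- keep & !is.na(v$aascore) & v$aascore <= thresholds$min_aascore
    keep[low] <- FALSE
    log$aascore <- sum(low)
  }

  calls$gt <- gt
  cohort$calls <- lapply(calls, function(m) m[keep, , drop = FALSE])
  cohort$variants <- v[keep, , drop = FALSE]
  cohort$variants$missing_fraction <- miss_frac[keep]
  if (slope_filter) cohort$variants$ad_dp_slope <- slope[keep]
  if (!is.null(cohort$geno) && nrow(cohort$geno) == length(keep))
    cohort$geno <- cohort$geno[keep, , drop = FALSE]
  if (!is.null(cohort$paternal) && nrow(cohort$paternal) == length(keep))
    cohort$paternal <- cohort$paternal[keep, , drop = FALSE]
  cohort$qc_log <- data.frame(
    filter = names(log),
    n_removed = unlist(log, use.names = FALSE),
    unit = c("calls", "calls", rep("variants", length(log) - 2L)),
    row.names = NULL, stringsAsFactors = FALSE)
  cohort
}
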