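# Covariate-adjusted gene burden regression and multiple-testing helpers.
#
# The burden fit is ordinary least squares of the standardised phenotype on
# per-gene carrier status plus covariates. The discovery study used linear
# mixed models whose random effects control relatedness and stratification;
# with unrelated samples the fixed-effect carrier estimand is identical, so
# OLS is the estimator here (a precomputed relatedness adjustment can be
# passed as an extra covariate column).

#' Fit a gene burden association
#'
#' OLS of `phenotype_sd` on carrier status plus every covariate column of
#' the analysis table. The reported effect is the carrier coefficient in
#' phenotype SD units, with its standard error and a two-sided p-value from
#' the t distribution at the residual degrees of freedom. Samples with
#' missing carrier status (missing at every qualifying variant) are
#' dropped (complete-case). Collinear covariates are dropped with a
#' message; a zero-variance carrier vector yields `status = "skipped"`.
#'
#' @param carrier A `carrier_vector` (see [collapse_burden()]) or a named
#'   0/1 vector aligned by `person_id`.
#' @param table An [analysis_table()].
#' @param arm Label stored in the result (defaults to the table's arm).
#' @param min_carriers Minimum carrier count among the analysed samples;
#'   below it the gene is reported non-testable (`status = "untestable"`).
#' @param covariates Covariate column names; default all columns except
#'   `person_id` and `phenotype_sd`.
#' @return One-row data.frame (`assoc_result`): `gene_id`, `mask_name`,
#'   `arm`, `beta_sd`, `se`, `p`, `n`, `n_carriers`, `status`.
#' @export
fit_burden <- function(carrier, table, arm = NULL, min_carriers = 10,
                       covariates = NULL) {
  if (inherits(carrier, "carrier_vector")) {
    gene_id <- carrier$gene_id; mask_name <- carrier$mask_name
    status <- carrier$status
  } else {
    gene_id <- attr(carrier, "gene_id") %||% NA_character_
    mask_name <- attr(carrier, "mask_name") %||% NA_character_
    status <- carrier
  }
  if (is.null(arm)) arm <- attr(table, "arm") %||% NA_character_
  if (is.null(names(status))) {
    if (length(status) != nrow(table))
      stop("unnamed carrier vector must match the table rows", call. = FALSE)
    x <- status
  } else {
    x <- status[table$person_id]
  }
  keep <- !is.na(x)
  x <- x[keep]
  tab <- table[keep, , drop = FALSE]
  n_car <- sum(x == 1L)
  res <- data.frame(gene_id = gene_id, mask_name = mask_name, arm = arm,
                    beta_sd = NA_real_, se = NA_real_, p = NA_real_,
                    n = length(x), n_carriers = n_car, status = "ok",
                    stringsAsFactors = FALSE)
  if (n_car < min_carriers) { res$status <- "untestable"; return(res) }
  if (stats::var(x) == 0) { res$status <- "skipped"; return(res) }
  if (is.null(covariates))
    covariates <- setdiff(names(tab), c("person_id", "phenotype_sd"))
  dat <- data.frame(.y = tab$phenotype_sd, .carrier = x,
                    tab[, covariates, drop = FALSE])
  # drop constant covariates up front (single-level factors break lm)
  const <- vapply(dat[, -(1:2), drop = FALSE],
                  function(col) length(unique(col)) < 2L, TRUE)
  if (any(const)) {
    message("dropping constant covariate(s): ",
            paste(names(const)[const], collapse = ", "))
    dat <- dat[, c(TRUE, TRUE, !const), drop = FALSE]
  }
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased))
    message("dropping collinear covariate(s): ", paste(aliased, collapse = ", "))
  sm <- summary(fit)$coefficients
  if (!".carrier" %in% rownames(sm)) { res$status <- "skipped"; return(res) }
  res$beta_sd <- sm[".carrier", "Estimate"]
  res$se <- sm[".carrier", "Std. Error"]
  res$p <- sm[".carrier", "Pr(>|t|)"]
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sex-stratified burden fits
#'
#' Fits the burden association separately in females and males (fetal arm),
#' dropping the sex covariate within strata. The minimum-carrier rule is
#' not applied within strata (genes inherit the sex-combined list); a
#' stratum with zero carriers is reported as not estimable.
#'
#' @param carrier A `carrier_vector` or named 0/1 vector.
#' @param table A fetal-arm [analysis_table()] (must have a `sex` column).
#' @return List with `female` and `male` one-row `assoc_result` data.frames
#'   (status `"not_estimable"` when a stratum has no carriers).
#' @export
sex_stratified_fit <- function(carrier, table) {
  if (!"sex" %in% names(table))
    stop("sex-stratified fits need a 'sex' column (fetal arm)", call. = FALSE)
  fit_stratum <- function(sx) {
    tab <- table[table$sex == sx, , drop = FALSE]
    tab$sex <- NULL
    status <- if (inherits(carrier, "carrier_vector")) carrier$status else carrier
    x <- status[tab$person_id]
    arm_label <- paste0("fetal_", c(F = "female", M = "male")[[sx]])
    out <- fit_burden(carrier, tab, min_carriers = 1)
    out$arm <- arm_label
    if (sum(x == 1L, na.rm = TRUE) == 0L) out$status <- "not_estimable"
    out
  }
  list(female = fit_stratum("F"), male = fit_stratum("M"))
}

#' Bonferroni exome-wide significance threshold
#'
#' `0.05 / n_tests`, where `n_tests` counts the gene x mask combinations
#' actually tested, summed across masks within an arm.
#'
#' @param n_tests Number of tests, >= 1.
#' @param alpha Family-wise error rate, default 0.05.
#' @return The per-test significance threshold.
#' @examples
#' bonferroni_threshold(16735 + 13684)  # 1.64e-6
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || any(n_tests < 1))
    stop("'n_tests' must be a positive count", call. = FALSE)
  alpha / n_tests
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjusted p-values with a pass/fail call at `alpha`.
#'
#' @param p P-values in (0, 1].
#' @param alpha FDR level, default 0.05.
#' @return Data frame with `p`, `p_adjusted`, `significant`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p_adjusted = adj, significant = adj <= alpha)
}
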