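# Secondary inference on identified genes: sex-dimorphism heterogeneity,
# conditional attenuation against GWAS sentinel dosages, and exact
# sign-test replication concordance.

#' Two-sample heterogeneity test for sex-stratified estimates
#'
#' Compares a gene's female and male effect estimates with
#' `z = (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)` and a two-sided p-value
#' from the standard normal (the large-df limit of the two-sample t-test;
#' at biobank stratum sizes the two coincide). The association is deemed
#' dimorphic at p < 0.05.
#'
#' @param beta_f,se_f Female-stratum estimate and SE.
#' @param beta_m,se_m Male-stratum estimate and SE.
#' @param alpha Dimorphism level, default 0.05.
#' @return List with `z`, `p`, `dimorphic`.
#' @examples
#' sex_heterogeneity(-1.710, 0.340, -0.177, 0.592)  # p ~= 2.5e-2
#' @export
sex_heterogeneity <- function(beta_f, se_f, beta_m, se_m, alpha = 0.05) {
  if (any(se_f <= 0) || any(se_m <= 0))
    stop("standard errors must be positive", call. = FALSE)
  z <- (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, dimorphic = p < alpha)
}

#' Conditional attenuation on a GWAS sentinel dosage
#'
#' Tests whether a gene's burden signal is shared with a nearby common
#' GWAS variant: the phenotype is first residualised on the covariates,
#' then the residuals are regressed on carrier status alone
#' (unconditional) and on carrier status plus the sentinel dosage jointly
#' (conditional). A relative change of the carrier estimate above 10% is
#' flagged as attenuation; a sign flip with |change| > 10% is attenuation
#' too, flagged specially.
#'
#' @param carrier A `carrier_vector` or named 0/1 vector.
#' @param snp_dosage Named dosage vector in \[0, 2\] per sample.
#' @param table An [analysis_table()].
#' @param threshold Relative-change cutoff, default 0.10.
#' @return List with `beta_unconditional`, `beta_conditional`,
#'   `relative_change`, `attenuated`, `sign_flip`.
#' @export
conditional_fit <- function(carrier, snp_dosage, table, threshold = 0.10) {
  status <- if (inherits(carrier, "carrier_vector")) carrier$status else carrier
  x <- if (is.null(names(status))) status else status[table$person_id]
  d <- if (is.null(names(snp_dosage))) snp_dosage else snp_dosage[table$person_id]
  if (any(d < 0 | d > 2, na.rm = TRUE))
    stop("SNP dosages must lie in [0, 2]", call. = FALSE)
  keep <- !is.na(x) & !is.na(d)
  x <- x[keep]; d <- d[keep]
  tab <- table[keep, , drop = FALSE]
  covs <- setdiff(names(tab), c("person_id", "phenotype_sd"))
  resid <- if (length(covs)) {
    stats::residuals(
      stats::lm(phenotype_sd ~ ., data = tab[, c("phenotype_sd", covs)]))
  } else {
    tab$phenotype_sd - mean(tab$phenotype_sd)
  }
  b_u <- stats::coef(stats::lm(resid ~ x))[["x"]]
  b_c <- stats::coef(stats::lm(resid ~ x + d))[["x"]]
  if (abs(b_u) < 1e-12) {
    return(list(beta_unconditional = b_u, beta_conditional = b_c,
                relative_change = NA_real_, attenuated = NA,
                sign_flip = NA))
  }
  rel <- abs(b_c - b_u) / abs(b_u)
  list(beta_unconditional = b_u, beta_conditional = b_c,
       relative_change = rel, attenuated = rel > threshold,
       sign_flip = sign(b_c) != sign(b_u))
}

#' Exact sign test of directional concordance
#'
#' Counts sign-concordant discovery/replication effect pairs and tests the
#' count against Binomial(n, 1/2) with the two-sided exact p-value
#' (symmetric doubled tail, capped at 1). Pairs with a zero effect on
#' either side are dropped with a message.
#'
#' @param discovery_betas,replication_betas Paired effect estimates for the
#'   same gene x mask combinations.
#' @return List with `k_concordant`, `n`, `p`.
#' @examples
#' sign_test(rep(1, 11), c(rep(1, 10), -1))  # 10/11 concordant: p ~= 0.012
#' @export
sign_test <- function(discovery_betas, replication_betas) {
  if (length(discovery_betas) != length(replication_betas))
    stop("discovery and replication estimates must be paired", call. = FALSE)
  ok <- is.finite(discovery_betas) & is.finite(replication_betas) &
    discovery_betas != 0 & replication_betas != 0
  if (any(!ok)) message("dropping ", sum(!ok), " pair(s) with zero/missing effects")
  if (!sum(ok)) stop("no non-zero pairs left to test", call. = FALSE)
  k <- sum(sign(discovery_betas[ok]) == sign(replication_betas[ok]))
  n <- sum(ok)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(k_concordant = k, n = n, p = min(1, 2 * min(lower, upper)))
}
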