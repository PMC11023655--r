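# Weighted-linear-model decomposition of correlated marginal maternal and
# fetal burden estimates into conditional effects.
#
# Under Mendelian transmission the maternal and fetal genotypes (and hence
# rare-variant carrier burdens) correlate at r = 0.5, so the marginal
# regressions have expectations
#   E[bF_hat] = bF + r * bM,   E[bM_hat] = bM + r * bF.
# The decomposition inverts this linear map; at r = 0.5 the inverse is
#   bF_adj = (4 bF_hat - 2 bM_hat) / 3,  bM_adj = (4 bM_hat - 2 bF_hat) / 3,
# with variances by linear error propagation (an optional correlation
# `rho` between the two marginal estimates, from sample overlap, enters
# the cross term).

#' WLM adjustment of marginal fetal/maternal estimates
#'
#' Converts marginal fetal and maternal burden estimates into conditional
#' (adjusted) effects by inverting the r-correlated marginal expectation
#' map, propagating the standard errors, and computing two-sided normal
#' p-values. Vectorised over its inputs.
#'
#' @param beta_f,se_f Marginal fetal estimate and SE (phenotype SD units).
#' @param beta_m,se_m Marginal maternal estimate and SE.
#' @param rho Correlation between the two marginal estimates induced by
#'   sample overlap; default 0.
#' @param r Genotype correlation between mother and child, default 0.5.
#' @return Data frame with `beta_fetal_adj`, `se_fetal_adj`, `p_fetal_adj`,
#'   `beta_maternal_adj`, `se_maternal_adj`, `p_maternal_adj`.
#' @examples
#' wlm_adjust(1.0, 0.1, 0.5, 0.1)  # exact inversion of (bF = 1, bM = 0)
#' @export
wlm_adjust <- function(beta_f, se_f, beta_m, se_m, rho = 0, r = 0.5) {
  if (any(se_f <= 0) || any(se_m <= 0))
    stop("standard errors must be positive", call. = FALSE)
  if (any(rho < -1 | rho > 1)) stop("'rho' must lie in [-1, 1]", call. = FALSE)
  if (any(abs(r) >= 1)) stop("genotype correlation must lie in (-1, 1)",
                             call. = FALSE)
  a <- 1 / (1 - r^2)
  b <- -r / (1 - r^2)
  bf <- a * beta_f + b * beta_m
  bm <- a * beta_m + b * beta_f
  vf <- a^2 * se_f^2 + b^2 * se_m^2 + 2 * a * b * rho * se_f * se_m
  vm <- a^2 * se_m^2 + b^2 * se_f^2 + 2 * a * b * rho * se_f * se_m
  sf <- sqrt(vf); sm <- sqrt(vm)
  data.frame(beta_fetal_adj = bf, se_fetal_adj = sf,
             p_fetal_adj = 2 * stats::pnorm(-abs(bf / sf)),
             beta_maternal_adj = bm, se_maternal_adj = sm,
             p_maternal_adj = 2 * stats::pnorm(-abs(bm / sm)))
}

#' Classify a gene from its adjusted p-values
#'
#' `fetal_only` when only the adjusted fetal effect is nominally
#' significant, `maternal_only` symmetrically, `both` or `neither`
#' accordingly.
#'
#' @param p_fetal_adj,p_maternal_adj Adjusted p-values.
#' @param alpha Nominal level, default 0.05.
#' @return Character vector of classifications.
#' @export
classify_gene <- function(p_fetal_adj, p_maternal_adj, alpha = 0.05) {
  f <- p_fetal_adj < alpha
  m <- p_maternal_adj < alpha
  out <- rep("neither", length(f))
  out[f & !m] <- "fetal_only"
  out[!f & m] <- "maternal_only"
  out[f & m] <- "both"
  out
}

#' Partition a table of marginal pairs
#'
#' Joins fetal and maternal `assoc_result` tables by gene x mask, applies
#' [wlm_adjust()] and [classify_gene()].
#'
#' @param fetal,maternal Data frames of burden results (rows with
#'   `status != "ok"` are dropped).
#' @param rho,r,alpha Passed to [wlm_adjust()] / [classify_gene()].
#' @return Data frame with gene, mask, both marginal and adjusted
#'   estimates, and the classification.
#' @export
wlm_partition <- function(fetal, maternal, rho = 0, r = 0.5, alpha = 0.05) {
  f <- fetal[fetal$status == "ok", , drop = FALSE]
  m <- maternal[maternal$status == "ok", , drop = FALSE]
  mg <- merge(f, m, by = c("gene_id", "mask_name"), suffixes = c("_f", "_m"))
  if (!nrow(mg)) {
    return(data.frame(gene_id = character(), mask_name = character()))
  }
  adj <- wlm_adjust(mg$beta_sd_f, mg$se_f, mg$beta_sd_m, mg$se_m,
                    rho = rho, r = r)
  out <- cbind(mg[, c("gene_id", "mask_name")],
               beta_fetal = mg$beta_sd_f, se_fetal = mg$se_f, p_fetal = mg$p_f,
               beta_maternal = mg$beta_sd_m, se_maternal = mg$se_m,
               p_maternal = mg$p_m, adj)
  out$classification <- classify_gene(adj$p_fetal_adj, adj$p_maternal_adj,
                                      alpha)
  out
}
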