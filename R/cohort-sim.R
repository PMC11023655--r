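# Mother-child duo cohort simulator.
#
# The generator realises the data structure the burden pipeline consumes:
# duos under Mendelian transmission (which induces the r = 0.5 correlation
# between maternal and fetal dosages), rare qualifying variants with
# gene-level fetal/maternal/sex-specific effects on a standardised birth
# weight scale, per-call sequencing artifacts, and raw repeated phenotype
# reports with the failure modes the derivation rules must handle.

#' Specify a gene's variant architecture and true effects
#'
#' A `gene_spec` describes one gene in a simulated cohort: either an explicit
#' variant table or a count of variants whose properties are realised (under
#' the simulation seed) when [simulate_duos()] runs. Effects are expressed in
#' phenotype standard-deviation units per carrier of any alternate allele in
#' the gene (the "carrier allele-set" that collapsing masks target).
#'
#' @param gene_id Gene symbol/identifier (unique within a config).
#' @param n_variants Number of variants to realise when `variants` is `NULL`.
#' @param af Allele frequencies: scalar or length-`n_variants` vector in
#'   (0, 1). `NULL` draws each frequency uniformly from (2e-5, 5e-4), i.e.
#'   rare variants comfortably below the MAF < 0.1% qualifying cutoff.
#' @param variants Optional explicit `data.frame` with columns `af`,
#'   `consequence`, `loftee`, `cadd` (one row per variant). Overrides
#'   `n_variants`/`af`.
#' @param ptv_fraction Fraction of realised variants drawn as high-confidence
#'   protein-truncating consequences; the remainder are damaging missense
#'   (CADD drawn in \[25, 45\]).
#' @param beta_fetal,beta_maternal True conditional effects (SD units) of
#'   fetal and maternal carrier status on the child's birth weight.
#' @param beta_fetal_female,beta_fetal_male Optional sex-specific fetal
#'   effects (SD units); when both are supplied they replace `beta_fetal`
#'   in the respective stratum.
#' @return An object of class `gene_spec`.
#' @examples
#' gene_spec("GCK1", n_variants = 12, beta_fetal = -0.311, beta_maternal = 0.430)
#' @export
gene_spec <- function(gene_id, n_variants = 20, af = NULL, variants = NULL,
                      ptv_fraction = 0.4,
                      beta_fetal = 0, beta_maternal = 0,
                      beta_fetal_female = NULL, beta_fetal_male = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  for (b in list(beta_fetal, beta_maternal, beta_fetal_female, beta_fetal_male)) {
    if (!is.null(b) && (!is.numeric(b) || length(b) != 1L || !is.finite(b)))
      stop("effect sizes must be finite numeric scalars", call. = FALSE)
  }
  if (!is.null(variants)) {
    stopifnot(is.data.frame(variants),
              all(c("af", "consequence", "loftee", "cadd") %in% names(variants)))
    af <- variants$af
    n_variants <- nrow(variants)
  }
  if (!is.null(af)) {
    if (!is.numeric(af) || any(!is.finite(af)) || any(af <= 0) || any(af >= 1))
      stop("allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
    if (length(af) == 1L) af <- rep(af, n_variants)
    if (length(af) != n_variants)
      stop("'af' must have length 1 or n_variants", call. = FALSE)
  }
  if (n_variants < 1L) stop("a gene needs at least one variant", call. = FALSE)
  if (!is.null(beta_fetal_female) != !is.null(beta_fetal_male))
    stop("supply both or neither of the sex-specific fetal effects", call. = FALSE)
  structure(list(gene_id = gene_id, n_variants = as.integer(n_variants),
                 af = af, variants = variants, ptv_fraction = ptv_fraction,
                 beta_fetal = beta_fetal, beta_maternal = beta_maternal,
                 beta_fetal_female = beta_fetal_female,
                 beta_fetal_male = beta_fetal_male),
            class = "gene_spec")
}

#' Simulation configuration for a mother-child duo cohort
#'
#' Bundles the cohort size, genetic architecture, residual noise, covariate
#' effects, sequencing-artifact rates and phenotype-reporting behaviour under
#' a single seed. With the seed fixed, [simulate_duos()], [simulate_reads()]
#' and [emit_cohort()] are fully deterministic.
#'
#' @param n_duos Number of mother-child pairs.
#' @param gene_specs List of [gene_spec()] objects.
#' @param noise_sd Residual SD of the latent phenotype (SD units).
#' @param covariate_effects Named list of covariate effects in SD units per
#'   standardised covariate unit: `age`, `age2`, `sex` (male offset), `pc`
#'   (applied to PC1), `batch` (second-batch offset), `mother_age`
#'   (mother's age at first birth).
#' @param artifact_rates Named list of probabilities: `low_dp` (per-call low
#'   coverage), `low_gq` (per-call degraded genotype quality), `allele_bias`
#'   (per-variant biased heterozygote allele fraction), `missing` (per-call
#'   missing genotype).
#' @param reporting Named list controlling raw phenotype reports: `n_visits`,
#'   `report_noise_kg`, `discordant_rate`, `multiple_birth_rate`,
#'   `extreme_rate`, `hospital_record_rate`.
#' @param bw_mean_kg,bw_sd_kg Mapping of the latent SD-scale phenotype to
#'   kilograms (defaults 3.5 kg mean, 0.5 kg SD — conventional term birth
#'   weight values, so the kg-domain exclusion rules are exercisable).
#' @param seed Integer seed governing all randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_duos,
                       gene_specs = list(),
                       noise_sd = 1,
                       covariate_effects = list(age = 0.02, age2 = 0.01,
                                                sex = 0.25, pc = 0.02,
                                                batch = 0.01, mother_age = 0.05),
                       artifact_rates = list(low_dp = 0.01, low_gq = 0.01,
                                             allele_bias = 0.02, missing = 0.005),
                       reporting = list(n_visits = 2, report_noise_kg = 0.05,
                                        discordant_rate = 0.005,
                                        multiple_birth_rate = 0.02,
                                        extreme_rate = 0.002,
                                        hospital_record_rate = 0.5),
                       bw_mean_kg = 3.5, bw_sd_kg = 0.5,
                       seed = 1L) {
  stopifnot(is.numeric(n_duos), length(n_duos) == 1L, n_duos >= 1)
  if (!is.list(gene_specs) || !all(vapply(gene_specs, inherits, TRUE, "gene_spec")))
    stop("'gene_specs' must be a list of gene_spec objects", call. = FALSE)
  ids <- vapply(gene_specs, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("gene ids must be unique", call. = FALSE)
  def_cov <- list(age = 0, age2 = 0, sex = 0, pc = 0, batch = 0, mother_age = 0)
  covariate_effects <- utils::modifyList(def_cov, as.list(covariate_effects))
  def_art <- list(low_dp = 0, low_gq = 0, allele_bias = 0, missing = 0)
  artifact_rates <- utils::modifyList(def_art, as.list(artifact_rates))
  rates <- unlist(artifact_rates)
  if (any(rates < 0 | rates > 1)) stop("artifact rates must lie in [0, 1]", call. = FALSE)
  def_rep <- list(n_visits = 2L, report_noise_kg = 0.05, discordant_rate = 0,
                  multiple_birth_rate = 0, extreme_rate = 0,
                  hospital_record_rate = 0.5)
  reporting <- utils::modifyList(def_rep, as.list(reporting))
  rrates <- unlist(reporting[c("discordant_rate", "multiple_birth_rate",
                               "extreme_rate", "hospital_record_rate")])
  if (any(rrates < 0 | rrates > 1)) stop("reporting rates must lie in [0, 1]", call. = FALSE)
  if (reporting$n_visits < 1) stop("need at least one report visit", call. = FALSE)
  stopifnot(is.numeric(noise_sd), noise_sd >= 0, is.finite(noise_sd),
            bw_sd_kg > 0, is.finite(bw_mean_kg))
  structure(list(n_duos = as.integer(n_duos), gene_specs = gene_specs,
                 noise_sd = noise_sd, covariate_effects = covariate_effects,
                 artifact_rates = artifact_rates, reporting = reporting,
                 bw_mean_kg = bw_mean_kg, bw_sd_kg = bw_sd_kg,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Realise variant tables for each gene spec. Positions are laid out on a
# synthetic map (one locus per gene) and keys follow chrom:pos:ref:alt.
realize_variants <- function(gene_specs) {
  if (length(gene_specs) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vclass = character(),
                      variant_key = character(), gene_id = character(),
                      consequence = character(), loftee = character(),
                      cadd = numeric(), af = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- vector("list", length(gene_specs))
  for (i in seq_along(gene_specs)) {
    gs <- gene_specs[[i]]
    nv <- gs$n_variants
    chrom <- as.character(((i - 1L) %% 22L) + 1L)
    pos <- i * 1000000L + seq_len(nv) * 97L
    if (!is.null(gs$variants)) {
      v <- gs$variants
      af <- v$af; consequence <- as.character(v$consequence)
      loftee <- as.character(v$loftee); cadd <- v$cadd
    } else {
      af <- if (is.null(gs$af)) stats::runif(nv, 2e-5, 5e-4) else gs$af
      n_ptv <- round(gs$ptv_fraction * nv)
      ptv_classes <- c("stop_gained", "frameshift", "splice_donor", "splice_acceptor")
      consequence <- c(sample(ptv_classes, n_ptv, replace = TRUE),
                       rep("missense", nv - n_ptv))
      loftee <- ifelse(consequence %in% ptv_classes, "HC", "none")
      cadd <- ifelse(consequence == "missense", stats::runif(nv, 25, 45),
                     stats::runif(nv, 30, 55))
    }
    is_indel <- consequence == "frameshift"
    ref <- ifelse(is_indel, "AT", "A")
    alt <- ifelse(is_indel, "A", "G")
    out[[i]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      vclass = ifelse(is_indel, "indel", "SNV"),
      variant_key = paste(chrom, pos, ref, alt, sep = ":"),
      gene_id = gs$gene_id, consequence = consequence, loftee = loftee,
      cadd = round(cadd, 2), af = af,
      stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, out)
  if (anyDuplicated(v$variant_key)) stop("variant keys must be unique", call. = FALSE)
  rownames(v) <- v$variant_key
  v
}

#' Simulate a mother-child duo cohort
#'
#' Draws maternal genotypes under Hardy-Weinberg equilibrium, transmits one
#' maternal allele to each child at random and draws the other from the
#' population allele frequency (which makes maternal and fetal dosages
#' correlate at r = 0.5 for any allele frequency), then builds the child's
#' latent phenotype on the SD scale as the sum of gene-level fetal/maternal
#' carrier effects (optionally sex-specific), covariate contributions and
#' Gaussian noise, maps it to kilograms, and generates raw repeated birth
#' weight reports for both analysis arms (child's own reports with visit
#' noise, discordance and extreme-value injection; mother's offspring
#' records from hospital and/or self-report sources).
#'
#' True genotypes are assigned before any sequencing artifacts; call-level
#' read data are added by [simulate_reads()].
#'
#' @param config A [sim_config()].
#' @return An object of class `duo_cohort`: list with `persons`, `variants`,
#'   `geno` (true dosage matrix, variants x persons), `paternal` (the
#'   child's non-maternal allele draws, for Mendelian checks),
#'   `own_reports`, `offspring_reports`, `truth` (latent phenotype and true
#'   kg birth weight per duo), and the `config`.
#' @examples
#' cfg <- sim_config(200, list(gene_spec("G1", beta_fetal = 0.3)), seed = 7)
#' cohort <- simulate_duos(cfg)
#' @export
simulate_duos <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_duos
  mid <- sprintf("M%06d", seq_len(n))
  cid <- sprintf("C%06d", seq_len(n))

  child_sex <- sample(c("F", "M"), n, replace = TRUE)
  age_child <- sample(40:69, n, replace = TRUE)
  age_mother_fb <- pmin(pmax(round(stats::rnorm(n, 26, 5)), 16), 45)
  pcs_child <- matrix(stats::rnorm(n * 10L), n, 10L,
                      dimnames = list(NULL, paste0("PC", 1:10)))
  pcs_mother <- matrix(stats::rnorm(n * 10L), n, 10L,
                       dimnames = list(NULL, paste0("PC", 1:10)))
  batch_child <- sample(c("b1", "b2"), n, replace = TRUE)
  batch_mother <- sample(c("b1", "b2"), n, replace = TRUE)

  persons <- data.frame(
    person_id = c(mid, cid),
    role = rep(c("mother", "child"), each = n),
    sex = c(rep("F", n), child_sex),
    mother_id = c(rep(NA_character_, n), mid),
    age = c(rep(NA_integer_, n), age_child),
    age_first_birth = c(age_mother_fb, rep(NA_integer_, n)),
    batch = c(batch_mother, batch_child),
    stringsAsFactors = FALSE)
  persons <- cbind(persons, rbind(pcs_mother, pcs_child))
  rownames(persons) <- persons$person_id

  variants <- realize_variants(config$gene_specs)
  nv <- nrow(variants)
  samp <- c(mid, cid)
  geno <- matrix(NA_integer_, max(nv, 0L), 2L * n,
                 dimnames = list(variants$variant_key, samp))
  paternal <- matrix(NA_integer_, max(nv, 0L), n,
                     dimnames = list(variants$variant_key, cid))
  if (nv > 0L) {
    for (j in seq_len(nv)) {
      f <- variants$af[j]
      gm <- stats::rbinom(n, 2L, f)
      transmitted <- stats::rbinom(n, 1L, gm / 2)
      pat <- stats::rbinom(n, 1L, f)
      geno[j, seq_len(n)] <- gm
      geno[j, n + seq_len(n)] <- transmitted + pat
      paternal[j, ] <- pat
    }
  }

  # latent phenotype of the child, SD scale
  ce <- config$covariate_effects
  z_age <- (age_child - 55) / 8
  z_mage <- (age_mother_fb - 26) / 5
  latent <- ce$age * z_age + ce$age2 * (z_age^2 - 1) +
    ce$sex * (child_sex == "M") + ce$pc * pcs_child[, 1L] +
    ce$batch * (batch_child == "b2") + ce$mother_age * z_mage +
    stats::rnorm(n, 0, config$noise_sd)
  for (gs in config$gene_specs) {
    keys <- variants$variant_key[variants$gene_id == gs$gene_id]
    gm <- geno[keys, seq_len(n), drop = FALSE]
    gc <- geno[keys, n + seq_len(n), drop = FALSE]
    mat_carrier <- as.integer(colSums(gm > 0L) > 0L)
    fet_carrier <- as.integer(colSums(gc > 0L) > 0L)
    if (!is.null(gs$beta_fetal_female)) {
      bf <- ifelse(child_sex == "F", gs$beta_fetal_female, gs$beta_fetal_male)
    } else bf <- gs$beta_fetal
    latent <- latent + bf * fet_carrier + gs$beta_maternal * mat_carrier
  }
  bw_kg <- config$bw_mean_kg + config$bw_sd_kg * latent

  rp <- config$reporting
  multiple_birth <- stats::rbinom(n, 1L, rp$multiple_birth_rate) == 1L

  # child's own reports across assessment visits
  nvst <- as.integer(rp$n_visits)
  own <- data.frame(
    person_id = rep(cid, each = nvst),
    visit = rep(seq_len(nvst), times = n),
    bw_kg = rep(bw_kg, each = nvst) + stats::rnorm(n * nvst, 0, rp$report_noise_kg),
    multiple_birth = rep(multiple_birth, each = nvst),
    stringsAsFactors = FALSE)
  disc <- which(stats::rbinom(n, 1L, rp$discordant_rate) == 1L)
  if (length(disc) && nvst >= 2L) {
    idx <- (disc - 1L) * nvst + 2L  # perturb the second visit
    own$bw_kg[idx] <- own$bw_kg[idx] +
      sample(c(-1, 1), length(disc), replace = TRUE) * stats::runif(length(disc), 1.1, 2.5)
  }
  extr <- which(stats::rbinom(n, 1L, rp$extreme_rate) == 1L)
  if (length(extr)) {
    lo <- stats::rbinom(length(extr), 1L, 0.5) == 1L
    ev <- ifelse(lo, stats::runif(length(extr), 0.2, 0.95),
                 stats::runif(length(extr), 7, 9.5))
    for (k in seq_along(extr))
      own$bw_kg[own$person_id == cid[extr[k]]] <- ev[k]
  }

  # mother's records of the (first) child's birth weight
  has_hosp <- stats::rbinom(n, 1L, rp$hospital_record_rate) == 1L
  self1 <- bw_kg + stats::rnorm(n, 0, rp$report_noise_kg)
  self2 <- bw_kg + stats::rnorm(n, 0, rp$report_noise_kg)
  mdisc <- stats::rbinom(n, 1L, rp$discordant_rate) == 1L
  self2[mdisc] <- self2[mdisc] +
    sample(c(-1, 1), sum(mdisc), replace = TRUE) * stats::runif(sum(mdisc), 1.1, 2.5)
  mextr <- stats::rbinom(n, 1L, rp$extreme_rate) == 1L
  if (any(mextr)) {
    lo <- stats::rbinom(sum(mextr), 1L, 0.5) == 1L
    ev <- ifelse(lo, stats::runif(sum(mextr), 0.2, 0.95),
                 stats::runif(sum(mextr), 7, 9.5))
    self1[mextr] <- ev; self2[mextr] <- ev
  }
  hosp_val <- bw_kg + stats::rnorm(n, 0, 0.005)
  offspring <- rbind(
    data.frame(mother_id = mid[has_hosp], source = "hospital",
               bw_kg = hosp_val[has_hosp], multiple_birth = multiple_birth[has_hosp],
               stringsAsFactors = FALSE),
    data.frame(mother_id = rep(mid, 2L), source = "self",
               bw_kg = c(self1, self2), multiple_birth = rep(multiple_birth, 2L),
               stringsAsFactors = FALSE))
  offspring <- offspring[order(match(offspring$mother_id, mid),
                               offspring$source != "hospital"), ]
  rownames(offspring) <- NULL

  structure(list(
    persons = persons, variants = variants, geno = geno, paternal = paternal,
    calls = NULL,
    own_reports = own, offspring_reports = offspring,
    truth = data.frame(mother_id = mid, child_id = cid, sex = child_sex,
                       latent = latent, bw_kg = bw_kg,
                       multiple_birth = multiple_birth,
                       stringsAsFactors = FALSE),
    config = config), class = "duo_cohort")
}

#' Simulate read-level call data (DP, GQ, AD) with sequencing artifacts
#'
#' Fills per-call depth, genotype quality and allele depths for every
#' genotype in the cohort, and injects the artifact classes the QC module is
#' designed to catch: low-coverage calls, degraded genotype quality,
#' allele-imbalanced heterozygotes at flagged variants, and missing calls.
#'
#' Depth is Poisson with mean `dp_mean` (mean `low_dp_mean` for calls hit by
#' the `low_dp` artifact); heterozygote alternate allele depth is
#' Binomial(DP, 0.5), or Binomial(DP, `bias_p`) at variants flagged
#' allele-biased at rate `allele_bias`.
#'
#' @param cohort A `duo_cohort` from [simulate_duos()].
#' @param artifact_rates Overrides the rates stored in the cohort's config.
#' @param dp_mean,low_dp_mean Poisson means for normal and low-coverage calls.
#' @param dp_fixed If non-`NULL`, every call gets this exact depth (useful
#'   for calibration checks).
#' @param bias_p Heterozygote alternate-allele fraction at biased variants.
#' @param gq_range,low_gq_range Inclusive integer ranges for normal and
#'   degraded genotype qualities.
#' @return The cohort with a `calls` element: matrices `gt` (observed dosage
#'   with `NA` for missing), `dp`, `gq`, `ad_ref`, `ad_alt`, plus the
#'   per-variant `biased` flag on `variants`.
#' @export
simulate_reads <- function(cohort, artifact_rates = NULL,
                           dp_mean = 30, low_dp_mean = 4, dp_fixed = NULL,
                           bias_p = 0.2, gq_range = c(60L, 99L),
                           low_gq_range = c(0L, 19L)) {
  stopifnot(inherits(cohort, "duo_cohort"))
  ar <- if (is.null(artifact_rates)) cohort$config$artifact_rates else
    utils::modifyList(cohort$config$artifact_rates, as.list(artifact_rates))
  if (any(unlist(ar) < 0 | unlist(ar) > 1))
    stop("artifact rates must lie in [0, 1]", call. = FALSE)
  set.seed(cohort$config$seed + 1L)
  geno <- cohort$geno
  nv <- nrow(geno); ns <- ncol(geno)
  biased <- stats::rbinom(nv, 1L, ar$allele_bias) == 1L
  ncalls <- nv * ns
  if (is.null(dp_fixed)) {
    low <- stats::rbinom(ncalls, 1L, ar$low_dp) == 1L
    dp <- ifelse(low, stats::rpois(ncalls, low_dp_mean), stats::rpois(ncalls, dp_mean))
  } else dp <- rep(as.integer(dp_fixed), ncalls)
  dp <- matrix(as.integer(dp), nv, ns, dimnames = dimnames(geno))
  gq <- matrix(sample(gq_range[1]:gq_range[2], ncalls, replace = TRUE), nv, ns,
               dimnames = dimnames(geno))
  lowq <- matrix(stats::rbinom(ncalls, 1L, ar$low_gq) == 1L, nv, ns)
  if (any(lowq)) gq[lowq] <- sample(low_gq_range[1]:low_gq_range[2], sum(lowq),
                                    replace = TRUE)
  p_alt <- matrix(0, nv, ns)
  p_alt[geno == 1L] <- 0.5
  if (any(biased)) p_alt[biased & geno == 1L] <- bias_p
  p_alt[geno == 2L] <- 1
  ad_alt <- matrix(stats::rbinom(ncalls, as.vector(dp), as.vector(p_alt)),
                   nv, ns, dimnames = dimnames(geno))
  ad_alt[geno == 2L] <- dp[geno == 2L]
  ad_alt[geno == 0L] <- 0L
  ad_ref <- dp - ad_alt
  gt <- geno
  miss <- matrix(stats::rbinom(ncalls, 1L, ar$missing) == 1L, nv, ns)
  gt[miss] <- NA_integer_
  cohort$calls <- list(gt = gt, dp = dp, gq = gq,
                       ad_ref = ad_ref, ad_alt = ad_alt)
  cohort$variants$biased <- biased
  cohort
}

#' @exportS3Method base::print
print.duo_cohort <- function(x, ...) {
  n <- sum(x$persons$role == "child")
  cat(sprintf("duo_cohort: %d mother-child duos, %d variants in %d genes%s\n",
              n, nrow(x$variants), length(unique(x$variants$gene_id)),
              if (is.null(x$calls)) " (no read-level calls)" else ""))
  invisible(x)
}
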