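# Birth weight phenotype derivation and cleaning for the two analysis arms:
# the child's own reported birth weight (fetal arm) and the mother's report
# of her first child's birth weight (maternal arm), followed by
# standardisation to SD units within arm.

#' Phenotype derivation and exclusion rules
#'
#' Defaults reproduce the discovery derivation: multiple births excluded;
#' repeat reports differing by more than 1 kg (range of visit values,
#' strict `>`) excluded as discordant; averaged values below 1 kg or at/
#' above 7 kg excluded as extreme; hospital records preferred over
#' self-reports for offspring birth weight. The confirmatory team's `>= 1
#' kg` discordance reading is available via `discordance_strict = FALSE`.
#'
#' @param max_visit_discordance_kg Discordance cutoff on the range of
#'   repeat reports, default 1 kg.
#' @param min_bw_kg,max_bw_kg Extreme-value bounds: excluded when
#'   `value < min_bw_kg` or `value >= max_bw_kg`.
#' @param exclude_multiple_births Exclude flagged multiple births.
#' @param prefer_hospital Prefer hospital records for offspring weight.
#' @param discordance_strict Strict `>` (default) vs `>=` discordance.
#' @return An object of class `derivation_rules`.
#' @export
derivation_rules <- function(max_visit_discordance_kg = 1.0,
                             min_bw_kg = 1.0, max_bw_kg = 7.0,
                             exclude_multiple_births = TRUE,
                             prefer_hospital = TRUE,
                             discordance_strict = TRUE) {
  if (min_bw_kg >= max_bw_kg) stop("'min_bw_kg' must be below 'max_bw_kg'",
                                   call. = FALSE)
  if (max_visit_discordance_kg <= 0) stop("discordance cutoff must be positive",
                                          call. = FALSE)
  structure(list(max_visit_discordance_kg = max_visit_discordance_kg,
                 min_bw_kg = min_bw_kg, max_bw_kg = max_bw_kg,
                 exclude_multiple_births = exclude_multiple_births,
                 prefer_hospital = prefer_hospital,
                 discordance_strict = discordance_strict),
            class = "derivation_rules")
}

combine_reports <- function(values, multiple_birth, rules) {
  values <- values[is.finite(values)]
  if (!length(values)) return(list(value = NA_real_, reason = "invalid"))
  if (rules$exclude_multiple_births && isTRUE(multiple_birth))
    return(list(value = NA_real_, reason = "multiple_birth"))
  rng <- max(values) - min(values)
  disc <- if (rules$discordance_strict) rng > rules$max_visit_discordance_kg
          else rng >= rules$max_visit_discordance_kg
  if (disc) return(list(value = NA_real_, reason = "discordant"))
  m <- mean(values)
  if (m < rules$min_bw_kg || m >= rules$max_bw_kg)
    return(list(value = NA_real_, reason = "extreme"))
  list(value = m, reason = NA_character_)
}

#' Derive a person's own birth weight from repeat visit reports
#'
#' Averages the visit values unless the person is excluded: flagged
#' multiple birth, discordant repeat reports (range above the cutoff), or
#' an extreme averaged value (below 1 kg or at/above 7 kg).
#'
#' @param values Numeric vector of reported weights in kg (one per visit).
#' @param multiple_birth Multiple-birth flag for the person.
#' @param rules A [derivation_rules()].
#' @return List with `value` (kg, or `NA`) and `reason` (one of
#'   `"multiple_birth"`, `"discordant"`, `"extreme"`, `"invalid"`, or `NA`
#'   when retained).
#' @examples
#' derive_own_bw(c(3.2, 3.4))              # retained, 3.3 kg
#' derive_own_bw(c(2.0, 3.5))              # discordant
#' @export
derive_own_bw <- function(values, multiple_birth = FALSE,
                          rules = derivation_rules()) {
  combine_reports(as.numeric(values), multiple_birth, rules)
}

#' Derive offspring birth weight from a mother's records
#'
#' Hospital records are preferentially retained when present (for
#' accuracy); otherwise self-reports are averaged. The same discordance and
#' extreme-value rules as [derive_own_bw()] apply to whichever source is
#' used.
#'
#' @param records Data frame with columns `bw_kg` and `source`
#'   (`"hospital"` / `"self"`).
#' @param multiple_birth Multiple-birth flag for the offspring.
#' @param rules A [derivation_rules()].
#' @return As [derive_own_bw()].
#' @export
derive_offspring_bw <- function(records, multiple_birth = FALSE,
                                rules = derivation_rules()) {
  stopifnot(is.data.frame(records), all(c("bw_kg", "source") %in% names(records)))
  use <- records$bw_kg
  if (rules$prefer_hospital && any(records$source == "hospital"))
    use <- records$bw_kg[records$source == "hospital"]
  combine_reports(as.numeric(use), multiple_birth, rules)
}

#' Standardise a phenotype to SD units
#'
#' Z-scores (sample mean and SD), applied after all exclusions, within one
#' analysis arm with sexes combined. Idempotent up to floating point.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return Vector with mean 0 and SD 1.
#' @export
standardize_phenotype <- function(x) {
  x <- as.numeric(x)
  if (sum(is.finite(x)) < 2L) stop("need at least two values", call. = FALSE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero-variance phenotype", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Build the per-arm analysis table
#'
#' Derives and cleans the arm's phenotype, standardises it, and assembles
#' the covariates: the fetal arm uses the child's age, age^2, sex, PC1-PC10
#' and sequencing batch; the maternal arm uses the mother's age at first
#' birth (and its square), PC1-PC10 and batch, with no sex term. Covariates
#' are complete-case.
#'
#' @param cohort A `duo_cohort` (simulated or read from disk).
#' @param arm `"fetal"` or `"maternal"`.
#' @param rules A [derivation_rules()].
#' @return Data frame with `person_id`, `phenotype_sd`, covariate columns
#'   (and `sex` in the fetal arm), plus an `"exclusions"` attribute: a
#'   data.frame of exclusion counts by reason.
#' @export
analysis_table <- function(cohort, arm = c("fetal", "maternal"),
                           rules = derivation_rules()) {
  arm <- match.arg(arm)
  p <- cohort$persons
  if (arm == "fetal") {
    reports <- cohort$own_reports
    if (is.null(reports)) stop("cohort has no own-birth-weight reports",
                               call. = FALSE)
    ids <- unique(reports$person_id)
    fid <- factor(reports$person_id, levels = ids)
    vals <- split(reports$bw_kg, fid)
    mb <- vapply(split(reports$multiple_birth, fid), any, TRUE)
    derived <- mapply(function(v, m) derive_own_bw(v, m, rules),
                      vals, mb, SIMPLIFY = FALSE)
  } else {
    reports <- cohort$offspring_reports
    if (is.null(reports)) stop("cohort has no offspring-birth-weight records",
                               call. = FALSE)
    ids <- unique(reports$mother_id)
    fid <- factor(reports$mother_id, levels = ids)
    vals <- split(reports$bw_kg, fid)
    srcs <- split(reports$source, fid)
    mb <- vapply(split(reports$multiple_birth, fid), any, TRUE)
    derived <- mapply(function(v, s, m) {
      use <- if (rules$prefer_hospital && any(s == "hospital"))
        v[s == "hospital"] else v
      combine_reports(as.numeric(use), m, rules)
    }, vals, srcs, mb, SIMPLIFY = FALSE)
  }
  value <- vapply(derived, `[[`, 0, "value")
  reason <- vapply(derived, `[[`, "", "reason")
  excl <- table(reason[!is.na(reason)])
  keep <- is.na(reason)
  ids <- ids[keep]; value <- value[keep]

  rows <- p[match(ids, p$person_id), , drop = FALSE]
  if (arm == "fetal") {
    tab <- data.frame(person_id = ids, bw_kg = value,
                      age = rows$age, age2 = rows$age^2,
                      sex = rows$sex, batch = rows$batch,
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(person_id = ids, bw_kg = value,
                      age = rows$age_first_birth,
                      age2 = rows$age_first_birth^2,
                      batch = rows$batch, stringsAsFactors = FALSE)
  }
  tab <- cbind(tab, rows[, paste0("PC", 1:10), drop = FALSE])
  cc <- stats::complete.cases(tab)
  n_cc <- sum(!cc)
  tab <- tab[cc, , drop = FALSE]
  sd_kg <- stats::sd(tab$bw_kg)
  mean_kg <- mean(tab$bw_kg)
  tab$phenotype_sd <- standardize_phenotype(tab$bw_kg)
  tab$bw_kg <- NULL
  tab <- tab[, c("person_id", "phenotype_sd",
                 setdiff(names(tab), c("person_id", "phenotype_sd")))]
  rownames(tab) <- NULL
  excl_df <- data.frame(reason = c(names(excl),
                                   if (n_cc) "missing_covariates"),
                        n = c(as.integer(excl), if (n_cc) n_cc),
                        stringsAsFactors = FALSE)
  attr(tab, "exclusions") <- excl_df
  attr(tab, "arm") <- arm
  # kg-scale moments of the derived phenotype (one observed SD = sd_kg kg)
  attr(tab, "mean_kg") <- mean_kg
  attr(tab, "sd_kg") <- sd_kg
  tab
}
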