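# Readers and writers for the cohort's on-disk representation:
# VCF 4.2 with FORMAT GT:DP:GQ:AD, plus header-rowed TSVs for annotations,
# covariates and raw phenotype reports. Reading goes through vcfR; writing
# is plain line formatting so emitted fixtures stay text.

fmt_num <- function(x) {
  # full-precision decimal text so numeric TSV columns round-trip exactly
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

gt_string <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

#' Write a simulated cohort to VCF + TSV files
#'
#' Emits the genotype calls as a VCF 4.2 file (FORMAT `GT:DP:GQ:AD`, AD as
#' "ref,alt"; the simulation seed is recorded in a header comment), the
#' variant annotations, the per-person covariates, and the raw birth weight
#' reports for both arms. The files round-trip losslessly through
#' [read_cohort()].
#'
#' @param cohort A `duo_cohort` with read-level calls (see [simulate_reads()];
#'   without calls a GT-only VCF is written from the true genotypes).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written
#'   (`vcf`, `annotations`, `covariates`, `own_bw`, `offspring_bw`).
#' @export
emit_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "duo_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                annotations = file.path(dir, "annotations.tsv"),
                covariates = file.path(dir, "covariates.tsv"),
                own_bw = file.path(dir, "own_bw.tsv"),
                offspring_bw = file.path(dir, "offspring_bw.tsv"))

  v <- cohort$variants
  samp <- colnames(cohort$geno)
  has_reads <- !is.null(cohort$calls)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##simulation_seed=%d", cohort$config$seed),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (has_reads) header <- c(header,
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">")
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samp), collapse = "\t"))
  lines <- character(nrow(v))
  for (j in seq_len(nrow(v))) {
    if (has_reads) {
      calls <- paste(gt_string(cohort$calls$gt[j, ]), cohort$calls$dp[j, ],
                     cohort$calls$gq[j, ],
                     paste0(cohort$calls$ad_ref[j, ], ",", cohort$calls$ad_alt[j, ]),
                     sep = ":")
      fmt <- "GT:DP:GQ:AD"
    } else {
      calls <- gt_string(cohort$geno[j, ])
      fmt <- "GT"
    }
    lines[j] <- paste(c(v$chrom[j], v$pos[j], v$variant_key[j], v$ref[j],
                        v$alt[j], ".", "PASS", ".", fmt, calls), collapse = "\t")
  }
  writeLines(c(header, lines), paths$vcf)

  # the simulated population frequency doubles as an external MAF reference
  if (is.null(v$maf_external) && !is.null(v$af)) v$maf_external <- v$af
  ann_cols <- intersect(c("variant_key", "gene_id", "consequence", "loftee",
                          "cadd", "biased", "aascore", "pathogenic_flag",
                          "maf_external"), names(v))
  write_tsv(v[, ann_cols, drop = FALSE], paths$annotations,
            num_cols = intersect(c("cadd", "aascore", "maf_external"), ann_cols))

  p <- cohort$persons
  write_tsv(p, paths$covariates, num_cols = paste0("PC", 1:10))
  write_tsv(cohort$own_reports, paths$own_bw, num_cols = "bw_kg")
  write_tsv(cohort$offspring_reports, paths$offspring_bw, num_cols = "bw_kg")
  invisible(paths)
}

write_tsv <- function(df, path, num_cols = character()) {
  out <- df
  for (cc in num_cols) out[[cc]] <- fmt_num(df[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a VCF file into genotype call matrices
#'
#' Parses a biallelic VCF 4.2 file via the vcfR package. `GT` is required;
#' `DP`, `GQ` and `AD` are optional (QC rules that need an absent field are
#' skipped downstream with a warning). `./.` genotypes are parsed as
#' missing; 1-based positions and sample order are preserved.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @return List with `variants` (chrom, pos, ref, alt, vclass, variant_key),
#'   `calls` (matrices `gt`, and `dp`/`gq`/`ad_ref`/`ad_alt` when present),
#'   `samples`, and `seed` (the recorded simulation seed, or `NA`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic record(s) at ",
         paste(utils::head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 3),
               collapse = ", "),
         "; split and left-normalise upstream", call. = FALSE)
  }
  samples <- colnames(vcf@gt)[-1L]
  if (anyDuplicated(samples)) stop("duplicated sample IDs in VCF", call. = FALSE)
  ref <- fix[, "REF"]
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt,
    vclass = ifelse(nchar(ref) != nchar(alt), "indel", "SNV"),
    variant_key = paste(fix[, "CHROM"], fix[, "POS"], ref, alt, sep = ":"),
    stringsAsFactors = FALSE)
  rownames(variants) <- variants$variant_key

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  parse_gt <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
  }
  gt <- matrix(parse_gt(gt_raw), nrow(variants), length(samples),
               dimnames = list(variants$variant_key, samples))
  calls <- list(gt = gt)
  fmt_fields <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DP" %in% fmt_fields)
    calls$dp <- matrix(as.integer(vcfR::extract.gt(vcf, "DP")),
                       nrow(variants), length(samples),
                       dimnames = dimnames(gt))
  if ("GQ" %in% fmt_fields)
    calls$gq <- matrix(as.integer(vcfR::extract.gt(vcf, "GQ")),
                       nrow(variants), length(samples),
                       dimnames = dimnames(gt))
  if ("AD" %in% fmt_fields) {
    ad <- vcfR::extract.gt(vcf, "AD")
    calls$ad_ref <- matrix(as.integer(sub(",.*$", "", ad)),
                           nrow(variants), length(samples), dimnames = dimnames(gt))
    calls$ad_alt <- matrix(as.integer(sub("^[^,]*,", "", ad)),
                           nrow(variants), length(samples), dimnames = dimnames(gt))
  }
  meta <- vcf@meta
  seed_line <- grep("^##simulation_seed=", meta, value = TRUE)
  seed <- if (length(seed_line)) as.integer(sub("^##simulation_seed=", "", seed_line[1]))
          else NA_integer_
  list(variants = variants, calls = calls, samples = samples, seed = seed)
}

#' Read an emitted cohort back from disk
#'
#' Inverse of [emit_cohort()]: reconstructs a `duo_cohort`-shaped object
#' (persons, annotated variants, call matrices, raw reports) from the files
#' in `dir` or from explicitly named paths.
#'
#' @param dir Directory written by [emit_cohort()], or `NULL` when paths are
#'   given individually.
#' @param vcf,annotations,covariates,own_bw,offspring_bw Individual file
#'   paths (override the defaults derived from `dir`). `own_bw`,
#'   `offspring_bw` and `annotations` may be `NULL`/missing files, in which
#'   case the corresponding element is `NULL`.
#' @return An object of class `duo_cohort` (without simulation truth).
#' @export
read_cohort <- function(dir = NULL,
                        vcf = file.path(dir, "cohort.vcf"),
                        annotations = file.path(dir, "annotations.tsv"),
                        covariates = file.path(dir, "covariates.tsv"),
                        own_bw = file.path(dir, "own_bw.tsv"),
                        offspring_bw = file.path(dir, "offspring_bw.tsv")) {
  vv <- read_vcf(vcf)
  variants <- vv$variants
  if (!is.null(annotations) && file.exists(annotations)) {
    ann <- read_tsv(annotations)
    if (!all(variants$variant_key %in% ann$variant_key))
      stop("annotation table does not cover every VCF variant", call. = FALSE)
    ann <- ann[match(variants$variant_key, ann$variant_key), , drop = FALSE]
    extra <- setdiff(names(ann), names(variants))
    variants <- cbind(variants, ann[, extra, drop = FALSE])
    rownames(variants) <- variants$variant_key
  }
  persons <- NULL
  if (!is.null(covariates) && file.exists(covariates)) {
    persons <- read_tsv(covariates)
    persons$person_id <- as.character(persons$person_id)
    persons$mother_id <- as.character(persons$mother_id)
    rownames(persons) <- persons$person_id
    kids <- persons[persons$role == "child", ]
    if (nrow(kids) && !all(kids$mother_id %in% persons$person_id))
      stop("every child must have its mother present in the covariate table",
           call. = FALSE)
  }
  own <- if (!is.null(own_bw) && file.exists(own_bw)) {
    x <- read_tsv(own_bw); x$person_id <- as.character(x$person_id); x
  }
  off <- if (!is.null(offspring_bw) && file.exists(offspring_bw)) {
    x <- read_tsv(offspring_bw); x$mother_id <- as.character(x$mother_id); x
  }
  structure(list(persons = persons, variants = variants, geno = vv$calls$gt,
                 paternal = NULL, calls = vv$calls,
                 own_reports = own, offspring_reports = off,
                 truth = NULL,
                 config = list(seed = vv$seed)),
            class = "duo_cohort")
}
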