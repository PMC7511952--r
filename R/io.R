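# Readers/writers for the plain-text interchange formats used throughout:
# sample sheets, probe x sample beta matrices with probe annotation,
# gene x sample expression matrices, variant tables and paired marker levels.
# All tabular IO is TSV (CSV selectable for sample sheets); matrices carry the
# id column first.

SAMPLE_SHEET_COLS <- c("sample_id", "cohort_set", "pcr", "er_status", "age")
COHORT_SETS  <- c("screening", "validation", "revalidation")
ER_LEVELS    <- c("positive", "negative", "unknown")
TIMEPOINTS   <- c("baseline", "on_treatment")
REGION_CLASSES <- c("cpg_island", "genic", "intergenic")
ANNOTATION_COLS <- c("probe_id", "chrom", "pos", "gene", "region_class", "region_id")
VARIANT_COLS <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                  "tumor_vaf", "normal_vaf", "homopolymer_len",
                  "fwd_alt", "rev_alt", "coverage", "consequence")
CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice",
                  "synonymous", "noncoding")

read_table_dialect <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  utils::read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_stage("io", sprintf("%s is missing required column(s): %s",
                              what, paste(missing, collapse = ", ")))
  }
}

#' Read and validate a sample sheet
#'
#' A sample sheet carries one row per patient sample: `sample_id`,
#' `cohort_set` (screening/validation/revalidation), `pcr` (pathological
#' complete response, the binary outcome), `er_status`
#' (positive/negative/unknown; blank is read as unknown), `age` in years, and
#' an optional `timepoint` (baseline/on_treatment, default baseline).
#' Columns beyond these are preserved untouched.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a `data.frame` with validated typed columns, rows in file order.
#' @export
read_sample_sheet <- function(path, dialect = c("tsv", "csv")) {
  df <- read_table_dialect(path, match.arg(dialect))
  require_columns(df, SAMPLE_SHEET_COLS, "sample sheet")
  validate_sample_sheet(as_sample_sheet(df))
}

# coerce raw character columns to the typed contract
as_sample_sheet <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  df$cohort_set <- as.character(df$cohort_set)
  if (!is.logical(df$pcr)) {
    df$pcr <- tolower(as.character(df$pcr)) %in% c("true", "t", "1", "yes", "pcr")
  }
  df$er_status <- as.character(df$er_status)
  df$er_status[is.na(df$er_status) | df$er_status == ""] <- "unknown"
  df$age <- as.integer(df$age)
  if (is.null(df$timepoint)) df$timepoint <- "baseline"
  df$timepoint <- as.character(df$timepoint)
  df$timepoint[is.na(df$timepoint) | df$timepoint == ""] <- "baseline"
  df
}

validate_sample_sheet <- function(df) {
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    abort_stage("io", "duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_set <- setdiff(unique(df$cohort_set), COHORT_SETS)
  if (length(bad_set) > 0) {
    abort_stage("io", "unknown cohort_set value(s): ", paste(bad_set, collapse = ", "))
  }
  bad_er <- setdiff(unique(df$er_status), ER_LEVELS)
  if (length(bad_er) > 0) {
    abort_stage("io", "unknown er_status value(s): ", paste(bad_er, collapse = ", "))
  }
  bad_tp <- setdiff(unique(df$timepoint), TIMEPOINTS)
  if (length(bad_tp) > 0) {
    abort_stage("io", "unknown timepoint value(s): ", paste(bad_tp, collapse = ", "))
  }
  if (any(is.na(df$age)) || any(df$age < 0)) {
    abort_stage("io", "age must be a non-negative integer for every sample")
  }
  if (any(is.na(df$pcr[df$timepoint == "baseline"]))) {
    abort_stage("io", "pcr outcome must be defined for every baseline sample")
  }
  df
}

#' Write a sample sheet
#' @param df a sample-sheet `data.frame`.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(df, path, dialect = c("tsv", "csv")) {
  sep <- if (match.arg(dialect) == "csv") "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a beta-value matrix
#'
#' A beta matrix is a numeric probes-by-samples matrix of Infinium-style
#' beta values (methylation fraction, 0 = unmethylated, 1 = methylated) with
#' probe ids as rownames and sample ids as colnames. Missing or out-of-range
#' entries are rejected with their coordinates.
#'
#' @param beta numeric matrix.
#' @return `beta`, invisibly, if valid.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort_stage("io", "beta matrix must be a numeric matrix")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort_stage("io", "beta matrix must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) {
    abort_stage("io", "duplicate probe ids in beta matrix")
  }
  bad <- which(!is.finite(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    coords <- apply(utils::head(bad, 5), 1, function(ij) {
      paste0(rownames(beta)[ij[1]], ",", colnames(beta)[ij[2]])
    })
    abort_stage("io", "beta values outside [0,1] or non-numeric at: ",
                paste(coords, collapse = "; "))
  }
  invisible(beta)
}

validate_annotation <- function(annotation) {
  require_columns(annotation, ANNOTATION_COLS, "probe annotation")
  # an absent gene is the empty string, not NA (blank cells read as NA)
  annotation$gene[is.na(annotation$gene)] <- ""
  key <- paste(annotation$chrom, annotation$pos)
  if (anyDuplicated(key)) {
    abort_stage("io", "duplicate (chrom, pos) in probe annotation")
  }
  bad_class <- setdiff(unique(annotation$region_class), REGION_CLASSES)
  if (length(bad_class) > 0) {
    abort_stage("io", "unknown region_class value(s): ",
                paste(bad_class, collapse = ", "))
  }
  chr_per_region <- tapply(annotation$chrom, annotation$region_id,
                           function(x) length(unique(x)))
  if (any(chr_per_region > 1)) {
    abort_stage("io", "probes sharing a region_id must share a chromosome: ",
                paste(names(chr_per_region)[chr_per_region > 1], collapse = ", "))
  }
  annotation
}

#' Read a beta matrix and its probe annotation
#'
#' The matrix TSV has `probe_id` as first column and one column per sample;
#' the annotation TSV has columns `probe_id`, `chrom`, `pos` (1-based),
#' `gene`, `region_class` (cpg_island/genic/intergenic) and `region_id` (the
#' grouping key for consecutive-probe aggregation). Every probe in the matrix
#' must be annotated; the two are returned aligned by probe id.
#'
#' @param path beta-matrix TSV path.
#' @param annotation_path probe-annotation TSV path.
#' @return a list with elements `beta` (validated matrix) and `annotation`
#'   (`data.frame` in matrix probe order).
#' @export
read_beta_matrix <- function(path, annotation_path) {
  df <- read_table_dialect(path, "tsv")
  require_columns(df, "probe_id", "beta matrix")
  beta <- as.matrix(df[, setdiff(names(df), "probe_id"), drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- as.character(df$probe_id)
  validate_beta_matrix(beta)
  annotation <- validate_annotation(read_table_dialect(annotation_path, "tsv"))
  missing <- setdiff(rownames(beta), annotation$probe_id)
  if (length(missing) > 0) {
    abort_stage("io", "probes missing annotation: ",
                paste(utils::head(missing, 10), collapse = ", "))
  }
  annotation <- annotation[match(rownames(beta), annotation$probe_id), ]
  rownames(annotation) <- NULL
  list(beta = beta, annotation = annotation)
}

write_id_matrix <- function(mat, path, id_col) {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a beta matrix (and optionally its annotation) as TSV
#' @param beta validated beta matrix.
#' @param path output TSV path.
#' @param annotation optional annotation `data.frame`.
#' @param annotation_path path for the annotation TSV (required when
#'   `annotation` is given).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, annotation = NULL,
                              annotation_path = NULL) {
  write_id_matrix(beta, path, "probe_id")
  if (!is.null(annotation)) {
    stopifnot(!is.null(annotation_path))
    utils::write.table(annotation, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#' @param path TSV with `gene_id` first column, one column per sample.
#' @return numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  df <- read_table_dialect(path, "tsv")
  require_columns(df, "gene_id", "expression matrix")
  mat <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df$gene_id)
  if (any(!is.finite(mat))) {
    abort_stage("io", "expression matrix contains non-finite values")
  }
  mat
}

#' Write a gene-by-sample expression matrix as TSV
#' @param mat numeric matrix with gene rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) write_id_matrix(mat, path, "gene_id")

#' Read a variant table
#'
#' One row per tumor/normal variant observation with the fields the six
#' filter rules test: allele frequencies in tumor and matched normal,
#' homopolymer context length, per-strand alternate-read support, total
#' coverage and functional consequence.
#'
#' @param path TSV path with columns
#'   `sample_id, gene, chrom, pos, ref, alt, tumor_vaf, normal_vaf,
#'   homopolymer_len, fwd_alt, rev_alt, coverage, consequence`.
#' @return validated `data.frame`.
#' @export
read_variant_table <- function(path) {
  df <- read_table_dialect(path, "tsv")
  require_columns(df, VARIANT_COLS, "variant table")
  validate_variant_table(df)
}

validate_variant_table <- function(df) {
  assert_fraction(df$tumor_vaf, "tumor_vaf", "io")
  assert_fraction(df$normal_vaf, "normal_vaf", "io")
  if (any(df$fwd_alt < 0) || any(df$rev_alt < 0) || any(df$coverage < 0)) {
    abort_stage("io", "read counts must be non-negative")
  }
  if (any(df$coverage < df$fwd_alt + df$rev_alt)) {
    abort_stage("io", "coverage must be >= fwd_alt + rev_alt")
  }
  bad <- setdiff(unique(df$consequence), CONSEQUENCES)
  if (length(bad) > 0) {
    abort_stage("io", "unknown consequence value(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Read paired baseline/on-treatment marker levels
#' @param path TSV with columns `sample_id, baseline, on_treatment, pcr`.
#' @return validated `data.frame`.
#' @export
read_paired_levels <- function(path) {
  df <- read_table_dialect(path, "tsv")
  require_columns(df, c("sample_id", "baseline", "on_treatment", "pcr"),
                  "paired marker levels")
  assert_fraction(df$baseline, "baseline", "io")
  assert_fraction(df$on_treatment, "on_treatment", "io")
  if (!is.logical(df$pcr)) {
    df$pcr <- tolower(as.character(df$pcr)) %in% c("true", "t", "1", "yes")
  }
  df
}
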