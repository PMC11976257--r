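ANNOT_LEVELS <- list(
  diagnosis = c("FL", "DLBCL", "FL-DLBCL", "other"),
  coo = c("GCB", "ABC", "unclassified", "n.a."),
  bcl2_rearranged = c("yes", "no", "unknown"),
  bcl6_rearranged = c("yes", "no", "unknown")
)
ANNOT_UNKNOWN <- c(
  diagnosis = "other", coo = "n.a.",
  bcl2_rearranged = "unknown", bcl6_rearranged = "unknown"
)

#' Read, write and validate sample annotation tables
#'
#' An annotation table is a delimited text file with one row per sample and a
#' required `sample_id` column. Recognised columns are `diagnosis` (FL, DLBCL,
#' FL-DLBCL, other), `coo` (GCB, ABC, unclassified, n.a.), `age` (years),
#' `bcl2_rearranged`/`bcl6_rearranged` (yes, no, unknown), `tcc` (tumor-cell
#' content fraction in `[0, 1]`) and `mutational_cluster`; arbitrary extra
#' columns pass through untouched. Unrecognised values of a declared
#' categorical column are mapped to its unknown level with a warning.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A tibble with factor columns for the declared categoricals.
#' @export
read_annotation <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  df <- reader(path, na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  validate_annotation(as_tibble(df))
}

#' @rdname read_annotation
#' @param annotation An annotation tibble.
#' @export
write_annotation <- function(annotation, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  df <- dplyr::mutate(annotation, dplyr::across(dplyr::where(is.factor), as.character))
  writer(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

validate_annotation <- function(annotation) {
  if (!"sample_id" %in% names(annotation)) {
    abort("annotation must contain a `sample_id` column.")
  }
  annotation$sample_id <- as.character(annotation$sample_id)
  if (anyDuplicated(annotation$sample_id)) abort("duplicate sample identifiers in annotation.")
  for (col in intersect(names(ANNOT_LEVELS), names(annotation))) {
    lv <- ANNOT_LEVELS[[col]]
    x <- as.character(annotation[[col]])
    bad <- !is.na(x) & !x %in% lv
    if (any(bad)) {
      warn(sprintf(
        "%d value(s) of `%s` outside declared levels mapped to '%s' (e.g. '%s').",
        sum(bad), col, ANNOT_UNKNOWN[[col]], x[bad][1]
      ))
      x[bad] <- ANNOT_UNKNOWN[[col]]
    }
    x[is.na(x)] <- ANNOT_UNKNOWN[[col]]
    annotation[[col]] <- factor(x, levels = lv)
  }
  if ("tcc" %in% names(annotation)) {
    tcc <- annotation$tcc
    if (any(!is.na(tcc) & (tcc < 0 | tcc > 1))) {
      abort("`tcc` must lie in [0, 1].")
    }
  }
  if ("age" %in% names(annotation) && any(!is.na(annotation$age) & annotation$age < 0)) {
    abort("`age` must be nonnegative.")
  }
  annotation
}

#' Align a beta matrix and an annotation table on shared samples
#'
#' Restricts both to the intersection of sample identifiers, in the matrix's
#' column order, and reports how many samples were dropped from each side.
#'
#' @param beta A beta tibble or CpG x sample matrix.
#' @param annotation An annotation tibble with a `sample_id` column.
#' @return A list with elements `beta` (beta tibble) and `annotation`
#'   (tibble), both restricted to the shared samples.
#' @export
align_cohort <- function(beta, annotation) {
  m <- as_beta_matrix(beta)
  annotation <- validate_annotation(annotation)
  keep <- intersect(colnames(m), annotation$sample_id)
  if (length(keep) == 0) abort("no samples shared between beta matrix and annotation.")
  dropped <- (ncol(m) - length(keep)) + (nrow(annotation) - length(keep))
  if (dropped > 0) {
    inform(sprintf("align_cohort: dropped %d matrix and %d annotation sample(s).",
                   ncol(m) - length(keep), nrow(annotation) - length(keep)))
  }
  list(
    beta = as_beta_tbl(m[, keep, drop = FALSE]),
    annotation = annotation[match(keep, annotation$sample_id), , drop = FALSE]
  )
}
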