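#' Beta-value matrices as tibbles
#'
#' Throughout the package a cohort's methylation data is a "beta tibble": a
#' tibble whose first column `cpg_id` holds unique probe identifiers and whose
#' remaining columns are one numeric column per sample, values in `[0, 1]`
#' (missing entries allowed). These helpers convert between that tibble form
#' and a plain numeric matrix (CpGs x samples) used internally.
#'
#' @param beta A beta tibble (`cpg_id` + one numeric column per sample).
#' @return `as_beta_matrix()`: a numeric matrix with CpG rownames and sample
#'   colnames. `as_beta_tbl()`: a beta tibble.
#' @name beta_matrix
NULL

#' @rdname beta_matrix
#' @export
as_beta_matrix <- function(beta) {
  if (is.matrix(beta)) {
    validate_beta(beta)
    return(beta)
  }
  if (!is.data.frame(beta) || !"cpg_id" %in% names(beta)) {
    abort("`beta` must be a beta tibble with a `cpg_id` column, or a matrix.")
  }
  m <- as.matrix(beta[setdiff(names(beta), "cpg_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(beta$cpg_id)
  validate_beta(m)
  m
}

#' @rdname beta_matrix
#' @param m A numeric CpG x sample matrix with dimnames.
#' @export
as_beta_tbl <- function(m) {
  validate_beta(m)
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(cpg_id = rownames(m)), out)
}

validate_beta <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("beta matrix must carry CpG rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate CpG (probe) identifiers.")
  if (anyDuplicated(colnames(m))) abort("duplicate sample identifiers.")
  v <- m[!is.na(m)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "beta value outside [0, 1] at CpG '%s', sample '%s'.",
      rownames(m)[bad[1]], colnames(m)[bad[2]]
    ))
  }
  invisible(m)
}

#' Read and write beta-value matrices
#'
#' The on-disk format is a delimited text file whose header row holds sample
#' identifiers, whose first column holds probe identifiers, and whose cells
#' are beta values in `[0, 1]`; empty cells or `NA` mark missing values.
#' Row and column order is preserved.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A beta tibble (see [as_beta_matrix()]).
#' @export
read_beta_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  df <- suppressWarnings(reader(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  ))
  if (nrow(df) == 0 || ncol(df) < 2) abort("empty or headerless beta matrix file.")
  names(df)[1] <- "cpg_id"
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-numeric beta value at CpG '%s', sample '%s'.",
      df$cpg_id[bad[1, 1]], colnames(vals)[bad[1, 2]]
    ))
  }
  rownames(num) <- df$cpg_id
  colnames(num) <- colnames(vals)
  as_beta_tbl(num)
}

#' @rdname read_beta_matrix
#' @param beta A beta tibble or CpG x sample matrix.
#' @param digits Decimal digits written (default 6).
#' @export
write_beta_matrix <- function(beta, path, dialect = c("tsv", "csv"), digits = 6) {
  dialect <- match.arg(dialect)
  m <- as_beta_matrix(beta)
  df <- as.data.frame(round(m, digits), check.names = FALSE)
  df <- cbind(cpg_id = rownames(m), df)
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

# Mean-impute missing betas per CpG; drop CpGs with more than `max_missing`
# missing fraction (complete-data stages need this: SD ranking, k-means, NMF).
impute_beta <- function(m, max_missing = 0.2) {
  miss <- rowMeans(is.na(m))
  drop <- miss > max_missing
  if (any(drop)) {
    inform(sprintf("dropped %d CpGs with > %.0f%% missing betas.",
                   sum(drop), 100 * max_missing))
    m <- m[!drop, , drop = FALSE]
  }
  if (anyNA(m)) {
    rm_ <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- rm_[idx[, 1]]
  }
  m
}
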