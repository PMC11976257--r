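#' Organize significant CpGs into modules and samples into patterns
#'
#' `assign_modules()` k-means-clusters the significant CpGs' beta profiles
#' into `k_mod` CpG modules, relabeled `M1..Mk` by ascending module median
#' beta (M1 least methylated). `assign_patterns()` k-means-clusters all
#' cohort samples' profiles over the significant CpGs into `k_pat`
#' methylation patterns, relabeled `MP1..MPk` by ascending pattern median
#' beta. The defaults `k_mod = 4`, `k_pat = 7` mirror the published modules
#' M1-M4 and patterns MP1-MP7; no automatic k selection is performed.
#'
#' @param beta A beta tibble or matrix restricted to the significant CpGs
#'   (all cohort samples as columns).
#' @param k_mod,k_pat Number of modules / patterns.
#' @param seed Integer seed.
#' @param n_init k-means restarts (default 10).
#' @return A tibble: `assign_modules()` has columns `cpg_id`, `module` and
#'   attribute `module_median` (named vector); `assign_patterns()` has
#'   `sample_id`, `pattern` and attribute `pattern_median`. Both carry an
#'   `inertia` attribute.
#' @export
assign_modules <- function(beta, k_mod = 4, seed = 1L, n_init = 10) {
  m <- impute_beta(as_beta_matrix(beta))
  if (k_mod < 1) abort("`k_mod` must be at least 1.")
  if (k_mod > nrow(m)) abort("`k_mod` cannot exceed the number of CpGs.")
  km <- run_kmeans(m, k_mod, seed, n_init)
  med <- vapply(seq_len(k_mod), function(c) {
    stats::median(m[km$cluster == c, , drop = FALSE])
  }, numeric(1))
  relabel <- match(seq_len(k_mod), order(med))
  labels <- factor(paste0("M", relabel[km$cluster]),
                   levels = paste0("M", seq_len(k_mod)))
  out <- tibble(cpg_id = rownames(m), module = labels)
  structure(out,
    class = c("module_assignment", class(out)),
    module_median = stats::setNames(sort(med), paste0("M", seq_len(k_mod))),
    inertia = km$tot.withinss, seed = as.integer(seed)
  )
}

#' @rdname assign_modules
#' @export
assign_patterns <- function(beta, k_pat = 7, seed = 1L, n_init = 10) {
  m <- impute_beta(as_beta_matrix(beta))
  if (k_pat < 1) abort("`k_pat` must be at least 1.")
  if (k_pat > ncol(m)) abort("`k_pat` cannot exceed the number of samples.")
  x <- t(m)
  km <- run_kmeans(x, k_pat, seed, n_init)
  med <- vapply(seq_len(k_pat), function(c) {
    stats::median(m[, km$cluster == c, drop = FALSE])
  }, numeric(1))
  relabel <- match(seq_len(k_pat), order(med))
  labels <- factor(paste0("MP", relabel[km$cluster]),
                   levels = paste0("MP", seq_len(k_pat)))
  out <- tibble(sample_id = colnames(m), pattern = labels)
  structure(out,
    class = c("pattern_assignment", class(out)),
    pattern_median = stats::setNames(sort(med), paste0("MP", seq_len(k_pat))),
    inertia = km$tot.withinss, seed = as.integer(seed)
  )
}

#' Cross-tabulate methylation patterns against an annotation field
#'
#' Counts samples per (pattern, level) pair, including the unknown level as
#' its own column; row sums equal pattern sizes.
#'
#' @param patterns Output of [assign_patterns()].
#' @param annotation Annotation tibble with `sample_id`.
#' @param field Name of the annotation column to tabulate.
#' @return A tibble, one row per pattern, columns `pattern`, one per level,
#'   and `n` (pattern size).
#' @export
pattern_composition <- function(patterns, annotation, field) {
  if (!field %in% names(annotation)) {
    abort(sprintf("annotation has no column `%s`.", field))
  }
  joined <- dplyr::inner_join(
    tibble(sample_id = patterns$sample_id, pattern = patterns$pattern),
    annotation[c("sample_id", field)], by = "sample_id"
  )
  x <- joined[[field]]
  if (!is.factor(x)) x <- factor(ifelse(is.na(as.character(x)), "unknown", as.character(x)))
  tab <- table(pattern = joined$pattern, level = x)
  out <- as_tibble(as.data.frame.matrix(tab), rownames = "pattern")
  dplyr::mutate(out, n = as.integer(rowSums(tab)))
}

#' Advisory silhouette report for a clustering
#'
#' Mean silhouette width per candidate k, computed on Euclidean distances.
#' Advisory only: the pipeline's `k_mod`/`k_pat` are configuration, not
#' selected automatically.
#'
#' @param beta Beta tibble or matrix; rows are clustered.
#' @param ks Candidate cluster counts.
#' @param seed,n_init Passed to the k-means runs.
#' @return Tibble with `k` and `mean_silhouette`.
#' @export
silhouette_report <- function(beta, ks = 2:8, seed = 1L, n_init = 5) {
  m <- impute_beta(as_beta_matrix(beta))
  d <- as.matrix(stats::dist(m))
  purrr::map_dfr(ks[ks < nrow(m)], function(k) {
    cl <- run_kmeans(m, k, derive_seed(seed, paste0("sil", k)), n_init)$cluster
    s <- vapply(seq_len(nrow(m)), function(i) {
      a <- mean(d[i, cl == cl[i] & seq_len(nrow(m)) != i])
      if (is.nan(a)) return(0)
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(c2) mean(d[i, cl == c2]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    tibble(k = k, mean_silhouette = mean(s))
  })
}
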