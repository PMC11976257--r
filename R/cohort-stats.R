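#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Two-sided rank-sum test for every unordered pair of groups. The exact null
#' distribution is enumerated when both groups have at most 10 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used. The Bonferroni family is the set of pairs
#' actually tested.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measurement and the
#'   group label.
#' @param adjust Apply Bonferroni adjustment (default `TRUE`).
#' @return A tibble with one row per pair: `group_a`, `group_b`, `statistic`
#'   (rank-sum W), `p_raw`, `p_adjusted`, `m`, `method`.
#' @export
#' @examples
#' df <- data.frame(x = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
#' pairwise_wilcoxon(df, x, g)
pairwise_wilcoxon <- function(data, value, group, adjust = TRUE) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(sprintf("skipping group(s) with < 2 observations: %s",
                 paste(small, collapse = ", ")))
    keep <- !g %in% small
    v <- v[keep]; g <- g[keep]
  }
  groups <- sort(unique(g))
  if (length(groups) < 2) abort("need at least 2 groups with >= 2 observations.")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  m <- length(pairs)
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- v[g == pr[1]]; b <- v[g == pr[2]]
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- length(a) <= 10 && length(b) <= 10 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    )
    # all observations tied across both groups: no evidence either way
    p <- if (is.na(wt$p.value)) 1 else wt$p.value
    tibble(
      group_a = pr[1], group_b = pr[2],
      statistic = unname(wt$statistic),
      p_raw = p, m = m,
      method = if (exact) "wilcoxon_exact" else "wilcoxon_normal"
    )
  })
  out$p_adjusted <- if (adjust) bonferroni_adjust(out$p_raw, m) else out$p_raw
  dplyr::relocate(out, "p_adjusted", .after = "p_raw")
}

#' Fisher exact enrichment with Haldane-Anscombe odds ratio
#'
#' Two-sided Fisher exact test (sum of hypergeometric probabilities no larger
#' than the observed table's) on a 2x2 count table, with the sample odds
#' ratio `(a d) / (b c)`. When `haldane = TRUE` and any cell is zero, 0.5 is
#' added to every cell before computing the odds ratio and its 95% Wald
#' confidence interval on the log scale.
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @param haldane Apply the Haldane-Anscombe correction when a cell is zero
#'   (default `TRUE`).
#' @return A one-row tibble: `odds_ratio`, `ci_low`, `ci_high`, `p_raw`,
#'   `method`.
#' @export
#' @examples
#' fisher_enrichment(matrix(c(10, 0, 0, 10), 2))
fisher_enrichment <- function(table, haldane = TRUE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) abort("`table` must be 2x2.")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be nonnegative integers.")
  }
  p <- min(1, stats::fisher.test(tab)$p.value)  # guard fp overshoot above 1
  ct <- tab
  if (haldane && any(tab == 0)) ct <- tab + 0.5
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  se <- sqrt(sum(1 / ct))
  ci <- if (is.finite(or) && or > 0) exp(log(or) + c(-1, 1) * 1.96 * se) else c(NA_real_, NA_real_)
  tibble(
    odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
    p_raw = p, method = "fisher_exact"
  )
}

#' epiCMIT mitotic-clock score
#'
#' The epiCMIT proliferation-history score of a sample is the maximum of a
#' hypermethylation component (mean beta over a hyper CpG list) and a
#' hypomethylation component (mean of `1 - beta` over a hypo CpG list). CpGs
#' absent from the data are dropped with a warning; if one list is entirely
#' absent, the score is the remaining component.
#'
#' @param beta Beta tibble or matrix (CpGs x samples).
#' @param hyper_list,hypo_list Character vectors of CpG identifiers. The
#'   published lists are user-supplied; [synthetic_epicmit_lists()] generates
#'   planted-truth lists for testing.
#' @return Tibble with `sample_id`, `hyper_component`, `hypo_component`,
#'   `score` (each in `[0, 1]`; absent components are `NA`).
#' @export
epicmit_score <- function(beta, hyper_list, hypo_list) {
  m <- as_beta_matrix(beta)
  hyper <- intersect(hyper_list, rownames(m))
  hypo <- intersect(hypo_list, rownames(m))
  n_missing <- (length(hyper_list) - length(hyper)) + (length(hypo_list) - length(hypo))
  if (n_missing > 0) {
    warn(sprintf("%d epiCMIT CpG(s) absent from the matrix were dropped.", n_missing))
  }
  if (length(hyper) == 0 && length(hypo) == 0) {
    abort("both epiCMIT CpG lists are entirely absent from the matrix.")
  }
  hyper_c <- if (length(hyper)) colMeans(m[hyper, , drop = FALSE], na.rm = TRUE) else rep(NA_real_, ncol(m))
  hypo_c <- if (length(hypo)) colMeans(1 - m[hypo, , drop = FALSE], na.rm = TRUE) else rep(NA_real_, ncol(m))
  tibble(
    sample_id = colnames(m),
    hyper_component = unname(hyper_c),
    hypo_component = unname(hypo_c),
    score = unname(pmax(hyper_c, hypo_c, na.rm = TRUE))
  )
}

#' Per-group methylation summary over a CpG subset
#'
#' For each group: the median, minimum and maximum of the per-sample median
#' beta over the CpG subset — the form of the published per-pattern
#' "median [range]" beta summaries.
#'
#' @param beta Beta tibble or matrix.
#' @param cpg_subset Character vector of CpG identifiers (non-empty).
#' @param groups Per-sample labels, named by sample or in column order.
#' @return Tibble with `group`, `median`, `min`, `max`, `n`.
#' @export
group_beta_summary <- function(beta, cpg_subset, groups) {
  m <- as_beta_matrix(beta)
  cpg_subset <- intersect(cpg_subset, rownames(m))
  if (length(cpg_subset) == 0) abort("`cpg_subset` is empty or absent from the matrix.")
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m)) abort("`groups` must label every sample.")
  per_sample <- apply(m[cpg_subset, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  tibble(group = as.character(groups), value = per_sample) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
}
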