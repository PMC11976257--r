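#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of drawing at least the observed overlap: with universe size
#' `|U|`, `|A|` successes and `|B|` draws, returns `P(X >= |A intersect B|)`.
#' Used to decide whether two biclusters' CpG sets match beyond chance.
#'
#' @param set_a,set_b Character vectors of identifiers, subsets of `universe`.
#' @param universe Character vector of all identifiers.
#' @return A p-value in `(0, 1]`.
#' @export
#' @examples
#' hypergeometric_overlap_p(letters[1:5], letters[1:5], letters[1:10]) # 1/252
hypergeometric_overlap_p <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of the universe.")
  }
  k <- length(intersect(set_a, set_b))
  stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                length(set_b), lower.tail = FALSE)
}

#' Permutation p-value for bicluster coherence
#'
#' Builds a null distribution by drawing `n_perm` random (row set, column set)
#' pairs of the bicluster's dimensions uniformly from `V` and computing their
#' coherence (mean absolute deviation from the per-row mean profile; lower is
#' tighter). The p-value uses the add-one rule:
#' `p = (1 + #\{null <= observed\}) / (n_perm + 1)`.
#'
#' @param cpg_ids,sample_ids Members of the bicluster (must index `V`).
#' @param V The full CpG x sample matrix.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A p-value in `(0, 1]`.
#' @export
coherence_permutation_p <- function(cpg_ids, sample_ids, V, n_perm = 999, seed = 1L) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  V <- as.matrix(V)
  rows <- match(cpg_ids, rownames(V))
  cols <- match(sample_ids, colnames(V))
  if (anyNA(rows) || anyNA(cols)) abort("bicluster members must index `V`.")
  if (length(rows) > nrow(V) || length(cols) > ncol(V)) {
    abort("bicluster dimensions exceed the matrix.")
  }
  obs <- bicluster_coherence(V, rows, cols)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      bicluster_coherence(V, sample.int(nrow(V), length(rows)),
                          sample.int(ncol(V), length(cols)))
    }, numeric(1))
    (1 + sum(null <= obs)) / (n_perm + 1)
  })
}
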