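#' Consensus fuzzy-NMF biclustering with significance filtering
#'
#' Runs [nmf_factorize()] and [extract_biclusters()] for every (rank, seed)
#' pair over a rank sweep, takes the first run of each rank as its reference,
#' and scores each reference bicluster on three axes: (i)
#' `consensus_support`, the fraction of all other runs (every rank) that
#' contain a bicluster whose CpG set matches by upper-tail hypergeometric
#' test at level `alpha`; (ii) `p_consensus`, the median of those matching
#' runs' best match p-values; (iii) `p_coherence`, a permutation p-value for
#' the bicluster's methylation coherence ([coherence_permutation_p()]). A
#' bicluster is `significant` when `p_consensus <= alpha`,
#' `p_coherence <= alpha` and `consensus_support >= support_min`. The
#' significant set is the union of CpGs and of samples over significant
#' biclusters — the analog of the published 300 CpGs across 119 samples.
#' Consensus matching uses CpG sets only; sample groupings are re-derived
#' downstream from the significant CpGs.
#'
#' @param beta A beta tibble or nonnegative CpG x sample matrix (typically
#'   restricted to representative CpGs).
#' @param ranks Integer vector of factorization ranks to sweep (default 3:10).
#' @param seeds Number of random restarts per rank (default 5, minimum 2).
#' @param row_thresh,col_thresh Fuzzy-membership thresholds (default 0.5).
#' @param alpha Significance level for both the match and the coherence tests
#'   (default 0.01).
#' @param support_min Minimum consensus support (default 0.5).
#' @param n_perm Permutations for the coherence test (default 999).
#' @param master_seed Integer; all per-run and permutation seeds derive from
#'   it, so the whole procedure is reproducible.
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @return A `consensus_biclusters` object: list with `biclusters` (tibble,
#'   one row per reference bicluster with memberships, support, p-values and
#'   the `significant` flag), `significant_cpgs`, `significant_samples`, and
#'   `params`.
#' @export
consensus_biclustering <- function(beta, ranks = 3:10, seeds = 5,
                                   row_thresh = 0.5, col_thresh = 0.5,
                                   alpha = 0.01, support_min = 0.5,
                                   n_perm = 999, master_seed = 1L,
                                   max_iter = 800, tol = 1e-8) {
  if (length(ranks) == 0) abort("`ranks` must be non-empty.")
  if (seeds < 2) abort("`seeds` must be at least 2.")
  V <- impute_beta(as_beta_matrix(beta))
  universe <- rownames(V)

  runs <- list()
  for (r in ranks) {
    for (s in seq_len(seeds)) {
      seed_rs <- derive_seed(master_seed, sprintf("nmf_r%d_s%d", r, s))
      fit <- nmf_factorize(V, r, seed = seed_rs, max_iter = max_iter, tol = tol)
      runs[[length(runs) + 1]] <- list(
        rank = r, seed_index = s,
        biclusters = extract_biclusters(fit, V, row_thresh, col_thresh)
      )
    }
  }

  is_ref <- vapply(runs, function(x) x$seed_index == 1L, logical(1))
  refs <- runs[is_ref]

  rows <- list()
  for (ref in refs) {
    bcs <- ref$biclusters
    if (is.null(bcs) || nrow(bcs) == 0) next
    others <- Filter(function(x) !(x$rank == ref$rank && x$seed_index == 1L), runs)
    for (b in seq_len(nrow(bcs))) {
      ref_cpgs <- bcs$cpg_ids[[b]]
      best_p <- vapply(others, function(run) {
        ob <- run$biclusters
        if (is.null(ob) || nrow(ob) == 0) return(1)
        min(vapply(ob$cpg_ids, hypergeometric_overlap_p, numeric(1),
                   set_b = ref_cpgs, universe = universe))
      }, numeric(1))
      matched <- best_p <= alpha
      support <- mean(matched)
      p_cons <- if (any(matched)) stats::median(best_p[matched]) else 1
      p_coh <- coherence_permutation_p(
        ref_cpgs, bcs$sample_ids[[b]], V, n_perm = n_perm,
        seed = derive_seed(master_seed, sprintf("perm_r%d_f%d", ref$rank, bcs$factor[b]))
      )
      rows[[length(rows) + 1]] <- dplyr::mutate(
        bcs[b, ],
        rank = ref$rank,
        consensus_support = support,
        p_consensus = p_cons,
        p_coherence = p_coh,
        significant = p_cons <= alpha & p_coh <= alpha & support >= support_min
      )
    }
  }
  biclusters <- dplyr::bind_rows(rows)
  if (nrow(biclusters) == 0) {
    warn("no non-empty biclusters found; significant set is empty.")
    sig_cpgs <- character(0); sig_samples <- character(0)
  } else {
    sig <- dplyr::filter(biclusters, .data$significant)
    sig_cpgs <- sort(unique(unlist(sig$cpg_ids)))
    sig_samples <- sort(unique(unlist(sig$sample_ids)))
  }

  structure(
    list(
      biclusters = biclusters,
      significant_cpgs = sig_cpgs,
      significant_samples = sig_samples,
      params = list(
        ranks = ranks, seeds = seeds, row_thresh = row_thresh,
        col_thresh = col_thresh, alpha = alpha, support_min = support_min,
        n_perm = n_perm, master_seed = as.integer(master_seed),
        max_iter = max_iter, tol = tol
      )
    ),
    class = "consensus_biclusters"
  )
}

#' @export
print.consensus_biclusters <- function(x, ...) {
  n <- if (is.null(x$biclusters)) 0 else nrow(x$biclusters)
  cat(sprintf(
    "<consensus_biclusters> %d reference biclusters (%d significant): %d CpGs x %d samples significant\n",
    n, if (n) sum(x$biclusters$significant) else 0,
    length(x$significant_cpgs), length(x$significant_samples)
  ))
  invisible(x)
}

#' @method tidy consensus_biclusters
#' @export
tidy.consensus_biclusters <- function(x, ...) {
  if (is.null(x$biclusters) || nrow(x$biclusters) == 0) {
    return(tibble(
      rank = integer(), factor = integer(), n_cpgs = integer(),
      n_samples = integer(), coherence = numeric(),
      consensus_support = numeric(), p_consensus = numeric(),
      p_coherence = numeric(), significant = logical()
    ))
  }
  dplyr::transmute(
    x$biclusters,
    rank = .data$rank, factor = .data$factor,
    n_cpgs = lengths(.data$cpg_ids),
    n_samples = lengths(.data$sample_ids),
    coherence = .data$coherence,
    consensus_support = .data$consensus_support,
    p_consensus = .data$p_consensus,
    p_coherence = .data$p_coherence,
    significant = .data$significant
  )
}

#' @method glance consensus_biclusters
#' @export
glance.consensus_biclusters <- function(x, ...) {
  tibble(
    n_biclusters = if (is.null(x$biclusters)) 0L else nrow(x$biclusters),
    n_significant = if (is.null(x$biclusters) || nrow(x$biclusters) == 0) 0L
      else sum(x$biclusters$significant),
    n_significant_cpgs = length(x$significant_cpgs),
    n_significant_samples = length(x$significant_samples)
  )
}
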