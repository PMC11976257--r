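#' Select the most variable CpGs
#'
#' Ranks CpGs by their across-sample standard deviation (denominator `n - 1`)
#' and flags the `k` most variable; ties are broken in favour of the earlier
#' row. Missing betas are mean-imputed per CpG before ranking (CpGs with more
#' than 20% missing are dropped).
#'
#' @param beta A beta tibble or CpG x sample matrix.
#' @param k Number of CpGs to keep (default 10,000). If `k` exceeds the number
#'   of CpGs, all are kept with a warning.
#' @return A tibble (input row order) with columns `cpg_id`, `sd` and
#'   `selected`.
#' @export
select_top_variable <- function(beta, k = 10000) {
  if (k < 1) abort("`k` must be at least 1.")
  m <- impute_beta(as_beta_matrix(beta))
  if (ncol(m) < 2) abort("standard deviation needs at least 2 samples.")
  sds <- apply(m, 1, stats::sd)
  if (k > nrow(m)) {
    warn(sprintf("`k` (%d) exceeds the %d available CpGs; keeping all.", k, nrow(m)))
    k <- nrow(m)
  }
  ord <- order(-sds, seq_along(sds))
  selected <- logical(nrow(m))
  selected[ord[seq_len(k)]] <- TRUE
  tibble(cpg_id = rownames(m), sd = unname(sds), selected = selected)
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  rn <- rowSums(x^2)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- pmax(rn - 2 * drop(x %*% x[centers[1], ]) + rn[centers[1]], 0)
  if (k > 1) {
    for (i in 2:k) {
      d2sum <- sum(d2)
      centers[i] <- if (d2sum <= 0) {
        sample(setdiff(seq_len(n), centers[seq_len(i - 1)]), 1)
      } else {
        sample.int(n, 1, prob = d2 / d2sum)
      }
      d2 <- pmin(d2, pmax(rn - 2 * drop(x %*% x[centers[i], ]) + rn[centers[i]], 0))
    }
  }
  x[centers, , drop = FALSE]
}

run_kmeans <- function(x, k, seed, n_init = 10, iter.max = 300) {
  if (k >= nrow(x)) {
    # singleton clusters: every point is its own center
    return(list(
      cluster = seq_len(nrow(x)), centers = x,
      tot.withinss = 0
    ))
  }
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      init <- kmeanspp_centers(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = iter.max, algorithm = "Lloyd")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
}

#' Reduce selected CpGs to cluster-representative CpGs
#'
#' Clusters the selected CpGs' beta profiles (samples as dimensions,
#' Euclidean) into `n_clusters` k-means clusters (k-means++ seeding, `n_init`
#' restarts, best inertia kept), then picks representatives: each cluster's
#' medoid (member closest to its centroid) plus, to reach `target_reps`,
#' further centroid-nearest members allocated across clusters proportionally
#' to cluster size by largest remainder. The defaults mirror the published
#' reduction of the 10,000 most variable CpGs to 1,000 clusters and 1,938
#' representatives.
#'
#' @param beta A beta tibble or CpG x sample matrix.
#' @param selection Optional output of [select_top_variable()]; when given,
#'   only CpGs with `selected == TRUE` are clustered.
#' @param n_clusters Number of k-means clusters (default 1,000).
#' @param target_reps Total representatives to return (default 1,938); must be
#'   at least `n_clusters`.
#' @param seed Integer seed (k-means restarts are deterministic given it).
#' @param n_init k-means restarts (default 10).
#' @return A `reduced_set` tibble with columns `cpg_id`, `sd`, `cluster` and
#'   `is_representative`; attributes `inertia`, `seed`.
#' @export
reduce_by_kmeans <- function(beta, selection = NULL, n_clusters = 1000,
                             target_reps = 1938, seed = 1L, n_init = 10) {
  if (target_reps < n_clusters) abort("`target_reps` must be >= `n_clusters`.")
  m <- impute_beta(as_beta_matrix(beta))
  if (!is.null(selection)) {
    keep <- selection$cpg_id[selection$selected]
    m <- m[intersect(rownames(m), keep), , drop = FALSE]
  }
  n <- nrow(m)
  if (n == 0) abort("no CpGs to cluster.")
  if (n_clusters > n) abort("`n_clusters` cannot exceed the number of selected CpGs.")

  km <- run_kmeans(m, n_clusters, seed, n_init)
  cl <- km$cluster
  sizes <- tabulate(cl, nbins = n_clusters)
  d2c <- rowSums((m - km$centers[cl, , drop = FALSE])^2)

  target_reps <- min(target_reps, n)
  extras <- allocate_extras(sizes, target_reps - n_clusters)

  is_rep <- logical(n)
  for (c in seq_len(n_clusters)) {
    members <- which(cl == c)
    ord <- members[order(d2c[members], members)]
    is_rep[ord[seq_len(min(1 + extras[c], length(ord)))]] <- TRUE
  }

  out <- tibble(
    cpg_id = rownames(m),
    sd = apply(m, 1, stats::sd),
    cluster = cl,
    is_representative = is_rep
  )
  structure(out,
    class = c("reduced_set", class(out)),
    inertia = km$tot.withinss, seed = as.integer(seed)
  )
}

# Size-proportional largest-remainder allocation of `total` extra
# representatives, capped at cluster size - 1 (the medoid is already taken).
allocate_extras <- function(sizes, total) {
  k <- length(sizes)
  alloc <- integer(k)
  cap <- pmax(sizes - 1L, 0L)
  remaining <- total
  while (remaining > 0 && any(alloc < cap)) {
    pool <- which(alloc < cap)
    quota <- remaining * sizes[pool] / sum(sizes[pool])
    add <- pmin(floor(quota), cap[pool] - alloc[pool])
    leftover <- remaining - sum(add)
    frac_ord <- pool[order(-(quota - floor(quota)), pool)]
    for (c in frac_ord) {
      if (leftover <= 0) break
      if (alloc[c] + add[match(c, pool)] < cap[c]) {
        add[match(c, pool)] <- add[match(c, pool)] + 1L
        leftover <- leftover - 1L
      }
    }
    alloc[pool] <- alloc[pool] + add
    remaining <- total - sum(alloc)
    if (all(add == 0)) break
  }
  alloc
}
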