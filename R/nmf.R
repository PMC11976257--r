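#' Fuzzy non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative CpG x sample matrix `V` as `W %*% H` (`W`:
#' CpG x rank, `H`: rank x sample, both nonnegative) by Lee-Seung
#' multiplicative updates minimizing squared Frobenius error. Both factors
#' are initialized uniform on (0, 1] scaled by `mean(V)`, so runs are
#' reproducible given `seed`. Iteration stops after `max_iter` updates or
#' when the relative reconstruction error `||V - WH||_F / ||V||_F` changes by
#' less than `tol` between iterations. Normalized rows of `W` (columns of
#' `H`) are the fuzzy memberships used downstream for biclustering.
#'
#' @param V Nonnegative numeric matrix (beta values qualify).
#' @param rank Factorization rank, `1 <= rank <= min(dim(V))`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum update iterations (default 800).
#' @param tol Stop when the relative error changes by less than this
#'   (default 1e-8). Tight convergence matters: under-converged factors give
#'   blurred memberships and unstable biclusters.
#' @return An `nmf_fit` object: list with `W`, `H`, `rank`, `seed`, `n_iter`
#'   and `error_trace` (relative Frobenius error, element 1 at
#'   initialization, non-increasing).
#' @export
nmf_factorize <- function(V, rank, seed = 1L, max_iter = 800, tol = 1e-8) {
  V <- as.matrix(V)
  if (anyNA(V) || any(V < 0)) abort("`V` must be nonnegative with no missing values.")
  if (rank < 1 || rank > min(dim(V))) abort("`rank` must satisfy 1 <= rank <= min(dim(V)).")
  m <- nrow(V); n <- ncol(V)
  nv <- norm(V, "F")
  if (nv == 0) nv <- 1
  eps <- .Machine$double.eps

  with_seed(seed, {
    sc <- mean(V)
    if (sc == 0) sc <- 1
    W <- matrix(stats::runif(m * rank), m, rank) * sc
    H <- matrix(stats::runif(rank * n), rank, n) * sc

    err <- norm(V - W %*% H, "F") / nv
    trace <- numeric(max_iter + 1)
    trace[1] <- err
    n_iter <- 0
    for (i in seq_len(max_iter)) {
      H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      new_err <- norm(V - W %*% H, "F") / nv
      n_iter <- i
      trace[i + 1] <- new_err
      if (abs(err - new_err) < tol) break
      err <- new_err
    }
    dimnames(W) <- list(rownames(V), NULL)
    dimnames(H) <- list(NULL, colnames(V))
    structure(
      list(W = W, H = H, rank = as.integer(rank), seed = as.integer(seed),
           n_iter = n_iter, error_trace = trace[seq_len(n_iter + 1)]),
      class = "nmf_fit"
    )
  })
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("<nmf_fit> rank %d, %d x %d, %d iterations, final rel. error %.3g\n",
              x$rank, nrow(x$W), ncol(x$H), x$n_iter,
              x$error_trace[length(x$error_trace)]))
  invisible(x)
}

# Fuzzy memberships from a factorization. NMF factors are defined only up to
# diagonal rescaling of (W, H); memberships are computed after the canonical
# scaling that gives every H row unit maximum, absorbing factor magnitude
# into W. Rows (CpGs): membership of CpG i in factor f is the share
# W[i,f] / sum_g W[i,g] of the row's scaled loading (all-zero rows stay 0,
# so uninformative probes never enter a bicluster). Columns (samples) are
# mixtures of all factors, so a share can never be decisive; a sample's
# membership in factor f is instead its activation H[f,j] min-max-normalized
# within the factor (1 = the factor's strongest sample).
fuzzy_memberships <- function(fit) {
  a <- apply(fit$H, 1, max)
  W <- sweep(fit$W, 2, pmax(a, .Machine$double.xmin), `*`)
  rs <- rowSums(W)
  rmem <- W / ifelse(rs > 0, rs, 1)
  rmem[rs == 0, ] <- 0
  cmem <- t(apply(fit$H, 1, function(h) {
    rng <- max(h) - min(h)
    if (rng <= 0) rep(0, length(h)) else (h - min(h)) / rng
  }))
  list(row = rmem, col = cmem)
}

# Coherence: mean absolute deviation of the bicluster's betas from the
# bicluster's row-mean profile (the per-sample mean over member CpGs).
# Low when member CpGs move in parallel across the member samples --
# regardless of the level differences between samples; lower = tighter.
bicluster_coherence <- function(V, rows, cols) {
  sub <- V[rows, cols, drop = FALSE]
  mean(abs(sweep(sub, 2, colMeans(sub))))
}

#' Extract fuzzy biclusters from a factorization
#'
#' Factors are first scale-canonicalized (unit-max `H` rows, magnitude
#' absorbed into `W`). For each factor `f`, CpG `i`'s membership is then the
#' share `W[i, f] / sum(W[i, ])` (zero if the row of `W` is all zero), and
#' sample `j`'s membership is its activation `H[f, j]` min-max-normalized
#' within factor `f` (samples are mixtures of all factors, so within-factor
#' activation — not a share across factors — is what ranks them). Factor
#' `f`'s bicluster keeps the CpGs with row membership `>= row_thresh` and
#' samples with column membership `>= col_thresh`; biclusters empty on either
#' side are dropped.
#'
#' @param fit An `nmf_fit`.
#' @param V The matrix that was factorized (used for coherence).
#' @param row_thresh,col_thresh Membership thresholds in `[0, 1)`
#'   (default 0.5).
#' @return A tibble with one row per retained factor: `factor`, list-columns
#'   `cpg_ids`, `sample_ids`, `row_membership`, `col_membership`, and
#'   `coherence`.
#' @export
extract_biclusters <- function(fit, V, row_thresh = 0.5, col_thresh = 0.5) {
  stopifnot(inherits(fit, "nmf_fit"))
  if (row_thresh < 0 || row_thresh >= 1 || col_thresh < 0 || col_thresh >= 1) {
    abort("thresholds must lie in [0, 1).")
  }
  V <- as.matrix(V)
  mem <- fuzzy_memberships(fit)
  res <- purrr::map(seq_len(fit$rank), function(f) {
    rows <- which(mem$row[, f] >= row_thresh & rowSums(fit$W) > 0)
    cols <- which(mem$col[f, ] >= col_thresh & colSums(fit$H) > 0)
    if (length(rows) == 0 || length(cols) == 0) return(NULL)
    tibble(
      factor = f,
      cpg_ids = list(rownames(V)[rows]),
      sample_ids = list(colnames(V)[cols]),
      row_membership = list(stats::setNames(mem$row[rows, f], rownames(V)[rows])),
      col_membership = list(stats::setNames(mem$col[f, cols], colnames(V)[cols])),
      coherence = bicluster_coherence(V, rows, cols)
    )
  })
  dplyr::bind_rows(res)
}
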