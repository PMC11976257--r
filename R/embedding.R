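#' Fit a 2-D UMAP embedding of samples on significant CpGs
#'
#' Embeds samples (columns) into two dimensions with UMAP, by default using
#' Manhattan distance and 15 neighbors as in the published analysis. The CpG
#' basis is order-normalized (sorted) internally, so embeddings are invariant
#' to the row order of the input. Fitting is single-threaded and fully
#' deterministic given `seed`.
#'
#' @param beta Beta tibble or matrix restricted to the significant CpGs.
#' @param n_neighbors UMAP neighborhood size (default 15); needs at least
#'   `n_neighbors + 1` samples.
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param seed Integer seed.
#' @return A `meth_umap` object: list with `coords` (tibble `sample_id`,
#'   `umap1`, `umap2`), `cpg_basis`, `params`, and the internal uwot model
#'   used by [project_samples()].
#' @export
fit_embedding <- function(beta, n_neighbors = 15,
                          metric = c("manhattan", "euclidean"),
                          min_dist = 0.1, seed = 1L) {
  metric <- match.arg(metric)
  m <- impute_beta(as_beta_matrix(beta))
  if (ncol(m) < n_neighbors + 1) {
    abort(sprintf("need at least n_neighbors + 1 = %d samples, got %d.",
                  n_neighbors + 1, ncol(m)))
  }
  basis <- sort(rownames(m))
  x <- t(m[basis, , drop = FALSE])
  model <- with_seed(seed, {
    uwot::umap(x, n_neighbors = n_neighbors, metric = metric,
               min_dist = min_dist, ret_model = TRUE,
               n_threads = 1, n_sgd_threads = 0)
  })
  coords <- tibble(
    sample_id = colnames(m),
    umap1 = model$embedding[, 1],
    umap2 = model$embedding[, 2]
  )
  structure(
    list(
      coords = coords, cpg_basis = basis,
      params = list(n_neighbors = n_neighbors, metric = metric,
                    min_dist = min_dist, seed = as.integer(seed)),
      model = model
    ),
    class = "meth_umap"
  )
}

#' Project new samples into a fitted UMAP space
#'
#' Transform-style projection: the training coordinates are never refitted,
#' so previously embedded cohorts keep their positions. The new matrix must
#' contain every CpG of the model's basis.
#'
#' @param model A `meth_umap` from [fit_embedding()].
#' @param beta Beta tibble or matrix for the new samples.
#' @return Tibble with `sample_id`, `umap1`, `umap2`.
#' @export
project_samples <- function(model, beta) {
  stopifnot(inherits(model, "meth_umap"))
  n_new <- if (is.matrix(beta)) ncol(beta) else ncol(beta) - 1
  if (n_new < 1) abort("no samples to project.")
  m <- impute_beta(as_beta_matrix(beta))
  missing <- setdiff(model$cpg_basis, rownames(m))
  if (length(missing)) {
    abort(sprintf(
      "new matrix lacks %d basis CpG(s): %s%s", length(missing),
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..." else ""
    ))
  }
  x <- t(m[model$cpg_basis, , drop = FALSE])
  emb <- with_seed(model$params$seed, {
    uwot::umap_transform(x, model$model, n_threads = 1, n_sgd_threads = 0)
  })
  tibble(sample_id = colnames(m), umap1 = emb[, 1], umap2 = emb[, 2])
}

#' @export
print.meth_umap <- function(x, ...) {
  cat(sprintf("<meth_umap> %d samples on %d CpGs (%s, %d neighbors, min_dist %.2f)\n",
              nrow(x$coords), length(x$cpg_basis), x$params$metric,
              x$params$n_neighbors, x$params$min_dist))
  invisible(x)
}

#' @method tidy meth_umap
#' @export
tidy.meth_umap <- function(x, ...) x$coords

#' @method glance meth_umap
#' @export
glance.meth_umap <- function(x, ...) {
  tibble(n_samples = nrow(x$coords), n_cpgs = length(x$cpg_basis),
         metric = x$params$metric, n_neighbors = x$params$n_neighbors,
         min_dist = x$params$min_dist, seed = x$params$seed)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted methylation UMAP
#'
#' @param object A `meth_umap`.
#' @param colour Optional vector (length = training samples) used to colour
#'   points, e.g. pattern labels or median methylation.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_umap
#' @export
autoplot.meth_umap <- function(object, colour = NULL, ...) {
  df <- object$coords
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$umap1, .data$umap2)) +
    ggplot2::labs(x = "UMAP1", y = "UMAP2")
  if (is.null(colour)) {
    p + ggplot2::geom_point(size = 1.5)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), size = 1.5) +
      ggplot2::labs(colour = NULL)
  }
}
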