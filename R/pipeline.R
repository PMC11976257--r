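#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the published
#' defaults: 10,000 most variable CpGs, 1,000 k-means clusters reduced to
#' 1,938 representatives, a rank sweep of fuzzy-NMF consensus biclustering,
#' 4 CpG modules, 7 methylation patterns, and a Manhattan/15-neighbor UMAP.
#' One `master_seed` deterministically derives every stage seed.
#'
#' @param beta_path,annotation_path Input file paths (TSV; see
#'   [read_beta_matrix()]), ignored when `beta`/`annotation` objects are
#'   supplied.
#' @param beta,annotation Optional in-memory inputs.
#' @param out_dir Optional output directory; when set, all stage outputs are
#'   written as TSV plus a JSON run-metadata sidecar.
#' @param k_top Top-variable CpG count K (default 10,000).
#' @param n_clusters Reduction cluster count C (default 1,000).
#' @param target_reps Representative count R (default 1,938).
#' @param ranks,seeds,row_thresh,col_thresh,alpha,support_min,n_perm
#'   Biclustering settings (see [consensus_biclustering()]).
#' @param k_mod,k_pat Module and pattern counts (defaults 4 and 7).
#' @param n_neighbors,metric,min_dist UMAP settings (defaults 15,
#'   `"manhattan"`, 0.1).
#' @param n_init k-means restarts (default 10).
#' @param master_seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(beta_path = NULL, annotation_path = NULL,
                            beta = NULL, annotation = NULL, out_dir = NULL,
                            k_top = 10000, n_clusters = 1000, target_reps = 1938,
                            ranks = 3:10, seeds = 5, row_thresh = 0.5,
                            col_thresh = 0.5, alpha = 0.01, support_min = 0.5,
                            n_perm = 999, k_mod = 4, k_pat = 7,
                            n_neighbors = 15, metric = "manhattan",
                            min_dist = 0.1, n_init = 10, master_seed = 1L) {
  if (target_reps < n_clusters) abort("config: `target_reps` must be >= `n_clusters`.")
  if (k_top < target_reps) abort("config: `k_top` must be >= `target_reps`.")
  for (x in c(k_top, n_clusters, target_reps, k_mod, k_pat, seeds, n_perm, n_init)) {
    if (x < 1) abort("config: all counts must be positive.")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full methylation-pattern pipeline
#'
#' Executes, in order: cohort IO and alignment, variable-CpG selection and
#' k-means reduction, consensus fuzzy-NMF biclustering with significance
#' filtering, module/pattern assignment, UMAP embedding, and downstream
#' statistics (per-pattern methylation summaries, pairwise Wilcoxon tests on
#' per-sample median methylation, Fisher enrichment of annotation levels per
#' pattern). Any stage failure aborts with the stage name; partially written
#' outputs are removed. Re-running with the same config and master seed
#' reproduces the output bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return A `meth_pipeline` object with elements `selection`, `reduced`,
#'   `consensus`, `modules`, `patterns`, `embedding`, `stats`, `seeds`,
#'   `config`, `timings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  written <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      for (f in written) unlink(f)
      abort(sprintf("stage %s: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    inform(sprintf("[%s] done (%.1fs)", name, timings[[name]]))
    res
  }
  out <- function(file, obj) {
    if (is.null(config$out_dir)) return(invisible())
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    path <- file.path(config$out_dir, file)
    readr::write_tsv(obj, path, na = "NA", progress = FALSE)
    written <<- c(written, path)
  }
  seeds <- list(
    reduce = derive_seed(config$master_seed, "feature_reduction"),
    biclust = derive_seed(config$master_seed, "fuzzy_nmf_biclustering"),
    modules = derive_seed(config$master_seed, "modules"),
    patterns = derive_seed(config$master_seed, "patterns"),
    embed = derive_seed(config$master_seed, "embedding")
  )

  io <- stage("cohort_io", {
    beta <- config$beta %||% read_beta_matrix(config$beta_path)
    ann <- config$annotation
    if (is.null(ann) && !is.null(config$annotation_path)) {
      ann <- read_annotation(config$annotation_path)
    }
    if (is.null(ann)) {
      ann <- tibble(sample_id = setdiff(names(beta), "cpg_id"))
    }
    align_cohort(beta, ann)
  })
  m <- as_beta_matrix(io$beta)

  red <- stage("feature_reduction", {
    k <- min(config$k_top, nrow(m))
    if (k < config$k_top) {
      warn(sprintf("K = %d exceeds the %d available CpGs; using all.",
                   config$k_top, nrow(m)))
    }
    sel <- select_top_variable(m, k)
    reduce_by_kmeans(m, sel, n_clusters = min(config$n_clusters, k),
                     target_reps = min(config$target_reps, k),
                     seed = seeds$reduce, n_init = config$n_init)
  })
  reps <- red$cpg_id[red$is_representative]
  out("reduced_set.tsv", red)

  cons <- stage("fuzzy_nmf_biclustering", {
    consensus_biclustering(
      m[reps, , drop = FALSE],
      ranks = config$ranks, seeds = config$seeds,
      row_thresh = config$row_thresh, col_thresh = config$col_thresh,
      alpha = config$alpha, support_min = config$support_min,
      n_perm = config$n_perm, master_seed = seeds$biclust
    )
  })
  out("biclusters.tsv", tidy(cons))
  out("significant_set.tsv", dplyr::bind_rows(
    tibble(kind = "cpg", id = cons$significant_cpgs),
    tibble(kind = "sample", id = cons$significant_samples)
  ))

  mp <- stage("modules_patterns", {
    if (length(cons$significant_cpgs) == 0) {
      abort("no significant CpGs; cannot derive modules and patterns.")
    }
    sig <- m[cons$significant_cpgs, , drop = FALSE]
    list(
      modules = assign_modules(sig, config$k_mod, seed = seeds$modules,
                               n_init = config$n_init),
      patterns = assign_patterns(sig, config$k_pat, seed = seeds$patterns,
                                 n_init = config$n_init)
    )
  })
  out("modules.tsv", tibble(cpg_id = mp$modules$cpg_id,
                            module = as.character(mp$modules$module)))
  out("patterns.tsv", tibble(sample_id = mp$patterns$sample_id,
                             pattern = as.character(mp$patterns$pattern)))

  emb <- stage("embedding", {
    fit_embedding(m[cons$significant_cpgs, , drop = FALSE],
                  n_neighbors = config$n_neighbors, metric = config$metric,
                  min_dist = config$min_dist, seed = seeds$embed)
  })
  out("embedding.tsv", emb$coords)

  st <- stage("cohort_stats", {
    pat <- stats::setNames(as.character(mp$patterns$pattern), mp$patterns$sample_id)
    med <- apply(m[cons$significant_cpgs, , drop = FALSE], 2, stats::median)
    wil <- pairwise_wilcoxon(
      tibble(value = med, pattern = pat[colnames(m)]), value, pattern
    )
    summ <- group_beta_summary(m, cons$significant_cpgs, pat)
    enr <- pattern_enrichment(mp$patterns, io$annotation)
    comp <- purrr::map(
      intersect(c("diagnosis", "coo", "mutational_cluster"), names(io$annotation)),
      function(f) pattern_composition(mp$patterns, io$annotation, f)
    )
    list(wilcoxon = wil, summary = summ, enrichment = enr, composition = comp)
  })
  out("stats_wilcoxon.tsv", st$wilcoxon)
  out("stats_summary.tsv", st$summary)
  if (!is.null(st$enrichment) && nrow(st$enrichment)) {
    out("stats_enrichment.tsv", st$enrichment)
  }

  if (!is.null(config$out_dir)) {
    meta <- list(
      package_version = as.character(utils::packageVersion("methpattern")),
      master_seed = config$master_seed, stage_seeds = seeds,
      params = config[c("k_top", "n_clusters", "target_reps", "ranks", "seeds",
                        "row_thresh", "col_thresh", "alpha", "support_min",
                        "n_perm", "k_mod", "k_pat", "n_neighbors", "metric",
                        "min_dist", "n_init")],
      counts = list(
        n_cpgs = nrow(m), n_samples = ncol(m),
        n_representatives = length(reps),
        n_significant_cpgs = length(cons$significant_cpgs),
        n_significant_samples = length(cons$significant_samples)
      )
    )
    path <- file.path(config$out_dir, "run_metadata.json")
    jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    written <- c(written, path)
  }

  structure(
    list(selection = red, consensus = cons, modules = mp$modules,
         patterns = mp$patterns, embedding = emb, stats = st,
         annotation = io$annotation, seeds = seeds, config = config,
         timings = timings),
    class = "meth_pipeline"
  )
}

# Fisher enrichment of every (pattern, annotation level) pair against the
# rest of the cohort; unknown levels are excluded row-wise.
pattern_enrichment <- function(patterns, annotation,
                               fields = c("diagnosis", "coo",
                                          "bcl2_rearranged", "bcl6_rearranged",
                                          "mutational_cluster")) {
  fields <- intersect(fields, names(annotation))
  if (length(fields) == 0) return(NULL)
  pat <- tibble(sample_id = patterns$sample_id,
                pattern = as.character(patterns$pattern))
  res <- list()
  for (f in fields) {
    df <- dplyr::inner_join(pat, annotation[c("sample_id", f)], by = "sample_id")
    x <- as.character(df[[f]])
    unknown <- ANNOT_UNKNOWN[f]
    keep <- !is.na(x) & (is.na(unknown) | x != unknown)
    df <- df[keep, ]; x <- x[keep]
    if (length(unique(x)) < 2 && length(unique(x)) * length(unique(df$pattern)) < 2) next
    for (p in sort(unique(df$pattern))) {
      for (lv in sort(unique(x))) {
        a <- sum(df$pattern == p & x == lv)
        b <- sum(df$pattern == p & x != lv)
        c_ <- sum(df$pattern != p & x == lv)
        d <- sum(df$pattern != p & x != lv)
        fe <- fisher_enrichment(matrix(c(a, c_, b, d), 2))
        res[[length(res) + 1]] <- dplyr::mutate(
          fe, field = f, pattern = p, level = lv, .before = 1
        )
      }
    }
  }
  if (length(res) == 0) return(NULL)
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- bonferroni_adjust(out$p_raw)
  out$m <- nrow(out)
  out
}

#' @export
print.meth_pipeline <- function(x, ...) {
  cat("<meth_pipeline>\n")
  cat(sprintf("  representatives: %d\n", sum(x$selection$is_representative)))
  cat(sprintf("  significant: %d CpGs x %d samples\n",
              length(x$consensus$significant_cpgs),
              length(x$consensus$significant_samples)))
  cat(sprintf("  modules: %s\n",
              paste(sprintf("%s=%d", levels(x$modules$module),
                            table(x$modules$module)), collapse = " ")))
  cat(sprintf("  patterns: %s\n",
              paste(sprintf("%s=%d", levels(x$patterns$pattern),
                            table(x$patterns$pattern)), collapse = " ")))
  invisible(x)
}

#' @method glance meth_pipeline
#' @export
glance.meth_pipeline <- function(x, ...) {
  tibble(
    n_cpgs = nrow(x$selection),
    n_representatives = sum(x$selection$is_representative),
    n_significant_cpgs = length(x$consensus$significant_cpgs),
    n_significant_samples = length(x$consensus$significant_samples),
    k_mod = x$config$k_mod, k_pat = x$config$k_pat,
    master_seed = x$config$master_seed
  )
}
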