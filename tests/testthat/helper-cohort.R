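# Small cohorts shared across tests. Built once per test run.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(
        n_cpgs = 600, n_samples = 70, n_modules = 3, n_patterns = 4, seed = 11
      )
    }
    cache
  }
})

# A tiny beta tibble from an explicit matrix.
beta_from <- function(values, cpgs = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- cpgs %||% sprintf("cg%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  as_beta_tbl(m)
}
`%||%` <- function(x, y) if (is.null(x)) y else x
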