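#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance
NULL

# Deterministic per-stage seed derived from a master seed and a stage name.
# Keeps results below 2^31 - 1 so they remain valid R integer seeds.
derive_seed <- function(master_seed, stage) {
  key <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master_seed)) * 31 + key * 7919) %% 2147483629)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Adjust p-values by the Bonferroni rule
#'
#' Multiplies each p-value by the family size `m` (the length of the input)
#' and caps at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p)`.
#' @return Numeric vector of adjusted p-values, same length as `p`.
#' @export
#' @examples
#' bonferroni_adjust(c(0.01, 0.04, 0.5))
bonferroni_adjust <- function(p, m = length(p)) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("all p-values must lie in [0, 1].")
  }
  pmin(1, m * p)
}
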