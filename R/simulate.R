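#' Mix tumor and bystander methylation
#'
#' A specimen's observed beta value is modelled as a linear mixture of the
#' tumor-intrinsic methylation and a non-tumor (bystander) profile, weighted
#' by the tumor-cell content (TCC): `tcc * beta_tumor + (1 - tcc) *
#' beta_bystander`. Low-TCC specimens are pulled toward the bystander
#' profile, which flattens between-pattern differences.
#'
#' @param beta_tumor,beta_bystander Beta values in `[0, 1]` (vectorised).
#' @param tcc Tumor-cell-content fraction in `[0, 1]`.
#' @return Mixed beta value(s) in `[0, 1]`.
#' @export
#' @examples
#' mix_tumor_bystander(0.8, 0.1, 0.5)
mix_tumor_bystander <- function(beta_tumor, beta_bystander, tcc) {
  for (a in list(beta_tumor, beta_bystander, tcc)) {
    if (!is.numeric(a) || anyNA(a) || any(a < 0 | a > 1)) {
      abort("all arguments must be numeric in [0, 1].")
    }
  }
  tcc * beta_tumor + (1 - tcc) * beta_bystander
}

# Draw a module x pattern mean matrix until (i) every pattern pair is
# separated by at least `min_separation` in at least one module and (ii)
# every module spans at least `module_contrast` between its lowest and
# highest pattern. (ii) makes each planted module a module in the biological
# sense -- a CpG set whose methylation actually varies across patterns, as
# the published modules do; without it a module can come out nearly flat and
# carry no recoverable signal.
draw_mu <- function(n_modules, n_patterns, min_separation,
                    module_contrast = 0.5, max_tries = 10000) {
  if (n_patterns == 1) module_contrast <- 0
  for (i in seq_len(max_tries)) {
    mu <- matrix(stats::runif(n_modules * n_patterns, 0.05, 0.95),
                 n_modules, n_patterns)
    ok <- all(apply(mu, 1, function(x) diff(range(x))) >= module_contrast)
    if (ok && n_patterns > 1) {
      for (p in seq_len(n_patterns - 1)) {
        for (q in seq(p + 1, n_patterns)) {
          if (max(abs(mu[, p] - mu[, q])) < min_separation) ok <- FALSE
        }
      }
    }
    if (ok) return(mu)
  }
  abort("could not draw a pattern-separated mean matrix; relax `min_separation`.")
}

#' Simulate a methylation cohort with planted module/pattern structure
#'
#' Generates a CpG x sample beta matrix in which a fraction of CpGs carry
#' module-by-pattern structure: a structured CpG in module `m` measured in a
#' sample of pattern `p` with tumor fraction `t` has expected beta
#' `t * mu[m, p] + (1 - t) * bystander[i]`, and the observed value is drawn
#' from a Beta distribution with that mean and concentration `precision`
#' (shape1 = mean * s, shape2 = (1 - mean) * s). Nuisance CpGs have a
#' pattern-independent tumor-intrinsic mean. The bystander profile mimics
#' non-malignant B cells: low methylation for all modules except the last,
#' which is highly methylated.
#'
#' @param n_cpgs,n_samples Cohort dimensions (default 5,000 x 180).
#' @param n_modules,n_patterns Planted CpG modules and sample methylation
#'   patterns (default 4 x 7).
#' @param frac_structured Fraction of CpGs carrying structure (default 0.1).
#' @param tcc_range Tumor-cell-content interval; per-sample TCC is uniform on
#'   it (default `c(0.6, 1)`).
#' @param precision Beta-noise concentration `s > 0` (default 50).
#' @param min_separation Minimum between-pattern difference guaranteed, for
#'   each pattern pair, in at least one module (default 0.25).
#' @param module_contrast Minimum spread (max - min across patterns) of each
#'   module's tumor-intrinsic means (default 0.5), so every planted module
#'   varies across patterns the way published CpG modules do.
#' @param seed Integer seed; the cohort is fully reproducible given it.
#' @return A list with `beta` (beta tibble), `annotation` (tibble with
#'   pattern-correlated diagnosis/COO/mutational-cluster labels and the true
#'   TCC), and `truth`, a `synthetic_truth` object holding `module_of_cpg`
#'   (0 = nuisance), `pattern_of_sample`, `mu`, `bystander_profile`,
#'   `tcc_of_sample`, `precision` and `seed`.
#' @export
simulate_cohort <- function(n_cpgs = 5000, n_samples = 180,
                            n_modules = 4, n_patterns = 7,
                            frac_structured = 0.1,
                            tcc_range = c(0.6, 1),
                            precision = 50,
                            min_separation = 0.25,
                            module_contrast = 0.5,
                            seed = 1L) {
  if (n_modules < 1 || n_patterns < 1) abort("need at least one module and one pattern.")
  if (n_patterns > n_samples) abort("`n_patterns` cannot exceed `n_samples`.")
  if (frac_structured <= 0 || frac_structured > 1) abort("`frac_structured` must be in (0, 1].")
  if (length(tcc_range) != 2 || any(tcc_range < 0 | tcc_range > 1) ||
      tcc_range[1] > tcc_range[2]) {
    abort("`tcc_range` must be a nonempty interval within [0, 1].")
  }
  if (precision <= 0) abort("`precision` must be positive.")

  with_seed(seed, {
    cpg_ids <- sprintf("cg%06d", seq_len(n_cpgs))
    sample_ids <- sprintf("S%03d", seq_len(n_samples))

    n_struct <- max(n_modules, round(frac_structured * n_cpgs))
    struct_idx <- sort(sample.int(n_cpgs, n_struct))
    module_of_cpg <- stats::setNames(integer(n_cpgs), cpg_ids)
    module_of_cpg[struct_idx] <- sample(rep_len(seq_len(n_modules), n_struct))

    pattern_of_sample <- stats::setNames(
      sample(rep_len(seq_len(n_patterns), n_samples)), sample_ids
    )
    tcc <- stats::setNames(stats::runif(n_samples, tcc_range[1], tcc_range[2]),
                           sample_ids)

    mu <- draw_mu(n_modules, n_patterns, min_separation, module_contrast)

    # nuisance tumor-intrinsic means, shared across patterns
    baseline <- stats::setNames(stats::runif(n_cpgs, 0.05, 0.95), cpg_ids)
    # bystander: low methylation except for the last (heterochromatic) module;
    # nuisance CpGs are cell-type-invariant (bystander = tumor baseline), so
    # their only variability is measurement noise, never TCC dilution
    byst_mean <- ifelse(module_of_cpg == n_modules, 0.85, 0.08)
    bystander <- stats::setNames(
      clamp01(stats::rbeta(n_cpgs, byst_mean * 100, (1 - byst_mean) * 100)),
      cpg_ids
    )
    bystander[module_of_cpg == 0] <- baseline[module_of_cpg == 0]

    tumor_mean <- matrix(baseline, n_cpgs, n_samples)
    is_struct <- module_of_cpg > 0
    tumor_mean[is_struct, ] <- mu[cbind(
      rep(module_of_cpg[is_struct], n_samples),
      rep(pattern_of_sample, each = sum(is_struct))
    )]

    mean_beta <- sweep(tumor_mean, 2, tcc, `*`) +
      outer(bystander, 1 - tcc)
    mean_beta <- pmin(pmax(mean_beta, 1e-4), 1 - 1e-4)
    obs <- matrix(
      stats::rbeta(length(mean_beta), mean_beta * precision,
                   (1 - mean_beta) * precision),
      n_cpgs, n_samples, dimnames = list(cpg_ids, sample_ids)
    )

    annotation <- synthetic_annotation(pattern_of_sample, n_patterns, tcc)
    truth <- structure(
      list(
        module_of_cpg = module_of_cpg,
        pattern_of_sample = pattern_of_sample,
        mu = mu,
        bystander_profile = bystander,
        baseline = baseline,
        tcc_of_sample = tcc,
        precision = precision,
        seed = as.integer(seed)
      ),
      class = "synthetic_truth"
    )
    list(beta = as_beta_tbl(obs), annotation = annotation, truth = truth)
  })
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Pattern-correlated sample annotation: early patterns lean FL/GCB, late ones
# DLBCL/ABC, with 10% random relabeling so associations are strong but
# imperfect, as in real cohorts.
synthetic_annotation <- function(pattern_of_sample, n_patterns, tcc) {
  p <- pattern_of_sample
  n <- length(p)
  flip <- stats::runif(n) < 0.1
  dx <- ifelse(p <= max(1, floor(n_patterns / 3)), "FL",
               ifelse(p == max(1, floor(n_patterns / 3)) + 1, "FL-DLBCL", "DLBCL"))
  dx[flip] <- sample(c("FL", "DLBCL", "FL-DLBCL"), sum(flip), replace = TRUE)
  coo <- ifelse(p <= ceiling(n_patterns * 0.7), "GCB", "ABC")
  coo_flip <- stats::runif(n) < 0.15
  coo[coo_flip] <- sample(c("GCB", "ABC", "unclassified"), sum(coo_flip), replace = TRUE)
  mc <- sprintf("MC%d", p)
  mc[flip] <- sprintf("MC%d", sample.int(n_patterns, sum(flip), replace = TRUE))
  validate_annotation(tibble(
    sample_id = names(p),
    diagnosis = dx,
    coo = coo,
    age = round(stats::runif(n, 35, 85)),
    bcl2_rearranged = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.6, 0.4)),
    bcl6_rearranged = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.2, 0.8)),
    tcc = round(unname(tcc), 4),
    mutational_cluster = mc
  ))
}

#' Synthetic epiCMIT CpG lists keyed to a planted truth
#'
#' Picks hyper-list CpGs from the planted module with the highest mean
#' tumor-intrinsic methylation and hypo-list CpGs from the lowest, so the
#' resulting mitotic-clock components track the planted structure. Intended
#' for testing the scorer; the published epiCMIT lists are user-supplied
#' configuration in real analyses.
#'
#' @param truth A `synthetic_truth` object from [simulate_cohort()].
#' @param n_each CpGs per list (default 20).
#' @param seed Integer seed.
#' @return A list with character vectors `hyper` and `hypo`.
#' @export
synthetic_epicmit_lists <- function(truth, n_each = 20, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mod_mean <- rowMeans(truth$mu)
  hi <- which.max(mod_mean); lo <- which.min(mod_mean)
  with_seed(seed, {
    pick <- function(m) {
      ids <- names(truth$module_of_cpg)[truth$module_of_cpg == m]
      sample(ids, min(n_each, length(ids)))
    }
    list(hyper = pick(hi), hypo = pick(lo))
  })
}
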