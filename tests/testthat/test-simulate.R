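test_that("mix_tumor_bystander is the TCC-weighted average and validates inputs", {
  expect_equal(mix_tumor_bystander(0.8, 0.1, 1.0), 0.8)
  expect_equal(mix_tumor_bystander(0.8, 0.1, 0.0), 0.1)
  expect_equal(mix_tumor_bystander(0.8, 0.2, 0.5), 0.5)
  expect_error(mix_tumor_bystander(1.2, 0.1, 0.5), "\\[0, 1\\]")
  expect_error(mix_tumor_bystander(0.8, 0.1, -0.1), "\\[0, 1\\]")
  # strict monotonicity in tcc when tumor > bystander
  tcc <- seq(0, 1, by = 0.1)
  expect_true(all(diff(mix_tumor_bystander(0.9, 0.2, tcc)) > 0))
})

test_that("simulated cohorts are reproducible, bounded and correctly shaped", {
  a <- simulate_cohort(n_cpgs = 100, n_samples = 20, n_modules = 2,
                       n_patterns = 3, seed = 5)
  b <- simulate_cohort(n_cpgs = 100, n_samples = 20, n_modules = 2,
                       n_patterns = 3, seed = 5)
  c <- simulate_cohort(n_cpgs = 100, n_samples = 20, n_modules = 2,
                       n_patterns = 3, seed = 6)
  expect_identical(a$beta, b$beta)
  expect_identical(a$truth$mu, b$truth$mu)
  expect_false(identical(a$beta, c$beta))

  m <- as_beta_matrix(a$beta)
  expect_identical(dim(m), c(100L, 20L))
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(table(a$truth$pattern_of_sample) >= 1))
  expect_true(all(a$truth$tcc_of_sample >= 0 & a$truth$tcc_of_sample <= 1))
  expect_true(all(a$truth$mu >= 0 & a$truth$mu <= 1))
  # every structured CpG in exactly one module, nuisance flagged 0
  expect_true(all(a$truth$module_of_cpg %in% 0:2))
})

test_that("noise-free, full-tumor cohorts reproduce the planted means", {
  sim <- simulate_cohort(n_cpgs = 80, n_samples = 21, n_modules = 2,
                         n_patterns = 3, frac_structured = 0.5,
                         tcc_range = c(1, 1), precision = 1e6, seed = 3)
  m <- as_beta_matrix(sim$beta)
  tr <- sim$truth
  for (cg in names(tr$module_of_cpg)[tr$module_of_cpg > 0]) {
    mod <- tr$module_of_cpg[[cg]]
    expected <- tr$mu[mod, tr$pattern_of_sample[colnames(m)]]
    expect_equal(unname(m[cg, ]), unname(expected), tolerance = 2e-3)
  }
})

test_that("full bystander dilution erases between-pattern differences", {
  sim <- simulate_cohort(n_cpgs = 200, n_samples = 40, n_modules = 2,
                         n_patterns = 2, frac_structured = 0.5,
                         tcc_range = c(0, 0), precision = 1e5, seed = 3)
  m <- as_beta_matrix(sim$beta)
  tr <- sim$truth
  struct <- names(tr$module_of_cpg)[tr$module_of_cpg > 0]
  # every structured CpG sits at its bystander level in every sample
  expect_equal(unname(rowMeans(m[struct, ])),
               unname(tr$bystander_profile[struct]), tolerance = 5e-3)
  p1 <- names(tr$pattern_of_sample)[tr$pattern_of_sample == 1]
  p2 <- names(tr$pattern_of_sample)[tr$pattern_of_sample == 2]
  gap <- abs(rowMeans(m[struct, p1]) - rowMeans(m[struct, p2]))
  expect_lt(max(gap), 0.01)
})

test_that("planted mu separates every pattern pair and every module has contrast", {
  sim <- simulate_cohort(n_cpgs = 60, n_samples = 30, seed = 9,
                         n_modules = 4, n_patterns = 7)
  mu <- sim$truth$mu
  for (p in 1:6) for (q in (p + 1):7) {
    expect_gte(max(abs(mu[, p] - mu[, q])), 0.25)
  }
  expect_true(all(apply(mu, 1, function(x) diff(range(x))) >= 0.5))
})

test_that("structured CpGs carry more between-pattern signal than nuisance", {
  sim <- small_cohort()
  m <- as_beta_matrix(sim$beta)
  tr <- sim$truth
  pat <- tr$pattern_of_sample[colnames(m)]
  between_var <- apply(m, 1, function(row) stats::var(tapply(row, pat, mean)))
  struct <- tr$module_of_cpg[rownames(m)] > 0
  thresh <- stats::quantile(between_var[!struct], 0.99)
  expect_gte(mean(between_var[struct] > thresh), 0.99)
})

test_that("degenerate simulation requests error", {
  expect_error(simulate_cohort(n_samples = 5, n_patterns = 9), "n_patterns")
  expect_error(simulate_cohort(tcc_range = c(0.9, 0.2)), "tcc_range")
  expect_error(simulate_cohort(frac_structured = 0), "frac_structured")
  expect_error(simulate_cohort(precision = -1), "precision")
})

test_that("synthetic epiCMIT lists point at the extreme planted modules", {
  sim <- small_cohort()
  lists <- synthetic_epicmit_lists(sim$truth, n_each = 10, seed = 2)
  mod <- sim$truth$module_of_cpg
  hi <- which.max(rowMeans(sim$truth$mu))
  lo <- which.min(rowMeans(sim$truth$mu))
  expect_true(all(mod[lists$hyper] == hi))
  expect_true(all(mod[lists$hypo] == lo))
})
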