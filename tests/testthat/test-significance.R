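test_that("hypergeometric overlap p matches exhaustive enumeration", {
  u <- letters[1:10]
  # identical 5-sets in a 10-universe: exactly 1/252
  expect_equal(hypergeometric_overlap_p(u[1:5], u[1:5], u), 1 / 252)
  expect_equal(enum_hyper_p(5, 5, 10, 5), 1 / 252)

  # random instances across universe sizes up to 12
  set.seed(31)
  for (i in 1:12) {
    n_u <- sample(4:12, 1)
    uni <- paste0("x", seq_len(n_u))
    a <- sample(uni, sample(1:n_u, 1))
    b <- sample(uni, sample(1:n_u, 1))
    k <- length(intersect(a, b))
    expect_equal(
      hypergeometric_overlap_p(a, b, uni),
      enum_hyper_p(length(a), length(b), n_u, k),
      tolerance = 1e-12
    )
  }

  # zero overlap is never evidence; a full-universe set always overlaps
  expect_equal(hypergeometric_overlap_p(letters[1:3], letters[4:6], letters[1:10]), 1)
  expect_equal(hypergeometric_overlap_p(letters[1:10], letters[2:4], letters[1:10]), 1)
  expect_error(hypergeometric_overlap_p(c("zz"), letters[1:2], letters[1:5]), "subsets")
})

test_that("coherence permutation p behaves at the degenerate and planted extremes", {
  const <- matrix(0.4, 12, 10,
                  dimnames = list(sprintf("cg%02d", 1:12), sprintf("S%02d", 1:10)))
  p <- coherence_permutation_p(rownames(const)[1:4], colnames(const)[1:3],
                               const, n_perm = 99, seed = 1)
  expect_equal(p, 1)

  # planted constant block in uniform noise is detected
  set.seed(12)
  V <- matrix(runif(900), 30, 30,
              dimnames = list(sprintf("cg%02d", 1:30), sprintf("S%02d", 1:30)))
  V[1:5, 1:5] <- 0.9
  p2 <- coherence_permutation_p(rownames(V)[1:5], colnames(V)[1:5], V,
                                n_perm = 999, seed = 7)
  expect_lte(p2, 0.01)

  # add-one rule with a single permutation
  p3 <- coherence_permutation_p(rownames(V)[1:5], colnames(V)[1:5], V,
                                n_perm = 1, seed = 3)
  expect_true(p3 %in% c(0.5, 1))

  expect_error(
    coherence_permutation_p(c("nope"), colnames(V)[1:2], V, n_perm = 9),
    "must index"
  )
})

test_that("consensus biclustering recovers planted structure at small scale", {
  sim <- small_cohort()
  m <- as_beta_matrix(sim$beta)
  sel <- select_top_variable(sim$beta, 300)
  red <- reduce_by_kmeans(sim$beta, sel, n_clusters = 60, target_reps = 120,
                          seed = 3, n_init = 3)
  reps <- red$cpg_id[red$is_representative]
  cons <- consensus_biclustering(m[reps, ], ranks = 3:6, seeds = 3,
                                 n_perm = 199, master_seed = 11)
  struct <- names(sim$truth$module_of_cpg)[sim$truth$module_of_cpg > 0]
  cand <- intersect(struct, reps)
  tp <- length(intersect(cons$significant_cpgs, cand))
  expect_gte(tp / length(cons$significant_cpgs), 0.9)   # precision
  expect_gte(tp / length(cand), 0.8)                    # recall among candidates
  # SignificantSet invariants
  expect_true(all(cons$significant_cpgs %in% reps))
  expect_true(all(cons$significant_samples %in% colnames(m)))
  sig <- dplyr::filter(cons$biclusters, significant)
  expect_true(all(sig$p_consensus <= 0.01 & sig$p_coherence <= 0.01 &
                    sig$consensus_support >= 0.5))
})

test_that("consensus is deterministic given the master seed", {
  sim <- small_cohort()
  V <- as_beta_matrix(sim$beta)[1:80, 1:30]
  c1 <- suppressWarnings(consensus_biclustering(V, ranks = 2:3, seeds = 2,
                                                n_perm = 49, master_seed = 5))
  c2 <- suppressWarnings(consensus_biclustering(V, ranks = 2:3, seeds = 2,
                                                n_perm = 49, master_seed = 5))
  expect_identical(c1$biclusters, c2$biclusters)
  expect_identical(c1$significant_cpgs, c2$significant_cpgs)
})

test_that("raising support_min never enlarges the significant set", {
  sim <- small_cohort()
  m <- as_beta_matrix(sim$beta)
  V <- m[1:200, ]
  lo <- suppressWarnings(consensus_biclustering(V, ranks = 3:4, seeds = 3,
          n_perm = 99, support_min = 0.3, master_seed = 2))
  hi <- suppressWarnings(consensus_biclustering(V, ranks = 3:4, seeds = 3,
          n_perm = 99, support_min = 0.8, master_seed = 2))
  expect_true(all(hi$significant_cpgs %in% lo$significant_cpgs))
  expect_true(all(hi$significant_samples %in% lo$significant_samples))
})

test_that("rank-1 sweeps and all-noise inputs degrade gracefully", {
  set.seed(20)
  V <- matrix(rbeta(600, 25, 25), 30, 20,
              dimnames = list(sprintf("cg%02d", 1:30), sprintf("S%02d", 1:20)))
  res <- suppressWarnings(
    consensus_biclustering(V, ranks = 1, seeds = 3, n_perm = 49, master_seed = 1)
  )
  expect_s3_class(res, "consensus_biclusters")
  expect_lte(nrow(tidy(res)), 1)
  expect_error(consensus_biclustering(V, ranks = integer(0)), "non-empty")
  expect_error(consensus_biclustering(V, ranks = 2, seeds = 1), "at least 2")
})
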