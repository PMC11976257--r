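test_that("exact Wilcoxon p-values match full enumeration up to n = 6", {
  df <- data.frame(x = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  res <- pairwise_wilcoxon(df, x, g)
  expect_equal(res$p_raw, 1 / 3)
  expect_identical(res$method, "wilcoxon_exact")

  set.seed(17)
  for (i in 1:10) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    vals <- sample(seq_len(40), na + nb)  # distinct => no ties
    df <- data.frame(v = vals, g = rep(c("a", "b"), c(na, nb)))
    res <- pairwise_wilcoxon(df, v, g)
    expect_equal(res$p_raw, enum_wilcoxon_p(vals[1:na], vals[-(1:na)]),
                 tolerance = 1e-12)
  }
})

test_that("ties fall back to the corrected normal approximation", {
  df <- data.frame(v = c(5, 5, 5, 5, 5, 5), g = rep(c("a", "b"), each = 3))
  res <- pairwise_wilcoxon(df, v, g)
  expect_equal(res$p_raw, 1)
  expect_identical(res$method, "wilcoxon_normal")
})

test_that("pairwise families are bookkept and adjusted per Bonferroni", {
  set.seed(3)
  df <- data.frame(v = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
  res <- pairwise_wilcoxon(df, v, g)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$m == 3))
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_raw))

  df2 <- rbind(df, data.frame(v = 1, g = "tiny"))
  expect_warning(res2 <- pairwise_wilcoxon(df2, v, g), "tiny")
  expect_identical(nrow(res2), 3L)

  expect_error(pairwise_wilcoxon(df[df$g == "a", ], v, g), "at least 2 groups")
})

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.01, 0.2, 0.3, 0.4, 0.02))[1], 0.05)
  expect_equal(bonferroni_adjust(c(0.5, 0.1, 0.2))[1], 1)
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fisher enrichment matches hand-computed odds ratios and enumeration", {
  sym <- fisher_enrichment(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_raw, 1)

  diag <- fisher_enrichment(matrix(c(10, 0, 0, 10), 2), haldane = TRUE)
  expect_equal(diag$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))  # 441
  expect_equal(diag$p_raw, 2 / choose(20, 10))
  expect_equal(diag$p_raw, enum_fisher_p(matrix(c(10, 0, 0, 10), 2)))

  # symmetry in the p-value, inversion of the OR under a row swap
  tab <- matrix(c(7, 2, 3, 9), 2)
  a <- fisher_enrichment(tab); b <- fisher_enrichment(tab[2:1, ])
  expect_equal(a$p_raw, b$p_raw)
  expect_equal(a$odds_ratio, 1 / b$odds_ratio)
  expect_equal(a$p_raw, enum_fisher_p(tab), tolerance = 1e-12)

  expect_error(fisher_enrichment(matrix(c(1, 2, 3, -1), 2)), "nonnegative")
  expect_error(fisher_enrichment(matrix(c(1, 2, 3, 1.5), 2)), "integer")
})

test_that("epiCMIT scores hit the saturation and arithmetic cases", {
  m <- matrix(c(1, 1, 0.4, 0.4, 0, 0.7), 6, 1,
              dimnames = list(c("h1", "h2", "a1", "a2", "l1", "l2"), "S1"))
  sat_hyper <- epicmit_score(m, hyper_list = c("h1", "h2"), hypo_list = "l2")
  expect_equal(sat_hyper$hyper_component, 1)
  expect_equal(sat_hyper$score, 1)

  sat_hypo <- epicmit_score(m, hyper_list = "a1", hypo_list = "l1")
  expect_equal(sat_hypo$hypo_component, 1)
  expect_equal(sat_hypo$score, 1)

  mid <- epicmit_score(m, hyper_list = c("a1", "a2"), hypo_list = "l2")
  expect_equal(mid$hyper_component, 0.4)
  expect_equal(mid$hypo_component, 0.3)
  expect_equal(mid$score, 0.4)

  expect_warning(
    part <- epicmit_score(m, hyper_list = c("a1", "missing"), hypo_list = "l2"),
    "absent"
  )
  expect_equal(part$hyper_component, 0.4)
  expect_error(
    suppressWarnings(epicmit_score(m, hyper_list = "nope", hypo_list = "nada")),
    "entirely absent"
  )
})

test_that("epiCMIT is monotone in hyper betas and antitone in hypo betas", {
  set.seed(23)
  for (i in 1:5) {
    v <- runif(8)
    m <- matrix(v, 8, 1, dimnames = list(sprintf("c%d", 1:8), "S1"))
    hyper <- sprintf("c%d", 1:4); hypo <- sprintf("c%d", 5:8)
    base <- epicmit_score(m, hyper, hypo)$score
    up <- m; up[1, 1] <- min(1, up[1, 1] + 0.2)
    expect_gte(epicmit_score(up, hyper, hypo)$score, base)
    down <- m; down[5, 1] <- min(1, down[5, 1] + 0.2)
    expect_lte(epicmit_score(down, hyper, hypo)$score, base)
  }
})

test_that("group beta summaries match direct recomputation", {
  const <- matrix(0.3, 4, 3,
                  dimnames = list(sprintf("c%d", 1:4), sprintf("S%d", 1:3)))
  s <- group_beta_summary(const, rownames(const), rep("g", 3))
  expect_equal(s$median, 0.3); expect_equal(s$min, 0.3); expect_equal(s$max, 0.3)

  two <- matrix(c(0.2, 0.2, 0.6, 0.6), 2, 2,
                dimnames = list(c("c1", "c2"), c("S1", "S2")))
  s2 <- group_beta_summary(two, c("c1", "c2"), c("g", "g"))
  expect_equal(s2$median, 0.4)

  set.seed(9)
  m <- matrix(runif(60), 10, 6,
              dimnames = list(sprintf("c%d", 1:10), sprintf("S%d", 1:6)))
  g <- rep(c("a", "b"), each = 3)
  s3 <- group_beta_summary(m, sprintf("c%d", 1:5), g)
  med <- apply(m[1:5, ], 2, median)
  expect_equal(s3$median[s3$group == "a"], median(med[1:3]))
  expect_equal(s3$max[s3$group == "b"], max(med[4:6]))
  expect_error(group_beta_summary(m, character(0), g), "empty")
})
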