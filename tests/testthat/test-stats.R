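# Nonparametric statistics against enumeration oracles, hand examples and
# the base-R implementations as independent cross-checks.

test_that("Mann-Whitney exact branch equals the permutation oracle", {
  set.seed(13)
  for (rep in 1:15) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    vals <- sample(1000, nx + ny)                   # no ties anywhere
    x <- vals[seq_len(nx)]; y <- vals[nx + seq_len(ny)]
    res <- mann_whitney(x, y)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
    expect_gt(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("Mann-Whitney hand examples and degenerate cases", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)          # 2 / choose(6, 3)
  same <- mann_whitney(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  # ties route to the corrected normal approximation, matching wilcox.test
  x <- c(1, 1, 2, 3, 5); y <- c(2, 3, 3, 4, 6)
  res2 <- mann_whitney(x, y)
  expect_false(res2$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("Freeman-Halton equals the brute-force enumeration oracle", {
  set.seed(14)
  for (rep in 1:20) {
    dims <- if (rep %% 2) c(2, 2) else c(3, 2)
    repeat {
      tb <- matrix(rpois(prod(dims), 3), dims[1], dims[2])
      if (sum(tb) >= 1 && sum(tb) <= 30 && all(rowSums(tb) > 0) &&
          all(colSums(tb) > 0)) break
    }
    got <- fisher_exact_rxc(tb)$p_value
    expect_equal(got, oracle_fisher_p(tb), tolerance = 1e-10)
    expect_equal(got, stats::fisher.test(tb)$p.value, tolerance = 1e-6)
  }
})

test_that("Fisher exact r x c hand examples", {
  expect_equal(round(fisher_exact_rxc(matrix(c(1, 9, 16, 9), 2))$p_value, 4),
               0.0072)
  expect_equal(round(fisher_exact_rxc(matrix(c(2, 4, 3, 1), 2))$p_value, 4),
               0.5238)
  expect_equal(fisher_exact_rxc(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2,
                                       dimnames = NULL)), "margins")
  expect_error(contingency_table(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("Fisher exact is invariant to row/column permutation and transpose", {
  set.seed(15)
  for (rep in 1:8) {
    tb <- matrix(rpois(6, 4) + 1, 3, 2)
    p0 <- fisher_exact_rxc(tb)$p_value
    expect_equal(fisher_exact_rxc(tb[sample(3), ])$p_value, p0,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_rxc(tb[, 2:1])$p_value, p0,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_rxc(t(tb))$p_value, p0, tolerance = 1e-12)
  }
})

test_that("Monte Carlo fallback engages above the enumeration cap", {
  tb <- matrix(c(8, 12, 10, 9, 11, 7), 3, 2)
  exact <- fisher_exact_rxc(tb)
  mc <- fisher_exact_rxc(tb, max_tables = 10, mc_draws = 20000, mc_seed = 4)
  expect_true(exact$exact)
  expect_false(mc$exact)
  expect_equal(mc$p_value, exact$p_value, tolerance = 0.05)
  mc2 <- fisher_exact_rxc(tb, max_tables = 10, mc_draws = 20000, mc_seed = 4)
  expect_identical(mc$p_value, mc2$p_value)   # seeded, reproducible
})

test_that("Kruskal-Wallis H and Dunn post hoc behave per contract", {
  k <- kruskal_wallis_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6),
                                c = c(7, 8, 9)), dunn_alpha = 1)
  expect_equal(k$omnibus$statistic, 7.2)
  ref <- stats::kruskal.test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(k$omnibus$p_value, ref$p.value, tolerance = 1e-12)
  # identical groups: their Dunn-adjusted p is 1 and z is 0
  k2 <- kruskal_wallis_dunn(list(a = c(1, 5, 9), b = c(1, 5, 9),
                                 c = c(20, 21, 22)), dunn_alpha = 1)
  ab <- k2$pairwise[k2$pairwise$group1 == "a" & k2$pairwise$group2 == "b", ]
  expect_equal(ab$z, 0)
  expect_equal(ab$p_adjusted, 1)
  # adjusted never below unadjusted
  expect_true(all(k2$pairwise$p_adjusted >= k2$pairwise$p_unadjusted - 1e-15))
  # all-identical data: H = 0, p = 1
  k3 <- kruskal_wallis_dunn(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(k3$omnibus$statistic, 0)
  expect_equal(k3$omnibus$p_value, 1)
  # tie correction matches base R on tied data
  g <- list(c(1, 2, 2, 3), c(2, 3, 3, 4), c(4, 4, 5, 6))
  expect_equal(kruskal_wallis_dunn(g)$omnibus$statistic,
               unname(stats::kruskal.test(g)$statistic), tolerance = 1e-12)
})

test_that("Spearman hand example, invariance, and edge cases", {
  res <- spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$statistic, 0.8)
  expect_equal(spearman(1:10, (1:10)^3)$statistic, 1)
  # invariant under strictly increasing transforms
  set.seed(16)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman(x, y)$statistic, spearman(exp(x), y)$statistic)
  expect_equal(spearman(x, y)$statistic,
               spearman(x, qlogis(plogis(y)))$statistic)
  # agrees with base R (tie-aware) including p
  x2 <- c(1, 2, 2, 3, 5, 5, 7); y2 <- c(2, 1, 4, 4, 6, 8, 9)
  ref <- suppressWarnings(stats::cor.test(x2, y2, method = "spearman"))
  expect_equal(spearman(x2, y2)$statistic, unname(ref$estimate))
  # zero variance flagged
  flat <- spearman(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(flat$statistic))
  expect_match(flat$note, "zero variance")
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(17)
  df <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  df$d <- df$a + rnorm(15, 0, 0.1)
  cm <- correlation_matrix(df)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 4))
  expect_true(all(abs(cm$rho) <= 1 + 1e-12))
  expect_gt(cm$rho["a", "d"], 0.9)
})

test_that("inter-rater agreement behaves on identical, relabeled, constant raters", {
  s <- cbind(r1 = c(1, 2, 3, 2, 1), r2 = c(1, 2, 3, 2, 1))
  expect_equal(interrater_agreement(s)$rho, 1)
  # monotone relabeling (1,2,3) -> (1,3,3) keeps rank order up to ties
  s2 <- cbind(r1 = c(1, 2, 3, 2, 1), r2 = c(1, 3, 3, 3, 1))
  rho <- interrater_agreement(s2)$rho
  expect_equal(rho, spearman(s2[, 1], s2[, 2])$statistic)
  expect_gt(rho, 0.9)
  # constant rater flagged undefined
  s3 <- cbind(r1 = c(1, 2, 3), r2 = c(2, 2, 2))
  res <- interrater_agreement(s3)
  expect_true(is.na(res$rho))
  expect_match(res$note, "zero variance")
})

test_that("highly concordant synthetic raters give rho >= 0.7 throughout", {
  co <- generate_cohort(cohort_spec(seed = 18, rater_sd = 0.3))
  sc <- co$subjects[, grep("^score_rater", names(co$subjects))]
  res <- interrater_agreement(sc)
  expect_true(all(res$rho >= 0.7))
})
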