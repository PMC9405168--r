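test_that("Kruskal-Wallis matches the hand-evaluated rank formula", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE))
})

test_that("degenerate and invalid group sets are rejected", {
  expect_error(kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5))), "degenerate")
  expect_error(kruskal_wallis(list(c(1, 2))), "at least 2 groups")
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))),
               "at least one observation")
})

test_that("the statistic is invariant under strictly increasing transforms", {
  set.seed(31)
  for (i in 1:10) {
    g <- replicate(3, sample(1:6, 8, replace = TRUE), simplify = FALSE)
    h1 <- kruskal_wallis(g)$H
    h2 <- kruskal_wallis(lapply(g, function(v) exp(v) + 7))$H
    expect_equal(h1, h2)
  }
})

test_that("the tie-corrected H agrees with the reference implementation", {
  set.seed(17)
  for (i in 1:10) {
    g <- replicate(4, sample(seq(0, 3, by = 0.5), 12, replace = TRUE),
                   simplify = FALSE)
    ours <- kruskal_wallis(g)
    ref <- stats::kruskal.test(g)
    expect_equal(ours$H, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
  }
})

test_that("two-group Kruskal-Wallis is equivalent to the rank-sum oracle", {
  set.seed(41)
  for (i in 1:10) {
    a <- sample(seq(1, 10, by = 0.5), 9, replace = TRUE)
    b <- sample(seq(1, 10, by = 0.5), 7, replace = TRUE)
    if (length(unique(c(a, b))) < 2) next
    kw <- kruskal_wallis(list(a, b))
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(kw$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Dunn Z values match the mean-rank formula and are antisymmetric", {
  d <- dunn_posthoc(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(d$Z, -2 / sqrt(5 / 3), tolerance = 1e-12)  # mean ranks 1.5, 3.5

  set.seed(43)
  g <- list(a = stats::runif(6), b = stats::runif(5), c = stats::runif(7))
  fwd <- dunn_posthoc(g)
  rev <- dunn_posthoc(g[c("b", "a", "c")])
  zab <- fwd$Z[fwd$group_a == "a" & fwd$group_b == "b"]
  zba <- rev$Z[rev$group_a == "b" & rev$group_b == "a"]
  expect_equal(zba, -zab)
})

test_that("multiplicity adjustment never shrinks a p value", {
  set.seed(47)
  g <- replicate(4, sample(1:5, 10, replace = TRUE), simplify = FALSE)
  for (adj in c("bonferroni", "holm")) {
    d <- dunn_posthoc(g, adjust = adj)
    expect_true(all(d$p_adjusted >= d$p_raw - 1e-15))
  }
  d0 <- dunn_posthoc(g, adjust = "none")
  expect_equal(d0$p_adjusted, d0$p_raw)
  expect_equal(nrow(d0), choose(4, 2))
})

test_that("the normality gate has the advertised operating characteristics", {
  normal_flags <- logical(100)
  expo_flags <- logical(100)
  for (i in 1:100) {
    set.seed(1000 + i)
    normal_flags[i] <- normality_check(stats::rnorm(500))$is_normal
    expo_flags[i] <- normality_check(stats::rexp(500))$is_normal
  }
  expect_gte(mean(normal_flags), 0.90)
  expect_lte(mean(expo_flags), 0.01)
  expect_error(normality_check(c(1, 2)), "between 3 and 5000")
})

test_that("significance codes follow the printed threshold map", {
  expect_equal(significance_code(0.00005), "****")
  expect_equal(significance_code(0.0005), "***")
  expect_equal(significance_code(0.005), "**")
  expect_equal(significance_code(0.03), "*")
  expect_equal(significance_code(0.5), "ns")
  expect_equal(significance_code(0.05), "ns")  # exactly 0.05 is not starred
  expect_equal(significance_code(c(0, 1)), c("****", "ns"))
  expect_error(significance_code(1.2), "\\[0, 1\\]")
})
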