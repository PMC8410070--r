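# Self-implemented rank tests against brute-force and reference oracles,
# Bonferroni, fold-change, and correlation matrices.

test_that("rank-sum handles the closed-form and degenerate cases", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p_value, 2 / 6)
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5))$p_value, 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(rank_sum_test(numeric(), 1), "nonempty")
  t <- rank_sum_test(1:3, 4:6)
  expect_identical(t$method, "exact")
  expect_equal(t$n1 + t$n2, 6)
})

test_that("exact rank-sum equals the brute-force oracle on tied data", {
  set.seed(7)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:3, n1, replace = TRUE)
    y <- sample(0:3, n2, replace = TRUE)
    expect_equal(rank_sum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 info = paste("rep", rep))
  }
})

test_that("exact rank-sum matches wilcox.test on untied data", {
  set.seed(8)
  for (rep in 1:10) {
    x <- rnorm(sample(3:7, 1)); y <- rnorm(sample(3:7, 1)) + runif(1, -1, 1)
    expect_equal(rank_sum_test(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("signed-rank handles closed-form and degenerate cases", {
  expect_equal(signed_rank_test(rep(0, 5), rep(1, 5))$p_value, 2 / 32)
  z <- signed_rank_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$p_value, 1)
  expect_equal(z$n_informative, 0L)
  expect_equal(signed_rank_test(c(0, 0), c(1, 0))$n_zero, 1)
  expect_error(signed_rank_test(1:3, 1:4), "equal length")
})

test_that("exact signed-rank equals the sign-flip oracle on tied scores", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    before <- sample(0:2, n, replace = TRUE)   # semiquantitative 0-2 scale
    after <- sample(0:2, n, replace = TRUE)
    expect_equal(signed_rank_test(before, after)$p_value,
                 oracle_signedrank_p(before, after),
                 info = paste("rep", rep))
  }
})

test_that("exact signed-rank matches wilcox.test on untied differences", {
  set.seed(10)
  for (rep in 1:8) {
    b <- rnorm(sample(5:12, 1)); a <- b + rnorm(length(b))
    expect_equal(signed_rank_test(b, a)$p_value,
                 stats::wilcox.test(a, b, paired = TRUE,
                                    exact = TRUE)$p.value)
  }
})

test_that("normal approximations sit close to exact p-values", {
  # tie-bearing integer scores at sizes just beyond the exact-mode default;
  # under extreme tie lumping (alphabet of ~5 values at n ~ 12) no continuous
  # approximation can track the exact p, whose jumps then exceed 0.04
  set.seed(11)
  for (rep in 1:50) {
    x <- sample(0:25, sample(10:14, 1), replace = TRUE)
    y <- sample(0:25, sample(10:14, 1), replace = TRUE)
    d <- abs(rank_sum_test(x, y, method = "normal_approx")$p_value -
               rank_sum_test(x, y, method = "exact")$p_value)
    expect_lt(d, 0.02)
    n <- sample(20:26, 1)
    b <- sample(0:25, n, replace = TRUE); a <- sample(0:25, n, replace = TRUE)
    d2 <- abs(signed_rank_test(b, a, method = "normal_approx")$p_value -
                signed_rank_test(b, a, method = "exact")$p_value)
    expect_lt(d2, 0.02)
  }
})

test_that("Bonferroni adjustment clamps, scales and stays monotone", {
  expect_equal(adjust_bonferroni(0.01, 10), 0.10)
  expect_equal(adjust_bonferroni(0.5, 10), 1.0)
  expect_equal(adjust_bonferroni(c(0.1, 0.02), 2), p.adjust(c(0.1, 0.02),
                                                            "bonferroni"))
  set.seed(12)
  p <- runif(50)
  expect_true(all(adjust_bonferroni(p) >= p))
  expect_error(adjust_bonferroni(c(0.1, 0.2), 1), "m must be")
  expect_error(adjust_bonferroni(1.2), "\\[0, 1\\]")
})

test_that("log fold-change has the closed form and is antisymmetric", {
  expect_equal(log_fold_change(5, 5), 0)
  expect_equal(log_fold_change(exp(1) - 1, 0), 1)
  set.seed(13)
  a <- runif(20, 0, 10); b <- runif(20, 0, 10)
  expect_equal(log_fold_change(a, b), -log_fold_change(b, a))
})

test_that("correlation matrices are symmetric, unit-diagonal and bounded", {
  set.seed(14)
  n <- 500
  f <- rnorm(n)
  x <- rbind(X1 = sqrt(0.5) * f + sqrt(0.5) * rnorm(n),
             X2 = sqrt(0.5) * f + sqrt(0.5) * rnorm(n),
             NEG = -(sqrt(0.5) * f + sqrt(0.5) * rnorm(n)),
             FLAT = rep(1, n))
  colnames(x) <- sprintf("C%03d", seq_len(n))
  expect_warning(cm <- correlation_matrix(x, c("X1", "X2", "NEG", "FLAT",
                                               "ABSENT")),
                 "ABSENT")
  expect_identical(cm$excluded_zero_variance, "FLAT")
  r <- cm$r
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_true(all(r >= -1 & r <= 1))
  # planted r = 0.5 recovered within 0.1
  expect_lt(abs(r["X1", "X2"] - 0.5), 0.1)
  exact <- rbind(A = c(1, 2, 3, 4), B = -c(1, 2, 3, 4))
  colnames(exact) <- paste0("C", 1:4)
  expect_equal(correlation_matrix(exact, c("A", "B"))$r["A", "B"], -1)
  expect_error(correlation_matrix(x, c("X1", "FLAT")), "fewer than 2")
})

test_that("vectorized scan reproduces the scalar normal-approximation test", {
  set.seed(15)
  values <- matrix(rpois(40 * 60, 1.5), 40, 60)
  values <- log1p(values)
  rownames(values) <- sprintf("G%02d", 1:40)
  colnames(values) <- sprintf("C%02d", 1:60)
  ind <- rep(c(TRUE, FALSE), 30)
  pre <- ecatlas:::rank_precompute(values)
  scan <- ecatlas:::ranksum_scan(pre, ind)
  for (g in c(1, 7, 23, 40)) {
    ref <- rank_sum_test(values[g, ind], values[g, !ind],
                         method = "normal_approx")
    expect_equal(scan$p_raw[g], ref$p_value)
  }
})
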