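test_that("rmse matches closed forms", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_equal(rmse(c(0.3, 0.4), c(0, 0)), sqrt(0.125))
  expect_error(rmse(numeric(), numeric()), "empty")
  expect_error(rmse(1:3, 1:4), "paired")
})

test_that("session table applies the 10-timepoint filter and matches a brute-force loop", {
  set.seed(2)
  prov <- data.frame(subject_id = rep(c("a", "a", "b"), c(9, 10, 25)),
                     session_id = rep(c("a1", "a2", "b1"), c(9, 10, 25)))
  obs <- rnorm(44, 37, 0.3)
  pred <- obs + rnorm(44, 0, 0.2)
  tab <- session_rmse_table(pred, obs, prov)
  expect_setequal(tab$session_id, c("a2", "b1"))     # 9-point session dropped
  excluded <- attr(tab, "excluded")
  expect_equal(excluded$session_id, "a1")
  expect_match(excluded$reason, "10")
  for (i in seq_len(nrow(tab))) {
    sel <- prov$session_id == tab$session_id[i]
    expect_equal(tab$rmse[i], sqrt(mean((pred[sel] - obs[sel])^2)))
  }
  # a timepoint with a missing prediction does not count as valid
  pred2 <- pred
  pred2[prov$session_id == "a2"][1] <- NA
  tab2 <- session_rmse_table(pred2, obs, prov)
  expect_false("a2" %in% tab2$session_id)
})

test_that("coverage counts inclusively and the curve is monotone for nested intervals", {
  iv <- data.frame(lower = c(36, 36, 36, 38), upper = c(38, 38, 38, 39))
  expect_equal(coverage(iv, c(37, 36, 38, 37.5)), 75)
  expect_equal(coverage(iv, rep(37.9, 4)), 75)
  expect_equal(coverage(iv[1:3, ], rep(50, 3)), 0)
  expect_error(coverage(iv[0, ], numeric()), "empty")

  # a perfectly calibrated oracle interval source tracks the identity
  set.seed(4)
  y <- rnorm(5000, 37, 0.4)
  y_hat <- rep(37, 5000)
  src <- function(lv) {
    q <- 0.4 * qnorm((1 + lv) / 2)      # true noise quantile
    data.frame(lower = y_hat - q, upper = y_hat + q)
  }
  curve <- coverage_curve(src, y, grid = seq(5, 95, by = 5))
  expect_true(all(abs(curve$coverage - curve$level) < 3))
  expect_true(all(diff(curve$coverage) >= 0))

  # degenerate zero-width intervals never cover continuous observations
  zero <- function(lv) data.frame(lower = y_hat, upper = y_hat)
  curve0 <- coverage_curve(zero, y)
  expect_true(all(curve0$coverage == 0))
})

test_that("coverage-curve AUC integrates the trapezoid exactly", {
  identity_curve <- data.frame(level = 0:100, coverage = 0:100)
  expect_identical(coverage_auc(identity_curve), 5000)
  expect_identical(coverage_auc(data.frame(level = 0:100,
                                           coverage = rep(100, 101))), 10000)
  expect_identical(coverage_auc(data.frame(level = 0:100,
                                           coverage = rep(0, 101))), 0)
  # linearity: halving the curve halves the area
  half <- data.frame(level = 0:100, coverage = (0:100) / 2)
  expect_equal(coverage_auc(half), 2500)
  # anchored 1-99 identity still integrates to 5000
  expect_equal(coverage_auc(data.frame(level = 1:99, coverage = 1:99)), 5000)
  expect_error(coverage_auc(data.frame(level = 10:99, coverage = 10:99),
                            anchor = FALSE), "span")
})

test_that("signed-rank test agrees with exhaustive enumeration and wilcox.test", {
  # all-positive differences {1..5}: two-sided exact p = 2/32
  expect_equal(paired_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value,
               0.0625)

  # enumeration oracle for n <= 10: all sign assignments of the ranks
  enum_p <- function(d) {
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), length(d)))
    Vs <- as.matrix(signs) %*% r
    2 * min(mean(Vs <= V), mean(Vs >= V))
  }
  set.seed(7)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.3, 1), 2)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    res <- paired_signed_rank(d, rep(0, length(d)))
    expect_equal(res$p_value, min(1, enum_p(d)), tolerance = 1e-12)
    # cross-check against the standard implementation
    expect_equal(res$p_value,
                 wilcox.test(d, alternative = "two.sided")$p.value,
                 tolerance = 1e-12)
  }

  # symmetry: swapping the paired vectors leaves p unchanged
  a <- c(0.31, 0.28, 0.45, 0.39, 0.33, 0.41)
  b <- c(0.35, 0.30, 0.40, 0.44, 0.37, 0.36)
  expect_equal(paired_signed_rank(a, b)$p_value,
               paired_signed_rank(b, a)$p_value)

  # identical vectors have no nonzero differences
  expect_error(paired_signed_rank(a, a), "nonzero")

  # large-n path uses the normal approximation
  set.seed(8)
  big_a <- rnorm(40); big_b <- big_a + rnorm(40, 0.2, 0.3)
  res_big <- paired_signed_rank(big_a, big_b)
  expect_match(res_big$method, "normal")
  expect_equal(res_big$p_value,
               wilcox.test(big_a, big_b, paired = TRUE, exact = FALSE,
                           correct = FALSE)$p.value, tolerance = 1e-10)
})

test_that("percent reduction reproduces the reported comparisons", {
  expect_equal(percent_reduction(0.35, 0.29), 17.1)
  expect_equal(percent_reduction(0.34, 0.29), 14.7)
  expect_equal(percent_reduction(0.42, 0.42), 0)
  expect_error(percent_reduction(0, 0.3), "positive")
})

test_that("residual summary grows with heteroscedastic bins", {
  pr <- oracle_pairs(20000, seed = 15)
  rs <- residual_summary(pr$y_hat, pr$y, edges = c(37.5, 38.5, 39.5))
  expect_equal(sum(rs$n), 20000)
  expect_gt(rs$sigma[nrow(rs)], rs$sigma[1])
})
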