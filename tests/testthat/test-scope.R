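test_that("stratum count follows the ceiling rule", {
  expect_identical(num_strata(23862, 1000), 24L)
  expect_identical(num_strata(1000, 1000), 1L)
  expect_identical(num_strata(1001, 1000), 2L)
  expect_identical(num_strata(1, 1), 1L)
  expect_error(num_strata(0, 1000), "positive")
  expect_error(num_strata(5000, 0), "positive")
})

test_that("nonconformity is the absolute residual", {
  expect_equal(nonconformity(38.0, 37.7), 0.3)
  expect_equal(nonconformity(37.0, 37.0), 0.0)
  expect_equal(nonconformity(c(36, 37), c(37, 36)), c(1, 1))  # symmetry
  expect_error(nonconformity(NA, 1), "finite")
})

test_that("stratum quantile matches the exhaustive order-statistic oracle", {
  scores <- seq(0.1, 0.9, by = 0.1)
  expect_equal(stratum_quantile(scores, 0.6827), 0.7)   # k = ceil(.6827*10)
  expect_equal(stratum_quantile(scores, 0.9973), 0.9)   # clamped to m
  expect_equal(stratum_quantile(rep(3.3, 5), c(0.1, 0.5, 0.99)),
               rep(3.3, 3))

  # oracle sweep: all m <= 50, the three sigma levels plus the median
  for (m in 1:50) {
    s <- sort(runif(m))
    for (g in c(0.5, 0.6827, 0.9545, 0.9973)) {
      k <- min(ceiling(g * (m + 1)), m)
      expect_identical(stratum_quantile(s, g), s[k])
      k_emp <- max(1, min(ceiling(g * m), m))
      expect_identical(stratum_quantile(s, g, convention = "empirical"),
                       s[k_emp])
    }
  }
  expect_error(stratum_quantile(numeric(), 0.5), "non-empty")
})

test_that("fitting builds balanced equal-frequency strata", {
  set.seed(5)
  y_hat <- rnorm(24000, 37.5, 0.8)
  y <- y_hat + rnorm(24000, 0, 0.2)
  tab <- fit_scope(y_hat, y, scope_config(density = 1000))
  expect_identical(tab$n_strata, 24L)
  expect_identical(sum(tab$counts), 24000L)
  expect_true(all(abs(tab$counts - 1000) <= 1))
  expect_false(is.unsorted(tab$edges))
  # quantiles non-decreasing in level within every stratum
  expect_true(all(apply(tab$quantiles, 1, function(q) !is.unsorted(q))))
  expect_true(all(tab$quantiles >= 0))
})

test_that("homoscedastic noise yields near-equal per-stratum quantiles", {
  set.seed(6)
  n <- 20000
  y <- rnorm(n, 37.5, 0.8)
  y_hat <- y + rnorm(n, 0, 0.25)
  tab <- fit_scope(y_hat, y, scope_config(density = 2000))
  q95 <- tab$quantiles[, heatscope:::format_level(0.9545)]
  # all strata estimate the same population quantile (0.25 * 2)
  expect_true(all(abs(q95 - 0.5) < 0.06))
})

test_that("heteroscedastic noise widens the top strata", {
  pr <- oracle_pairs(20000, seed = 8)
  tab <- fit_scope(pr$y_hat, pr$y, scope_config(density = 1000))
  q <- tab$quantiles[, heatscope:::format_level(0.9545)]
  expect_gt(q[tab$n_strata], 2 * q[1])
  # residual sigma diagnostic grows with the stratum as well
  expect_gt(tab$sigma[tab$n_strata], tab$sigma[1])
})

test_that("stratum assignment clamps and matches a brute-force binning oracle", {
  pr <- oracle_pairs(5000, seed = 9)
  tab <- fit_scope(pr$y_hat, pr$y, scope_config(density = 1000))
  expect_identical(assign_stratum(tab, min(pr$y_hat) - 5), 1L)
  expect_identical(assign_stratum(tab, max(pr$y_hat) + 5), tab$n_strata)
  expect_identical(assign_stratum(tab, tab$edges[2]), 3L)  # right-hand bin

  set.seed(10)
  probe <- runif(500, 34, 43)
  oracle <- vapply(probe, function(v) {
    i <- 1L
    for (e in tab$edges) if (v >= e) i <- i + 1L
    i
  }, 0L)
  expect_identical(assign_stratum(tab, probe), oracle)
  expect_error(assign_stratum(tab, NaN), "finite")
})

test_that("intervals are symmetric, nested across levels, and serialisable", {
  pr <- oracle_pairs(4000, seed = 11)
  tab <- fit_scope(pr$y_hat, pr$y, scope_config(density = 1000))
  iv68 <- predict_interval(tab, 37.0, 0.6827)
  iv95 <- predict_interval(tab, 37.0, 0.9545)
  expect_equal(iv68$y_hat - iv68$lower, iv68$upper - iv68$y_hat)
  expect_lte(iv95$lower, iv68$lower)
  expect_gte(iv95$upper, iv68$upper)
  # direct formula
  q <- stratum_quantile(tab$scores[[iv68$stratum]], 0.6827)
  expect_equal(iv68$lower, 37.0 - q)
  # off-grid levels recomputed from stored scores
  iv_odd <- predict_interval(tab, 37.0, 0.777)
  q_odd <- stratum_quantile(tab$scores[[iv_odd$stratum]], 0.777)
  expect_equal(iv_odd$upper - iv_odd$y_hat, q_odd)

  # JSON round trip preserves interval construction exactly
  js <- scope_to_json(tab)
  tab2 <- scope_from_json(js)
  probe <- seq(35, 42, by = 0.25)
  for (lv in c(0.6827, 0.9545, 0.777))
    expect_equal(predict_interval(tab2, probe, lv),
                 predict_interval(tab, probe, lv))
})

test_that("single-stratum fallback reduces to unstratified conformal prediction", {
  pr <- oracle_pairs(1500, seed = 12)
  expect_warning(tab <- fit_scope(pr$y_hat, pr$y,
                                  scope_config(density = 1000)),
                 "one stratum")
  expect_identical(tab$n_strata, 1L)
  big_d <- fit_scope(pr$y_hat, pr$y, scope_config(density = 5000))
  expect_identical(big_d$n_strata, 1L)
  # identical to the plain ICP quantile on all scores
  eps <- sort(nonconformity(pr$y_hat, pr$y))
  expect_equal(predict_interval(big_d, 37, 0.9545)$upper - 37,
               eps[ceiling(0.9545 * (length(eps) + 1))])
})

test_that("marginal coverage meets the nominal level on exchangeable data", {
  for (seed in c(21, 22)) {
    pr <- oracle_pairs(15000, seed = seed)
    cal <- 1:5000; ev <- 5001:15000
    tab <- fit_scope(pr$y_hat[cal], pr$y[cal], scope_config(density = 1000))
    for (lv in c(0.6827, 0.9545)) {
      cov <- coverage(predict_interval(tab, pr$y_hat[ev], lv), pr$y[ev])
      slack <- 300 * sqrt(lv * (1 - lv) / length(ev))
      expect_gte(cov, 100 * lv - slack)
    }
  }
})

test_that("per-stratum coverage is approximately valid under heteroscedastic noise", {
  pr <- oracle_pairs(30000, seed = 23)
  cal <- 1:10000; ev <- 10001:30000
  tab <- fit_scope(pr$y_hat[cal], pr$y[cal], scope_config(density = 2000))
  iv <- predict_interval(tab, pr$y_hat[ev], 0.9545)
  inside <- pr$y[ev] >= iv$lower & pr$y[ev] <= iv$upper
  for (s in unique(iv$stratum)) {
    sel <- iv$stratum == s
    if (sum(sel) < 500) next
    slack <- 400 * sqrt(0.9545 * 0.0455 / sum(sel))
    expect_gte(100 * mean(inside[sel]), 95.45 - slack)
  }
})
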