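test_that("log transform handles zeros via the offset and preserves order", {
  expect_equal(log_minutes(0), 0)
  expect_equal(log_minutes(exp(1) - 1), 1)
  x <- c(0, 3, 7, 2, 100)
  expect_equal(order(log_minutes(x)), order(x))
  expect_error(log_minutes(-1), "non-negative")
})

test_that("correlation cells match the explicit-sum oracle with pairwise n", {
  set.seed(3)
  n <- 40
  tab <- data.frame(a = rexp(n, 0.1), b = rexp(n, 0.1), c = rexp(n, 0.05))
  tab$b[1:5] <- NA
  cm <- correlation_matrix(tab, c("a", "b"), c("b", "c"))
  expect_equal(unname(cm$n["a", "b"]), n - 5)
  ok <- !is.na(tab$b)
  expect_equal(unname(cm$r["a", "b"]),
               oracle_cor(log1p(tab$a[ok]), log1p(tab$b[ok])),
               tolerance = 1e-10)
  expect_equal(unname(cm$r["b", "b"]), 1)
  # p from the t approximation
  r <- cm$r["a", "c"]
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(unname(cm$p["a", "c"]), 2 * pt(-abs(tt), n - 2),
               tolerance = 1e-12)
})

test_that("paired t-test matches hand arithmetic and the oracle", {
  tab <- data.frame(a = c(2, 4, 6), b = c(1, 2, 3))  # diffs 1, 2, 3
  r <- paired_comparison(tab, "a", "b")
  expect_equal(r$mean_diff, 2)
  expect_equal(r$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_equal(r$n, 3)

  set.seed(4)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    a <- rnorm(n, 50, 20); b <- rnorm(n, 45, 15)
    got <- paired_comparison(data.frame(a = a, b = b), "a", "b")
    want <- oracle_paired_t(a, b)
    expect_equal(got$mean_diff, want$mean, tolerance = 1e-10)
    expect_equal(got$t_stat, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }

  same <- data.frame(a = c(1, 2, 3), b = c(1, 2, 3))
  r0 <- paired_comparison(same, "a", "b")
  expect_equal(r0$mean_diff, 0)
  expect_true(is.na(r0$t_stat))
})

test_that("stratified bias splits on objective MVPA at the threshold", {
  tab <- data.frame(obj = c(80, 90, 70, 30, 20, 40, 55),
                    rep = c(50, 60, 45, 29, 21, 38, 54))
  sb <- stratified_bias(tab, "rep", "obj", "obj", threshold = 60)
  expect_equal(sb$n, c(3L, 4L))
  expect_equal(sb$mean_diff[sb$stratum == "active"],
               mean(c(50 - 80, 60 - 90, 45 - 70)))
  # all subjects below threshold: active stratum missing
  low <- stratified_bias(tab[tab$obj < 60, ], "rep", "obj", "obj")
  expect_true(is.na(low$mean_diff[low$stratum == "active"]))
  expect_equal(low$n[low$stratum == "active"], 0L)
})

test_that("Bland-Altman computes bias, limits and proportional bias", {
  # constant shift: bias = c, zero-width limits, no proportional bias
  tab <- data.frame(a = c(10, 20, 30, 40), b = c(10, 20, 30, 40) - 7)
  ba <- bland_altman(tab, "a", "b")
  expect_equal(ba$bias, 7)
  expect_equal(ba$sd_diff, 0)
  expect_true(is.na(ba$prop_bias_r))

  set.seed(6)
  n <- 30
  x <- rnorm(n, 60, 20); y <- x + rnorm(n, -5, 8)
  ba2 <- bland_altman(data.frame(a = x, b = y), "a", "b")
  d <- x - y; m <- (x + y) / 2
  expect_equal(ba2$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba2$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba2$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba2$prop_bias_r, oracle_cor(d, m), tolerance = 1e-10)
  expect_equal(nrow(ba2$data), n)
})

test_that("Bland-Altman limits cover about 95% of Gaussian differences", {
  set.seed(7)
  n <- 4000
  a <- rnorm(n, 50, 15)
  b <- a + rnorm(n, -10, 12)
  ba <- bland_altman(data.frame(a = a, b = b), "a", "b")
  cover <- mean(ba$data$diff >= ba$loa_low & ba$data$diff <= ba$loa_high)
  expect_gt(cover, 0.95 - 3 * sqrt(0.95 * 0.05 / n))
  expect_lt(cover, 0.95 + 3 * sqrt(0.95 * 0.05 / n))
})

test_that("regression matches the normal-equations oracle; nested R2 monotone", {
  set.seed(9)
  n <- 45
  tab <- data.frame(y = rexp(n, 1 / 50), x1 = rexp(n, 1 / 30),
                    x2 = rexp(n, 1 / 20), x3 = rexp(n, 1 / 40))
  fit <- fit_mvpa_regression(tab, "y", c("x1", "x2", "x3"))
  o <- oracle_ols(log1p(tab$y), cbind(log1p(tab$x1), log1p(tab$x2),
                                      log1p(tab$x3)))
  expect_equal(unname(fit$coefficients$b), o$b, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients$se), unname(o$se), tolerance = 1e-10)
  expect_equal(fit$r_squared, o$r2, tolerance = 1e-10)

  # nested models on identical rows never gain R^2 by dropping a predictor
  f2 <- fit_mvpa_regression(tab, "y", c("x1", "x2"))
  expect_lte(f2$r_squared, fit$r_squared + 1e-12)

  # y as its own predictor: perfect fit
  f1 <- suppressWarnings(fit_mvpa_regression(cbind(tab, yy = tab$y), "y", "yy"))
  expect_equal(f1$r_squared, 1)
  expect_equal(unname(f1$coefficients["yy", "b"]), 1, tolerance = 1e-10)

  # collinear design rejected with the offender named
  tab$x4 <- tab$x1
  expect_error(fit_mvpa_regression(tab, "y", c("x1", "x4"),
                                   log_vars = character(0)),
               "collinear.*x4")
})

test_that("cohort descriptives report mean, SD and quartiles", {
  tab <- data.frame(v = c(1, 2, 3, 4, 100, NA))
  d <- describe_cohort(tab, "v")
  expect_equal(d$n, 5)
  expect_equal(d$mean, 22)
  expect_equal(d$q50, 3)
  expect_equal(d$sd, sd(c(1, 2, 3, 4, 100)))
})
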