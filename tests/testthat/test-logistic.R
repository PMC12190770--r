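test_that("noiseless logistic samples are recovered to near machine precision", {
  pts <- logistic_points(0.5, 10, 2, seq(0, 30, by = 2))
  fit <- fit_logistic3(pts, "on")
  expect_true(fit$converged)
  expect_equal(fit$a, 0.5, tolerance = 1e-6)
  expect_equal(fit$b, 10, tolerance = 1e-6)
  expect_equal(fit$c, 2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("fit matches an exhaustive coarse grid-search SSE minimizer", {
  withr::local_seed(14)
  x <- rep(seq(0, 30, length.out = 8), 2)
  y <- 1.5 / (1 + exp(-0.4 * (x - 12))) + rnorm(length(x), 0, 0.08)
  fit <- fit_logistic3(tibble::tibble(x = x, y = y), "on")
  grid <- expand.grid(a = seq(0.05, 1.2, by = 0.025),
                      b = seq(2, 25, by = 0.25),
                      c = seq(0.5, 2.5, by = 0.05))
  sse <- mapply(function(a, b, c) sum((y - c / (1 + exp(-a * (x - b))))^2),
                grid$a, grid$b, grid$c)
  best <- grid[which.min(sse), ]
  expect_equal(fit$a, best$a, tolerance = 0.05)
  expect_equal(fit$b, best$b, tolerance = 0.05)
  expect_equal(fit$c, best$c, tolerance = 0.05)
  expect_lte(sum((y - predict(fit))^2), min(sse) + 1e-8)
})

test_that("constant zero data degenerates to c = 0 and is flagged", {
  fit <- fit_logistic3(tibble::tibble(x = c(0, 5, 10, 20), y = rep(0, 4)), "on")
  expect_true(fit$degenerate)
  expect_equal(fit$c, 0)
  expect_error(derived_x(fit, 0.5, "rise"), "c <= 0|a = 0")
})

test_that("too few points or too few distinct x error", {
  expect_error(fit_logistic3(tibble::tibble(x = c(0, 5, 10), y = c(0, 1, 2)), "on"),
               "4 points")
  expect_error(fit_logistic3(tibble::tibble(x = c(0, 0, 5, 5), y = c(0, 0, 1, 1)), "on"),
               "distinct")
})

test_that("derived_x inverts the logistic: closed form vs bisection oracle", {
  fit <- fit_logistic3(logistic_points(1, 0, 1, seq(-6, 6, by = 1)), "on")
  bisect <- function(target, lo = -50, hi = 50) {
    f <- function(x) fit$c / (1 + exp(-fit$a * (x - fit$b))) - target
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(derived_x(fit, 0.9, "rise"), log(9), tolerance = 1e-4)
  expect_equal(derived_x(fit, 0.9, "rise"), bisect(0.9 * fit$c), tolerance = 1e-6)
  # 20% crossing can be negative and is reported as-is
  expect_equal(derived_x(fit, 0.2, "rise"), -log(4), tolerance = 1e-4)
  expect_equal(derived_x(fit, 0.2, "rise"), bisect(0.2 * fit$c), tolerance = 1e-6)
})

test_that("half-maximum derived time equals the inflection point exactly", {
  withr::local_seed(3)
  for (i in 1:10) {
    a <- runif(1, 0.1, 2); b <- runif(1, 2, 25); c <- runif(1, 0.5, 5)
    x <- seq(0, 40, length.out = 12)
    y <- c / (1 + exp(-a * (x - b))) + rnorm(12, 0, 0.02 * c)
    fit <- fit_logistic3(tibble::tibble(x = x, y = y), "on")
    if (!fit$converged) next
    expect_equal(derived_x(fit, 0.5, "rise"), fit$b, tolerance = 1e-9)
  }
})

test_that("rise crossings at p and 1-p are symmetric about the inflection", {
  fit <- fit_logistic3(logistic_points(0.35, 14, 2.2, seq(0, 40, by = 4)), "on")
  for (p in c(0.1, 0.2, 0.35)) {
    expect_equal(derived_x(fit, p, "rise") - fit$b,
                 -(derived_x(fit, 1 - p, "rise") - fit$b), tolerance = 1e-9)
  }
})

test_that("the fitted curve is monotone with predictions inside (0, c)", {
  fit <- fit_logistic3(logistic_points(0.5, 10, 2, seq(0, 30, by = 3)), "on")
  xx <- tibble::tibble(x = seq(-20, 60, length.out = 400))
  yy <- predict(fit, xx)
  expect_true(all(diff(yy) > 0))
  expect_true(all(yy > 0 & yy < fit$c))
})

test_that("off-direction fits recover a negative rate and increasing tOFF quantiles", {
  pts <- logistic_points(-0.3, 12, 2, seq(0, 40, by = 4))
  fit <- fit_logistic3(pts, "off")
  expect_equal(fit$a, -0.3, tolerance = 1e-6)
  toff <- vapply(c(0.2, 0.5, 0.9), function(p) derived_x(fit, p, "decay"), numeric(1))
  expect_true(all(diff(toff) > 0))
  expect_equal(toff[2], fit$b, tolerance = 1e-9)
})

test_that("zero-noise bootstrap collapses to the point estimate and is seed-stable", {
  fit <- fit_logistic3(logistic_points(0.5, 10, 2, seq(0, 30, by = 3)), "on")
  ci <- derived_ci(fit, 0.9, "rise", n_boot = 200, seed = 4)
  expect_lt(ci$conf.high - ci$conf.low, 1e-6)
  expect_equal(ci$estimate, derived_x(fit, 0.9, "rise"))
  withr::local_seed(99)
  x <- seq(0, 30, by = 3)
  y <- 2 / (1 + exp(-0.5 * (x - 10))) + rnorm(length(x), 0, 0.15)
  nfit <- fit_logistic3(tibble::tibble(x = x, y = y), "on")
  ci1 <- derived_ci(nfit, 0.5, "rise", n_boot = 250, seed = 7)
  ci2 <- derived_ci(nfit, 0.5, "rise", n_boot = 250, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1$conf.low, ci1$estimate)
  expect_gte(ci1$conf.high, ci1$estimate)
  # delta-method interval brackets the estimate too
  cid <- derived_ci(nfit, 0.5, "rise", method = "delta")
  expect_lt(cid$conf.low, cid$estimate)
  expect_gt(cid$conf.high, cid$estimate)
})

test_that("derived_params tabulates increasing quantiles with CIs", {
  fit <- fit_logistic3(logistic_points(0.5, 10, 2, seq(0, 30, by = 3)), "on")
  dp <- derived_params(fit, n_boot = 200, seed = 2)
  expect_equal(dp$kind, rep("tON", 3))
  expect_true(all(diff(dp$estimate) > 0))
  expect_true(all(dp$conf.low <= dp$estimate & dp$estimate <= dp$conf.high))
})

test_that("tidy and glance expose parameters and fit quality", {
  withr::local_seed(41)
  x <- rep(seq(0, 30, by = 3), 2)
  y <- 2 / (1 + exp(-0.5 * (x - 10))) + rnorm(length(x), 0, 0.1)
  fit <- fit_logistic3(tibble::tibble(x = x, y = y), "on")
  td <- tidy(fit)
  expect_identical(td$term, c("a", "b", "c"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_lte(gl$r.squared, 1)
  expect_true(gl$converged)
})
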