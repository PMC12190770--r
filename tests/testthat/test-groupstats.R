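test_that("dark subtraction matches keys and retains negatives", {
  treated <- tibble::tibble(axis_value = c(0, 8, 8), bio_replicate = c("1", "1", "2"),
                            value = c(5, 2, 1.5))
  dark <- tibble::tibble(axis_value = c(0, 8, 8), bio_replicate = c("1", "1", "2"),
                         value = c(2, 3, 1.5))
  out <- subtract_dark(treated, dark)
  expect_equal(out$value, c(3, -1, 0))
  expect_equal(subtract_dark(treated, treated)$value, rep(0, 3))
  expect_error(subtract_dark(treated, dark[-2, ]), "axis_value=8")
})

test_that("technical aggregation averages QC-passing records and flags empty groups", {
  rec <- tibble::tibble(
    tool = "FGF", condition = "455nm",
    axis_value = c(0, 0, 8, 8), bio_replicate = "1",
    norm_gfp = c(2, 4, 10, 99), qc_passed = c(TRUE, TRUE, TRUE, FALSE))
  agg <- aggregate_technical(rec)
  expect_equal(agg$value[agg$axis_value == 0], 3)
  expect_equal(agg$value[agg$axis_value == 8], 10)
  expect_equal(agg$n_excluded[agg$axis_value == 8], 1L)
  rec$qc_passed <- c(FALSE, FALSE, TRUE, TRUE)
  agg2 <- aggregate_technical(rec)
  expect_true(agg2$missing[agg2$axis_value == 0])
  expect_true(is.na(agg2$value[agg2$axis_value == 0]))
})

test_that("balanced-design least-square means equal arithmetic means exactly", {
  withr::local_seed(6)
  df <- expand.grid(condition = c("dark", "495nm", "455nm"),
                    bio_replicate = c("1", "2", "3"))
  df$value <- rnorm(9, mean = c(1, 1.2, 3)[as.integer(df$condition)], sd = 0.3) +
    rnorm(9, 0, 0.5)[as.integer(df$bio_replicate)]
  fit <- fit_random_intercept(df)
  raw <- tapply(df$value, df$condition, mean)
  expect_equal(fit$lsmeans$lsmean[match(names(raw), fit$lsmeans$condition)],
               as.vector(raw), tolerance = 1e-10)
})

test_that("REML estimates match a direct profiled-likelihood grid oracle", {
  withr::local_seed(18)
  for (i in 1:4) {
    df <- expand.grid(condition = c("a", "b", "c"),
                      replicate = factor(1:4))
    df$bio_replicate <- df$replicate
    df$value <- c(0, 0.5, 2)[as.integer(df$condition)] +
      rnorm(4, 0, 1)[as.integer(df$replicate)] + rnorm(12, 0, 0.5)
    fit <- fit_random_intercept(df)
    oracle <- reml_grid_oracle(df)
    expect_equal(unname(fit$varcomp["residual"]), unname(oracle["residual"]),
                 tolerance = 0.02)
    expect_equal(unname(fit$varcomp["replicate"]), unname(oracle["replicate"]),
                 tolerance = max(0.05, 0.05 * oracle["replicate"]))
  }
})

test_that("variance components are recovered in a seeded simulation study", {
  withr::local_seed(77)
  est <- t(replicate(300, {
    df <- expand.grid(condition = c("a", "b", "c"), replicate = factor(1:3))
    df$bio_replicate <- df$replicate
    df$value <- rnorm(3, 0, 1)[as.integer(df$replicate)] + rnorm(9, 0, 0.5)
    fit <- fit_random_intercept(df)
    fit$varcomp
  }))
  # With only 3 replicate levels the between-replicate estimator is chi^2_2
  # distributed, so its median sits well below the truth; the mean is the
  # (nearly) unbiased summary for that component, the median for the residual.
  expect_lt(abs(mean(est[, "replicate"]) - 1) / 1, 0.25)
  expect_lt(abs(median(est[, "residual"]) - 0.25) / 0.25, 0.25)
})

test_that("adjusted p-values are never smaller than unadjusted ones", {
  withr::local_seed(10)
  df <- tibble::tibble(condition = rep(c("0", "8", "30"), each = 5),
                       value = rnorm(15, rep(c(0, 0.5, 1), each = 5)))
  for (style in c("dunnett_vs_control", "tukey_all_pairs")) {
    ph <- posthoc(df, style, control = "0", n_mc = 2e4, seed = 5)
    expect_true(all(ph$adj.p.value >= ph$p.value))
  }
})

test_that("identical groups give adjusted p near 1", {
  df <- tibble::tibble(condition = rep(c("a", "b", "c"), each = 4),
                       value = rep(c(1, 2, 3, 4), 3))
  ph <- posthoc(df, "dunnett_vs_control", control = "a", n_mc = 2e4, seed = 5)
  expect_true(all(ph$adj.p.value > 0.95))
})

test_that("two-group Dunnett agrees with the plain t-test oracle", {
  withr::local_seed(30)
  x <- rnorm(8, 0); y <- rnorm(8, 1)
  df <- tibble::tibble(condition = rep(c("ctrl", "trt"), each = 8), value = c(x, y))
  ph <- posthoc(df, "dunnett_vs_control", control = "ctrl", n_mc = 2e5, seed = 8)
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(ph$adj.p.value, tt$p.value, tolerance = 0.01)
  expect_equal(ph$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("Dunnett adjustment agrees with multcomp on a three-group layout", {
  skip_if_not_installed("multcomp")
  withr::local_seed(44)
  df <- data.frame(condition = factor(rep(c("0", "8", "30"), each = 6)),
                   value = rnorm(18, rep(c(0, 0.7, 1.2), each = 6)))
  ph <- posthoc(df, "dunnett_vs_control", control = "0", n_mc = 2e5, seed = 9)
  mc <- summary(multcomp::glht(stats::aov(value ~ condition, df),
                               linfct = multcomp::mcp(condition = "Dunnett")))
  expect_equal(sort(ph$adj.p.value), sort(as.numeric(mc$test$pvalues)),
               tolerance = 0.02)
})

test_that("fold change is a guarded ratio", {
  expect_equal(fold_change(6, 2), 3)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(0, 2), 0)
  expect_error(fold_change(1, 0), "positive denominator")
})

test_that("phenotype gate enforces the 60%/20% boundaries as worded", {
  counts <- function(light_severe, light_total, dark_bad = 1, dark_total = 20) {
    tibble::tibble(
      condition = c("light_injected", "dark_injected"),
      normal = c(light_total - light_severe, dark_total - dark_bad),
      mild_deform = c(0, dark_bad), severe_deform = c(light_severe, 0),
      lysed = 0, v1_v4 = 0, v2_plus_present = FALSE)
  }
  expect_true(phenotype_gate(counts(12, 20), "FGF")$passed)   # 60% exactly
  res <- phenotype_gate(counts(11, 20), "FGF")                # 55%
  expect_false(res$passed)
  expect_true("low_efficacy" %in% res$reasons)
  # exactly 20% dark defects passes ("more than 20%" fails)
  expect_true(phenotype_gate(counts(12, 20, dark_bad = 4), "FGF")$passed)
  expect_false(phenotype_gate(counts(12, 20, dark_bad = 5), "FGF")$passed)
})

test_that("BMP gate needs V1-V4 >= 60% and V2-or-higher present", {
  bmp_counts <- function(v14, total, v2 = TRUE) {
    tibble::tibble(
      condition = c("light_injected", "dark_injected"),
      normal = c(total - v14, 20), mild_deform = 0, severe_deform = 0,
      lysed = 0, v1_v4 = c(v14, 0), v2_plus_present = c(v2, FALSE))
  }
  expect_true(phenotype_gate(bmp_counts(14, 20), "BMP")$passed)
  res <- phenotype_gate(bmp_counts(14, 20, v2 = FALSE), "BMP")
  expect_false(res$passed)
  expect_true("no_v2_or_higher" %in% res$reasons)
  expect_false(phenotype_gate(bmp_counts(11, 20), "BMP")$passed)
})

test_that("phenotype gate is monotone in light-condition severity and handles controls", {
  base <- tibble::tibble(
    condition = c("light_injected", "dark_injected", "uninjected_dark", "uninjected_light"),
    normal = c(8, 19, 10, 10), mild_deform = c(0, 1, 8, 8),
    severe_deform = c(12, 0, 0, 0), lysed = 0, v1_v4 = 0, v2_plus_present = FALSE)
  res <- phenotype_gate(base, "FGF")
  expect_true(res$excluded)  # >30% uninjected defects in both conditions
  # adding severe embryos to the light condition never flips pass -> fail
  ok <- base[base$condition %in% c("light_injected", "dark_injected"), ]
  for (extra in c(0, 5, 20)) {
    more <- ok
    more$severe_deform[1] <- more$severe_deform[1] + extra
    expect_true(phenotype_gate(more, "FGF")$passed)
  }
  expect_error(phenotype_gate(ok[1, ], "FGF"), "dark_injected")
})
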