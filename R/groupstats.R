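#' Subtract matched dark controls
#'
#' Subtracts each treated observation's matched dark control (time-matched
#' for kinetics, round-matched for irradiance) within biological replicate.
#' Negative differences are retained — undershoot below the dark baseline is
#' real data, not an error.
#'
#' @param treated Data frame of treated group means with the key columns in
#'   `by` and a `value` column.
#' @param dark Data frame of matched dark-control means, same keys.
#' @param by Key columns (default `axis_value` + `bio_replicate`).
#' @param value Name of the value column.
#' @return `treated` with `value` replaced by `treated - dark` and a
#'   `dark_value` column appended.
#' @export
subtract_dark <- function(treated, dark, by = c("axis_value", "bio_replicate"),
                          value = "value") {
  stopifnot(is.data.frame(treated), is.data.frame(dark))
  miss <- setdiff(by, names(treated)); miss2 <- setdiff(by, names(dark))
  if (length(miss) || length(miss2)) {
    abort(sprintf("Key column(s) missing: %s.",
                  paste(unique(c(miss, miss2)), collapse = ", ")))
  }
  dk <- dark[, c(by, value)]
  names(dk)[names(dk) == value] <- ".dark_value"
  joined <- dplyr::left_join(treated, dk, by = by)
  if (anyNA(joined$.dark_value)) {
    bad <- joined[is.na(joined$.dark_value), by, drop = FALSE]
    keys <- apply(bad, 1L, function(r) paste(by, r, sep = "=", collapse = ", "))
    abort(sprintf("No matched dark control for: %s.",
                  paste(unique(keys), collapse = "; ")))
  }
  joined[[value]] <- joined[[value]] - joined$.dark_value
  names(joined)[names(joined) == ".dark_value"] <- "dark_value"
  tibble::as_tibble(joined)
}

#' Average technical replicates within condition and biological replicate
#'
#' QC-failed records are excluded (and counted); a group whose records all
#' failed QC is kept as an explicit missing-group marker rather than being
#' silently dropped.
#'
#' @param records Quantification tibble (one row per technical replicate)
#'   with a logical `qc_passed` column.
#' @param value Name of the value column to average (e.g. `norm_gfp`).
#' @param by Grouping keys.
#' @return A tibble with one row per group: `value` (mean over passing
#'   records, `NA` if none), `n_technical`, `n_excluded`, `missing`.
#' @export
aggregate_technical <- function(records, value = "norm_gfp",
                                by = c("tool", "condition", "axis_value",
                                       "bio_replicate")) {
  stopifnot(is.data.frame(records), value %in% names(records))
  if (!"qc_passed" %in% names(records)) records$qc_passed <- TRUE
  by <- intersect(by, names(records))
  v <- rlang::sym(value)
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_technical = sum(.data$qc_passed & !is.na(!!v)),
      n_excluded = sum(!.data$qc_passed | is.na(!!v)),
      value = if (any(.data$qc_passed & !is.na(!!v)))
        mean((!!v)[.data$qc_passed & !is.na(!!v)]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(missing = is.na(.data$value))
  out
}

#' Random-intercept mixed model with least-square means
#'
#' REML fit of a one-way design with a fixed condition effect and a random
#' biological-replicate intercept (`value ~ condition + (1 | replicate)`),
#' the model used for wavelength-dependence comparisons. Returns predicted
#' least-square (marginal) means with standard errors per condition and an
#' F-test of the condition effect (Satterthwaite degrees of freedom).
#'
#' @param data Data frame of group observations.
#' @param value,condition,replicate Column names.
#' @return An object of class `random_intercept_fit`: the lme4 model,
#'   `lsmeans` tibble (`condition`, `lsmean`, `se`, `df`), `anova` tibble
#'   (`f.statistic`, `p.value`), `varcomp` (`replicate`, `residual`).
#' @export
fit_random_intercept <- function(data, value = "value", condition = "condition",
                                 replicate = "bio_replicate") {
  stopifnot(is.data.frame(data),
            all(c(value, condition, replicate) %in% names(data)))
  df <- data.frame(value = data[[value]],
                   condition = factor(data[[condition]]),
                   replicate = factor(data[[replicate]]))
  df <- df[!is.na(df$value), ]
  if (nlevels(droplevels(df$condition)) < 2L) abort("Need >= 2 conditions.")
  if (nlevels(droplevels(df$replicate)) < 2L) abort("Need >= 2 replicates.")
  model <- withCallingHandlers(
    lmerTest::lmer(value ~ condition + (1 | replicate), data = df, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage")
  )
  emm <- emmeans::emmeans(model, "condition")
  emm_df <- as.data.frame(emm)
  lsmeans <- tibble::tibble(condition = as.character(emm_df$condition),
                            lsmean = emm_df$emmean, se = emm_df$SE,
                            df = emm_df$df)
  an <- suppressMessages(anova(model))
  anova_tbl <- tibble::tibble(term = rownames(an),
                              f.statistic = an[["F value"]],
                              df1 = an[["NumDF"]], df2 = an[["DenDF"]],
                              p.value = an[["Pr(>F)"]])
  vc <- as.data.frame(lme4::VarCorr(model))
  varcomp <- c(replicate = vc$vcov[vc$grp == "replicate"],
               residual = vc$vcov[vc$grp == "Residual"])
  structure(list(model = model, lsmeans = lsmeans, anova = anova_tbl,
                 varcomp = varcomp, emmeans = emm),
            class = "random_intercept_fit")
}

#' @exportS3Method base::print
print.random_intercept_fit <- function(x, ...) {
  cat("<random_intercept_fit> REML one-way model with random replicate intercept\n")
  print(x$lsmeans)
  cat(sprintf("condition effect: F = %.3f, p = %.4g\n",
              x$anova$f.statistic[1L], x$anova$p.value[1L]))
  invisible(x)
}

#' @export
tidy.random_intercept_fit <- function(x, ...) x$lsmeans

#' @export
glance.random_intercept_fit <- function(x, ...) {
  tibble::tibble(f.statistic = x$anova$f.statistic[1L],
                 p.value = x$anova$p.value[1L],
                 var.replicate = unname(x$varcomp["replicate"]),
                 var.residual = unname(x$varcomp["residual"]))
}

# Monte-Carlo draws of the null max-|t| statistic for a one-way layout.
# ns: per-group sample sizes, first element = control for dunnett.
mc_null_maxt <- function(ns, df, style, n_mc, seed) {
  withr::with_seed(seed, {
    k <- length(ns)
    z <- matrix(rnorm(n_mc * k), n_mc, k)
    z <- sweep(z, 2L, sqrt(ns), `/`)
    s <- sqrt(rchisq(n_mc, df) / df)
    if (style == "dunnett_vs_control") {
      tmat <- vapply(2:k, function(j) {
        (z[, j] - z[, 1L]) / (s * sqrt(1 / ns[j] + 1 / ns[1L]))
      }, numeric(n_mc))
    } else {
      pairs <- utils::combn(k, 2L)
      tmat <- vapply(seq_len(ncol(pairs)), function(m) {
        i <- pairs[1L, m]; j <- pairs[2L, m]
        (z[, j] - z[, i]) / (s * sqrt(1 / ns[j] + 1 / ns[i]))
      }, numeric(n_mc))
    }
    apply(abs(tmat), 1L, max)
  })
}

#' Post-hoc multiple comparisons (Dunnett / Tukey) by seeded Monte Carlo
#'
#' Family-wise adjusted p-values for all-pairs (Tukey-style) or
#' versus-control (Dunnett-style) comparisons in a one-way layout. The
#' adjustment simulates the null distribution of the maximum absolute t
#' statistic for the actual design (shared control correlation included) with
#' a seeded Monte-Carlo sample; the adjusted p for a comparison is the null
#' probability that the max-|t| exceeds its observed |t|, clamped to be no
#' smaller than the unadjusted p.
#'
#' @param data Data frame with `value` and `condition` columns (one row per
#'   observation).
#' @param style `"dunnett_vs_control"` or `"tukey_all_pairs"`.
#' @param control Control condition label (required for Dunnett; the
#'   kinetics analysis uses time = 0).
#' @param value,condition Column names.
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed Integer seed.
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble: `comparison`, `estimate`, `t.statistic`, `p.value`
#'   (unadjusted two-sided), `adj.p.value`, `significant`.
#' @export
posthoc <- function(data, style = c("dunnett_vs_control", "tukey_all_pairs"),
                    control = NULL, value = "value", condition = "condition",
                    n_mc = 1e5, seed = 1L, alpha = 0.05) {
  style <- match.arg(style)
  stopifnot(is.data.frame(data), all(c(value, condition) %in% names(data)))
  v <- data[[value]]
  g <- factor(data[[condition]])
  keep <- !is.na(v)
  v <- v[keep]; g <- droplevels(g[keep])
  lv <- levels(g)
  if (style == "dunnett_vs_control") {
    if (is.null(control)) abort("`control` is required for Dunnett comparisons.")
    control <- as.character(control)
    if (!control %in% lv) {
      abort(sprintf("Control '%s' is not among the groups (%s).", control,
                    paste(lv, collapse = ", ")))
    }
    lv <- c(control, setdiff(lv, control))
    g <- factor(as.character(g), levels = lv)
  }
  ns <- tabulate(g, nbins = length(lv))
  if (any(ns < 2L)) abort("Every group needs >= 2 observations.")
  means <- tapply(v, g, mean)
  df <- length(v) - length(lv)
  mse <- sum((v - means[g])^2) / df
  if (style == "dunnett_vs_control") {
    idx <- cbind(rep(1L, length(lv) - 1L), 2:length(lv))
  } else {
    idx <- t(utils::combn(length(lv), 2L))
  }
  est <- means[idx[, 2L]] - means[idx[, 1L]]
  se <- sqrt(mse * (1 / ns[idx[, 2L]] + 1 / ns[idx[, 1L]]))
  tstat <- est / se
  p_unadj <- 2 * pt(-abs(tstat), df)
  maxt <- mc_null_maxt(ns, df, style, n_mc, seed)
  p_adj <- vapply(abs(tstat), function(t0) mean(maxt >= t0), numeric(1))
  p_adj <- pmax(p_adj, p_unadj)
  tibble::tibble(
    comparison = paste(lv[idx[, 2L]], "-", lv[idx[, 1L]]),
    estimate = unname(est), t.statistic = unname(tstat),
    p.value = unname(p_unadj), adj.p.value = unname(p_adj),
    significant = unname(p_adj < alpha)
  )
}

#' Monte-Carlo critical value for a post-hoc family
#'
#' The `1 - alpha` quantile of the simulated null max-|t| distribution for a
#' given one-way design; useful for calibration studies.
#'
#' @param ns Per-group sample sizes (control first for Dunnett).
#' @param df Error degrees of freedom.
#' @param style `"dunnett_vs_control"` or `"tukey_all_pairs"`.
#' @param alpha Family-wise level.
#' @param n_mc,seed Monte-Carlo settings.
#' @return Critical |t| value.
#' @export
posthoc_critical_value <- function(ns, df, style = c("dunnett_vs_control",
                                                     "tukey_all_pairs"),
                                   alpha = 0.05, n_mc = 1e5, seed = 1L) {
  style <- match.arg(style)
  quantile(mc_null_maxt(ns, df, style, n_mc, seed), 1 - alpha, names = FALSE)
}

#' Fold change between two group means
#'
#' @param mean_a Numerator mean (e.g. light-exposed).
#' @param mean_b Denominator mean (e.g. dark), must be > 0.
#' @return `mean_a / mean_b`. Reports conventionally round to one decimal.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) abort("Fold change requires a positive denominator.")
  mean_a / mean_b
}

#' Phenotype-based mRNA-quality inclusion gate
#'
#' Encodes the experiment-inclusion criteria scored on 1 dpf phenotypes.
#' FGF/Nodal rule: proceed iff at least 60% of injected 455 nm-exposed
#' embryos are severely deformed or lysed, and the dark-injected condition
#' shows no more than 20% disallowed phenotypes (mild-severe deformity,
#' lysed). BMP rule: proceed iff at least 60% of injected light-exposed
#' embryos show ventralized V1-V4 phenotypes with V2-or-higher present, and
#' the dark-injected condition shows no more than 20% disallowed phenotypes
#' (V1-V4, mild-severe deformity, lysed). Boundaries follow the wording:
#' exactly 60% passes ("at least 60%"), exactly 20% passes ("more than 20%"
#' fails). Independently, an experiment is excluded when uninjected embryos
#' show over 30% defects in both dark and light conditions.
#'
#' @param counts Data frame with one row per condition: `condition` in
#'   `dark_injected`, `light_injected`, `uninjected_dark`,
#'   `uninjected_light`; count columns `normal`, `mild_deform`,
#'   `severe_deform`, `lysed`, `v1_v4`; logical `v2_plus_present`
#'   (light-injected row, BMP only).
#' @param tool `"FGF"`, `"Nodal"`, or `"BMP"`.
#' @return A list: `passed`, `excluded`, `reasons` (character), `fractions`
#'   tibble per condition.
#' @export
phenotype_gate <- function(counts, tool = c("FGF", "Nodal", "BMP")) {
  tool <- match.arg(tool)
  stopifnot(is.data.frame(counts), "condition" %in% names(counts))
  cls <- c("normal", "mild_deform", "severe_deform", "lysed", "v1_v4")
  for (cc in cls) if (!cc %in% names(counts)) counts[[cc]] <- 0
  if (!"v2_plus_present" %in% names(counts)) counts$v2_plus_present <- FALSE
  if (any(counts[cls] < 0)) abort("Phenotype counts must be >= 0.")
  row_of <- function(cond) {
    r <- counts[counts$condition == cond, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    r[1L, ]
  }
  need <- c("light_injected", "dark_injected")
  for (cond in need) {
    r <- row_of(cond)
    if (is.null(r)) abort(sprintf("Missing required condition '%s'.", cond))
    if (sum(as.numeric(r[cls])) == 0) {
      abort(sprintf("Zero embryos counted in required condition '%s'.", cond))
    }
  }
  totals <- vapply(counts$condition, function(cond)
    sum(as.numeric(row_of(cond)[cls])), numeric(1))
  frac <- function(r, cols) sum(as.numeric(r[cols])) / sum(as.numeric(r[cls]))
  light <- row_of("light_injected"); dark <- row_of("dark_injected")
  reasons <- character()
  if (tool %in% c("FGF", "Nodal")) {
    eff <- frac(light, c("severe_deform", "lysed"))
    if (eff < 0.60) reasons <- c(reasons, "low_efficacy")
    leak <- frac(dark, c("mild_deform", "severe_deform", "lysed"))
    if (leak > 0.20) reasons <- c(reasons, "dark_leak")
  } else {
    eff <- frac(light, "v1_v4")
    if (eff < 0.60) reasons <- c(reasons, "low_efficacy")
    if (!isTRUE(light$v2_plus_present)) reasons <- c(reasons, "no_v2_or_higher")
    leak <- frac(dark, c("v1_v4", "mild_deform", "severe_deform", "lysed"))
    if (leak > 0.20) reasons <- c(reasons, "dark_leak")
  }
  excluded <- FALSE
  ud <- row_of("uninjected_dark"); ul <- row_of("uninjected_light")
  if (!is.null(ud) && !is.null(ul) &&
      sum(as.numeric(ud[cls])) > 0 && sum(as.numeric(ul[cls])) > 0) {
    defect <- c("mild_deform", "severe_deform", "lysed", "v1_v4")
    if (frac(ud, defect) > 0.30 && frac(ul, defect) > 0.30) {
      excluded <- TRUE
      reasons <- c(reasons, "uninjected_defects")
    }
  }
  fractions <- tibble::tibble(
    condition = counts$condition,
    n = totals,
    defect_fraction = vapply(counts$condition, function(cond)
      frac(row_of(cond), c("mild_deform", "severe_deform", "lysed", "v1_v4")),
      numeric(1))
  )
  list(passed = length(reasons) == 0L, excluded = excluded,
       reasons = reasons, fractions = fractions)
}
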