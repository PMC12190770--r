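#' End-to-end run configuration
#'
#' @param tool `"FGF"`, `"BMP"`, or `"Nodal"`. Region-statistic selection
#'   follows the assay's rule: FGF and BMP read the GFP-normalized effector
#'   median within the GFP region (`norm_gfp`); Nodal, whose effector pSmad2
#'   is largely nuclear, reads the DAPI+GFP region (`norm_dapi_gfp`).
#' @param region_stat Optional override of the statistic column.
#' @param exposure_end_min Light-off boundary splitting the kinetics
#'   time-course into on (`time <= exposure_end`) and off (`time >=
#'   exposure_end`) fits; default 30 min.
#' @param quant A [quant_config()].
#' @param fit_scope `"replicate_mean"` fits the per-time-point replicate
#'   means (matching the aggregation of the source analysis);
#'   `"pooled"` fits all replicate values.
#' @param n_boot,seed Bootstrap settings for derived-parameter CIs.
#' @param p Derived-parameter fractions.
#' @return An object of class `run_config`.
#' @export
run_config <- function(tool = c("FGF", "BMP", "Nodal"), region_stat = NULL,
                       exposure_end_min = 30, quant = quant_config(),
                       fit_scope = c("replicate_mean", "pooled"),
                       n_boot = 500, seed = 1L, p = c(0.2, 0.5, 0.9)) {
  tool <- match.arg(tool)
  fit_scope <- match.arg(fit_scope)
  region_stat <- region_stat %||%
    if (tool %in% c("FGF", "BMP")) "norm_gfp" else "norm_dapi_gfp"
  structure(list(tool = tool, region_stat = region_stat,
                 exposure_end_min = exposure_end_min, quant = quant,
                 fit_scope = fit_scope, n_boot = n_boot, seed = as.integer(seed),
                 p = p),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Accepts the same fields as [run_config()] plus nested `quant`/`qc` blocks
#' (`dapi_threshold`, `gfp_threshold`, `background_threshold`,
#' `min_gfp_coverage`, `max_saturated_fraction`, `dapi_damage_fraction`).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  qc_args <- y$qc %||% list()
  qc <- do.call(qc_config, qc_args)
  quant_args <- y$quant %||% list()
  quant_args$qc <- qc
  quant <- do.call(quant_config, quant_args)
  run_config(tool = y$tool %||% "FGF", region_stat = y$region_stat,
             exposure_end_min = y$exposure_end_min %||% 30, quant = quant,
             fit_scope = y$fit_scope %||% "replicate_mean",
             n_boot = y$n_boot %||% 500, seed = y$seed %||% 1L,
             p = unlist(y$p %||% c(0.2, 0.5, 0.9)))
}

# Shared front half of both pipelines: quantify, select statistic,
# average technical replicates, subtract matched dark controls.
pipeline_observations <- function(dataset, config) {
  quant <- quantify_dataset(dataset, config$quant)
  agg <- aggregate_technical(quant, value = config$region_stat)
  light <- agg[agg$condition != "dark" & !agg$missing, ]
  dark <- agg[agg$condition == "dark" & !agg$missing, ]
  if (nrow(dark) == 0L) abort("Pipeline requires matched dark controls.")
  if (nrow(light) == 0L) {
    return(list(quant = quant, aggregated = agg, observations = light[0, ]))
  }
  obs <- subtract_dark(light, dark)
  list(quant = quant, aggregated = agg, observations = obs)
}

fit_points <- function(obs, config) {
  if (config$fit_scope == "replicate_mean") {
    obs |>
      dplyr::group_by(.data$axis_value) |>
      dplyr::summarise(y = mean(.data$value), .groups = "drop") |>
      dplyr::transmute(x = .data$axis_value, y = .data$y)
  } else {
    tibble::tibble(x = obs$axis_value, y = obs$value)
  }
}

#' Run the on/off kinetics analysis end to end
#'
#' Quantification of every sample, technical-replicate averaging,
#' time-matched dark subtraction, a one-way ANOVA of time with Dunnett
#' comparisons against time = 0, a phase split at the configured exposure
#' end, a three-parameter logistic fit per phase (off phase re-expressed as
#' time since light removal), and derived tON/tOFF parameters at 20/50/90%
#' with bootstrap CIs.
#'
#' @param dataset A `response_dataset` or dataset directory (see
#'   [quantify_dataset()]).
#' @param config A [run_config()].
#' @return An object of class `kinetics_report`: `quant`, `observations`
#'   (dark-subtracted per-replicate values), `anova`, `posthoc`, `fit_on`,
#'   `fit_off` (possibly `NULL`), `derived` tibble, `config`.
#' @export
run_kinetics <- function(dataset, config = run_config()) {
  stage <- pipeline_observations(dataset, config)
  obs <- stage$observations
  if (nrow(obs) == 0L) abort("Stage dark-subtraction: no light-exposed observations.")
  # One-way ANOVA with fixed effect of time on the dark-subtracted values,
  # then Dunnett comparisons against time = 0 when the effect is present.
  obs$time_f <- factor(obs$axis_value)
  anova_tbl <- NULL
  ph <- NULL
  if (nlevels(obs$time_f) >= 2L && all(table(obs$time_f) >= 2L)) {
    aovfit <- stats::aov(value ~ time_f, data = obs)
    an <- summary(aovfit)[[1L]]
    anova_tbl <- tibble::tibble(term = trimws(rownames(an)),
                                df = an$Df, f.statistic = an$`F value`,
                                p.value = an$`Pr(>F)`)
    if (0 %in% obs$axis_value) {
      ph <- posthoc(obs, "dunnett_vs_control", control = "0",
                    value = "value", condition = "time_f", seed = config$seed)
    }
  }
  on_obs <- obs[obs$axis_value <= config$exposure_end_min, ]
  off_obs <- obs[obs$axis_value >= config$exposure_end_min, ]
  pts_on <- fit_points(on_obs, config)
  fit_on <- fit_logistic3(pts_on, "on")
  derived <- tibble::tibble()
  if (!fit_on$degenerate) {
    derived <- derived_params(fit_on, kind = "tON", p = config$p,
                              n_boot = config$n_boot, seed = config$seed)
  }
  fit_off <- NULL
  if (length(unique(off_obs$axis_value)) >= 3L && nrow(off_obs) >= 4L) {
    pts_off <- fit_points(off_obs, config)
    pts_off$x <- pts_off$x - config$exposure_end_min  # time since light removal
    fit_off <- fit_logistic3(pts_off, "off")
    if (!fit_off$degenerate) {
      derived <- dplyr::bind_rows(
        derived,
        derived_params(fit_off, kind = "tOFF", p = config$p,
                       n_boot = config$n_boot, seed = config$seed))
    }
  }
  structure(list(quant = stage$quant, aggregated = stage$aggregated,
                 observations = obs, anova = anova_tbl, posthoc = ph,
                 fit_on = fit_on, fit_off = fit_off, derived = derived,
                 config = config),
            class = "kinetics_report")
}

#' @exportS3Method base::print
print.kinetics_report <- function(x, ...) {
  cat("<kinetics_report>\n")
  cat(sprintf("  %d samples quantified, %d passed QC\n",
              nrow(x$quant), sum(x$quant$qc_passed)))
  if (!is.null(x$fit_on)) {
    cat(sprintf("  on fit: a=%.4g /min, b=%.4g min, c=%.4g AU, R^2=%.4f%s\n",
                x$fit_on$a, x$fit_on$b, x$fit_on$c, x$fit_on$r_squared,
                if (x$fit_on$degenerate) " [degenerate]" else ""))
  }
  if (!is.null(x$fit_off)) {
    cat(sprintf("  off fit: a=%.4g /min, b=%.4g min, c=%.4g AU, R^2=%.4f%s\n",
                x$fit_off$a, x$fit_off$b, x$fit_off$c, x$fit_off$r_squared,
                if (x$fit_off$degenerate) " [degenerate]" else ""))
  }
  if (nrow(x$derived)) print(x$derived)
  invisible(x)
}

#' Run the irradiance-dependence analysis end to end
#'
#' As [run_kinetics()] but on the irradiance axis: no phase split, a single
#' three-parameter logistic dose fit, and derived I_20 / I_50 / I_90 with
#' bootstrap CIs.
#'
#' @param dataset A `response_dataset` or dataset directory.
#' @param config A [run_config()].
#' @return An object of class `dose_report`: `quant`, `observations`, `fit`,
#'   `derived`, `config`.
#' @export
run_dose <- function(dataset, config = run_config()) {
  stage <- pipeline_observations(dataset, config)
  obs <- stage$observations
  if (nrow(obs) == 0L) abort("Stage dark-subtraction: no light-exposed observations.")
  pts <- fit_points(obs, config)
  fit <- fit_logistic3(pts, "dose")
  derived <- tibble::tibble()
  if (!fit$degenerate) {
    derived <- derived_params(fit, kind = "I", p = config$p,
                              n_boot = config$n_boot, seed = config$seed)
  }
  structure(list(quant = stage$quant, aggregated = stage$aggregated,
                 observations = obs, fit = fit, derived = derived,
                 config = config),
            class = "dose_report")
}

#' @exportS3Method base::print
print.dose_report <- function(x, ...) {
  cat("<dose_report>\n")
  cat(sprintf("  %d samples quantified, %d passed QC\n",
              nrow(x$quant), sum(x$quant$qc_passed)))
  if (!is.null(x$fit)) {
    cat(sprintf("  dose fit: a=%.4g per W/m2, b=%.4g W/m2, c=%.4g AU, R^2=%.4f%s\n",
                x$fit$a, x$fit$b, x$fit$c, x$fit$r_squared,
                if (x$fit$degenerate) " [degenerate]" else ""))
  }
  if (nrow(x$derived)) print(x$derived)
  invisible(x)
}

#' The 9-step irradiance ladder used for dose-response characterization
#' @return Numeric vector of irradiances in W/m2.
#' @export
irradiance_ladder <- function() {
  c(0, 0.02, 0.05, 0.15, 0.46, 1.39, 4.17, 12.50, 50.00)
}
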