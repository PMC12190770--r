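#' Fit the three-parameter logistic response model
#'
#' Least-squares fit of `y = c / (1 + exp(-a (x - b)))` — growth rate `a`
#' (per x-unit), inflection point `b` (x-units), upper asymptote `c` (AU) —
#' with the lower asymptote fixed at 0. This is the model used for both
#' on/off kinetics (x = time in min; for the off phase x is time since light
#' removal and `a` is negative) and irradiance dependence (x in W/m2).
#' Dark-subtracted responses may legitimately be negative and are retained.
#'
#' Fitting is deterministic multi-start Levenberg-Marquardt: `c0 = max(y)`,
#' `b0` = the x nearest the half-maximum crossing, `a0` over a fixed grid
#' `{0.05, 0.5, 5}` signed by `direction`; the candidate with the lowest SSE
#' wins. `c` is constrained `>= 0`.
#'
#' @param data Data frame with columns `x` and `y` (one row per response
#'   point; a `bio_replicate` column is allowed and ignored here).
#' @param direction `"on"` (rise), `"off"` (decay), or `"dose"` (irradiance
#'   rise).
#' @return An object of class `logistic3_fit`: parameters `a`, `b`, `c`,
#'   `r_squared`, 95% Wald `param_cis`, `vcov`, `sigma`, `n_points`,
#'   `converged`, `degenerate`, plus the data and direction.
#' @export
fit_logistic3 <- function(data, direction = c("on", "off", "dose")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  x <- as.numeric(data$x)
  y <- as.numeric(data$y)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L || length(unique(x)) < 3L) {
    abort("At least 4 points spanning >= 3 distinct x values are required.")
  }
  out <- structure(
    list(a = NA_real_, b = NA_real_, c = NA_real_, r_squared = NA_real_,
         param_cis = NULL, vcov = NULL, sigma = NA_real_,
         n_points = length(x), converged = FALSE, degenerate = FALSE,
         direction = direction, data = tibble::tibble(x = x, y = y)),
    class = "logistic3_fit"
  )
  c0 <- max(y)
  ss_tot <- sum((y - mean(y))^2)
  if (c0 <= 0 || ss_tot == 0) {
    # Null response: no positive signal to fit; the asymptote degenerates to 0.
    out$a <- 0; out$b <- mean(x); out$c <- max(c0, 0)
    out$degenerate <- TRUE
    out$r_squared <- if (ss_tot == 0) NA_real_ else 1 - sum(y^2) / ss_tot
    return(out)
  }
  b0 <- x[which.min(abs(y - c0 / 2))]
  a_grid <- c(0.05, 0.5, 5)
  # Scale the rate grid to the span of x so time-courses (tens of min) and
  # irradiance ladders (decades of W/m2) both get useful starts.
  a_scale <- 10 / max(diff(range(x)), .Machine$double.eps)
  a_grid <- sort(unique(c(a_grid, a_grid * a_scale)))
  if (direction == "off") a_grid <- -a_grid
  best <- NULL
  best_sse <- Inf
  for (a0 in a_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c / (1 + exp(-a * (x - b))),
        data = data.frame(x = x, y = y),
        start = list(a = a0, b = b0, c = c0),
        lower = c(-Inf, -Inf, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  if (is.null(best)) {
    out$degenerate <- TRUE
    return(out)
  }
  cf <- coef(best)
  out$a <- unname(cf["a"]); out$b <- unname(cf["b"]); out$c <- unname(cf["c"])
  out$converged <- isTRUE(best$convInfo$isConv)
  out$r_squared <- 1 - best_sse / ss_tot
  df <- length(x) - 3L
  out$sigma <- sqrt(best_sse / max(df, 1L))
  vc <- tryCatch(vcov(best), error = function(e) NULL)
  out$vcov <- vc
  if (!is.null(vc) && df > 0) {
    se <- sqrt(pmax(diag(vc), 0))
    tq <- qt(0.975, df)
    out$param_cis <- tibble::tibble(
      term = c("a", "b", "c"),
      estimate = c(out$a, out$b, out$c),
      std.error = unname(se[c("a", "b", "c")]),
      conf.low = c(out$a, out$b, out$c) - tq * unname(se[c("a", "b", "c")]),
      conf.high = c(out$a, out$b, out$c) + tq * unname(se[c("a", "b", "c")])
    )
  }
  out
}

#' @exportS3Method base::print
print.logistic3_fit <- function(x, ...) {
  cat(sprintf("<logistic3_fit> direction=%s n=%d%s\n", x$direction, x$n_points,
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  a=%.5g  b=%.5g  c=%.5g  R^2=%.4f\n", x$a, x$b, x$c, x$r_squared))
  invisible(x)
}

#' Predict from a fitted three-parameter logistic
#' @param object A `logistic3_fit`.
#' @param newdata Optional data frame with `x`.
#' @param ... Unused.
#' @return Predicted `y`.
#' @export
predict.logistic3_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  object$c / (1 + exp(-object$a * (x - object$b)))
}

#' @export
tidy.logistic3_fit <- function(x, ...) {
  if (!is.null(x$param_cis)) return(x$param_cis)
  tibble::tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c),
                 std.error = NA_real_, conf.low = NA_real_, conf.high = NA_real_)
}

#' @export
glance.logistic3_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma,
                 nobs = x$n_points, converged = x$converged,
                 degenerate = x$degenerate)
}

#' Derived response quantile (tON_p, tOFF_p, I_p)
#'
#' Inverts the fitted logistic to the x at which the response reaches a
#' fraction `p` of the upper asymptote. For a rise (`mode = "rise"`,
#' tON_p / I_p) this solves `y = p c`, giving
#' `x = b - (1/a) log((1 - p) / p)`; for a decay (`mode = "decay"`, tOFF_p,
#' time measured from light removal) it solves for a fractional *decrease*
#' `p`, i.e. `y = (1 - p) c`, giving `x = b - (1/a) log(p / (1 - p))`.
#' At `p = 0.5` both reduce to the inflection point `b` exactly. Negative
#' derived times are possible (the lag phase can place the 20% crossing
#' before time zero) and are reported as-is.
#'
#' @param fit A `logistic3_fit`.
#' @param p Fraction in (0, 1).
#' @param mode `"rise"` or `"decay"`.
#' @return The derived x (same units as the fit's x axis).
#' @export
derived_x <- function(fit, p, mode = c("rise", "decay")) {
  mode <- match.arg(mode)
  if (any(p <= 0 | p >= 1)) abort("`p` must be strictly between 0 and 1.")
  if (is.na(fit$a) || fit$a == 0) abort("Derived x undefined for a = 0.")
  if (is.na(fit$c) || fit$c <= 0) abort("Derived x undefined for c <= 0.")
  if (mode == "rise") fit$b - log((1 - p) / p) / fit$a
  else fit$b - log(p / (1 - p)) / fit$a
}

#' Bootstrap confidence interval for a derived quantile
#'
#' Seeded residual bootstrap: residuals are resampled with replacement onto
#' the fitted values, the logistic is refit (started at the original
#' estimates), and the derived x recomputed; the interval is the 2.5/97.5
#' percentile of the bootstrap distribution. If more than 20% of refits
#' fail, the interval is marked unreliable. A delta-method interval (first
#' order propagation of the parameter covariance through the inversion
#' formula) is available for comparison.
#'
#' @param fit A converged `logistic3_fit`.
#' @param p Fraction in (0, 1).
#' @param mode `"rise"` or `"decay"`.
#' @param n_boot Bootstrap replicates (>= 200).
#' @param seed Integer seed.
#' @param method `"bootstrap"` or `"delta"`.
#' @return A list: `estimate`, `conf.low`, `conf.high`, `method`, `n_fail`,
#'   `reliable`.
#' @export
derived_ci <- function(fit, p, mode = c("rise", "decay"), n_boot = 500,
                       seed = 1L, method = c("bootstrap", "delta")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  est <- derived_x(fit, p, mode)
  if (method == "delta") {
    if (is.null(fit$vcov)) abort("No parameter covariance available for the delta method.")
    lg <- if (mode == "rise") log((1 - p) / p) else log(p / (1 - p))
    grad <- c(a = lg / fit$a^2, b = 1, c = 0)
    v <- drop(t(grad) %*% fit$vcov[c("a", "b", "c"), c("a", "b", "c")] %*% grad)
    tq <- qt(0.975, max(fit$n_points - 3L, 1L))
    hw <- tq * sqrt(max(v, 0))
    return(list(estimate = est, conf.low = est - hw, conf.high = est + hw,
                method = "delta", n_fail = 0L, reliable = TRUE))
  }
  if (n_boot < 200) abort("`n_boot` must be >= 200.")
  if (!fit$converged) abort("Bootstrap requires a converged fit.")
  x <- fit$data$x
  yhat <- predict(fit)
  res <- fit$data$y - yhat
  start <- list(a = fit$a, b = fit$b, c = fit$c)
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      yb <- yhat + sample(res, length(res), replace = TRUE)
      rf <- tryCatch(
        minpack.lm::nlsLM(yb ~ c / (1 + exp(-a * (x - b))),
                          data = data.frame(x = x, yb = yb),
                          start = start, lower = c(-Inf, -Inf, 0),
                          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL
      )
      if (is.null(rf)) return(NA_real_)
      cf <- coef(rf)
      if (cf["a"] == 0 || cf["c"] <= 0) return(NA_real_)
      if (mode == "rise") cf[["b"]] - log((1 - p) / p) / cf[["a"]]
      else cf[["b"]] - log(p / (1 - p)) / cf[["a"]]
    }, numeric(1))
  })
  n_fail <- sum(is.na(draws))
  ok <- draws[!is.na(draws)]
  qs <- quantile(ok, c(0.025, 0.975), names = FALSE)
  list(estimate = est, conf.low = qs[1L], conf.high = qs[2L],
       method = "bootstrap", n_fail = n_fail,
       reliable = n_fail <= 0.2 * n_boot)
}

#' Table of derived parameters with confidence intervals
#'
#' Computes tON_p / tOFF_p / I_p for the conventional fractions 20%, 50%,
#' 90% with bootstrap 95% CIs.
#'
#' @param fit A `logistic3_fit`.
#' @param kind `"tON"`, `"tOFF"`, or `"I"`; default follows the fit
#'   direction.
#' @param p Fractions (default `c(0.2, 0.5, 0.9)`).
#' @param ci Compute bootstrap CIs?
#' @param n_boot,seed Bootstrap settings.
#' @return A tibble: `kind`, `p`, `estimate`, `conf.low`, `conf.high`,
#'   `reliable`.
#' @export
derived_params <- function(fit, kind = NULL, p = c(0.2, 0.5, 0.9), ci = TRUE,
                           n_boot = 500, seed = 1L) {
  kind <- kind %||% switch(fit$direction, on = "tON", off = "tOFF", dose = "I")
  mode <- if (kind == "tOFF") "decay" else "rise"
  rows <- purrr::map(p, function(pp) {
    est <- derived_x(fit, pp, mode)
    if (ci && fit$converged) {
      ival <- derived_ci(fit, pp, mode, n_boot = n_boot, seed = seed)
      tibble::tibble(kind = kind, p = pp, estimate = est,
                     conf.low = ival$conf.low, conf.high = ival$conf.high,
                     reliable = ival$reliable)
    } else {
      tibble::tibble(kind = kind, p = pp, estimate = est,
                     conf.low = NA_real_, conf.high = NA_real_,
                     reliable = NA)
    }
  })
  dplyr::bind_rows(rows)
}
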