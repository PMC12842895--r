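#' Log-rate/log-interval regression and mode classification
#'
#' Ordinary least squares of `log10(rate)` on `log10(interval)` over a set of
#' rate-interval pairs. The slope of this regression separates modes of
#' evolution: a directional trend yields rates independent of interval
#' (slope 0), an unbiased random walk yields rates falling as the inverse
#' square root of the interval (slope -1/2), and stasis -- a fixed net
#' difference regardless of elapsed time -- yields slope -1. The mode call
#' assigns the anchor slope contained in the 95% confidence interval when
#' exactly one of \{0, -0.5, -1\} is contained; otherwise `"ambiguous"`.
#' Zero (and non-finite) rates are dropped before taking logs and their count
#' reported.
#'
#' When the fit is numerically exact (residual variance ~ 0, as with
#' noise-free synthetic lineages) the confidence interval degenerates to a
#' point and classification falls back to nearest-anchor matching within
#' `classify_tolerance`.
#'
#' @param pairs data frame with columns `interval` and `rate`, as produced by
#'   [rate_interval_pairs()].
#' @param classify_tolerance half-width for nearest-anchor classification
#'   when the slope is estimated without residual error. Default 0.05.
#' @param conf_level confidence level for the slope interval. Default 0.95.
#' @return An object of class `lri_fit`: `slope`, `intercept` (log10 rate at
#'   unit interval), `slope_interval`, `n_pairs` (used), `n_zero_dropped`,
#'   `mode_call`, and the underlying `lm` fit as `model`.
#' @examples
#' ts <- trait_series(data.frame(age = c(4000, 3000, 2000, 1000, 0),
#'                               mean = 900 * exp(0.0001 * seq(0, 4000, 1000)),
#'                               sd = 90, n = 30), age_unit = "generations")
#' lri_fit(rate_interval_pairs(ts))   # constant-step trend: slope ~ 0
#' @export
lri_fit <- function(pairs, classify_tolerance = 0.05, conf_level = 0.95) {
  stopifnot(is.data.frame(pairs), all(c("interval", "rate") %in% names(pairs)))
  ok <- is.finite(pairs$rate) & pairs$rate > 0 & pairs$interval > 0
  n_zero <- sum(!ok)
  d <- data.frame(log_interval = log10(pairs$interval[ok]),
                  log_rate = log10(pairs$rate[ok]))
  if (nrow(d) < 3L) {
    stop(sprintf("need >= 3 positive-rate pairs for the log-rate/log-interval regression (have %d after dropping %d)",
                 nrow(d), n_zero), call. = FALSE)
  }
  fit <- stats::lm(log_rate ~ log_interval, data = d)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  sigma <- stats::sigma(fit)
  anchors <- c(directional = 0, random_walk = -0.5, stasis = -1)
  if (!is.finite(sigma) || sigma < 1e-10) {
    ci <- c(slope, slope)
    hit <- abs(anchors - slope) <= classify_tolerance
    mode_call <- if (sum(hit) == 1L) names(anchors)[hit] else "ambiguous"
  } else {
    ci <- unname(stats::confint(fit, "log_interval", level = conf_level)[1L, ])
    hit <- anchors >= ci[1L] & anchors <= ci[2L]
    mode_call <- if (sum(hit) == 1L) names(anchors)[hit] else "ambiguous"
  }
  structure(list(slope = slope, intercept = intercept,
                 slope_interval = ci, conf_level = conf_level,
                 n_pairs = nrow(d), n_zero_dropped = n_zero,
                 mode_call = mode_call, model = fit),
            class = "lri_fit")
}

#' @export
print.lri_fit <- function(x, digits = 4, ...) {
  cat("Log-rate/log-interval regression\n")
  cat(sprintf("  slope: %s  (%g%% CI %s to %s)\n",
              format(x$slope, digits = digits), 100 * x$conf_level,
              format(x$slope_interval[1L], digits = digits),
              format(x$slope_interval[2L], digits = digits)))
  cat(sprintf("  intercept (log10 rate at 1 generation): %s\n",
              format(x$intercept, digits = digits)))
  cat(sprintf("  pairs used: %d (zero/non-finite rates dropped: %d)\n",
              x$n_pairs, x$n_zero_dropped))
  cat(sprintf("  mode call: %s  (anchors: directional 0, random walk -0.5, stasis -1)\n",
              x$mode_call))
  invisible(x)
}

#' @export
coef.lri_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.lri_fit <- function(object, ...) {
  out <- list(fit = object, lm_summary = summary(object$model))
  class(out) <- "summary.lri_fit"
  out
}

#' @export
print.summary.lri_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying least-squares fit:\n")
  print(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
predict.lri_fit <- function(object, interval_generations, ...) {
  stopifnot(all(interval_generations > 0))
  10^stats::predict(object$model,
                    newdata = data.frame(log_interval = log10(interval_generations)))
}

#' @export
plot.lri_fit <- function(x, ...) {
  d <- x$model$model
  graphics::plot(d$log_interval, d$log_rate,
                 xlab = "log10 interval (generations)",
                 ylab = "log10 |rate| (per generation)", ...)
  graphics::abline(x$model, lty = 1)
  for (a in c(0, -0.5, -1)) {
    graphics::abline(a = mean(d$log_rate) - a * mean(d$log_interval), b = a,
                     lty = 3, col = "grey50")
  }
  invisible(x)
}
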