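#' Net divergence on the natural-log mean scale
#'
#' Returns `ln(mean_to / mean_from)` between two bins of a trait series: the
#' proportional (mean-standardized) net change of the trait mean over the
#' interval. Positive when the trait increased toward the more recent bin.
#'
#' @param series a [trait_series()] (bins oldest first).
#' @param from_bin,to_bin bin indices (1 = oldest).
#' @return The log mean-ratio (dimensionless scalar).
#' @examples
#' ts <- trait_series(data.frame(age = c(2e6, 1e4), mean = c(400, 1350),
#'                               sd = c(50, 120), n = c(5, 40)),
#'                    age_unit = "years", generation_time = 29)
#' net_divergence_log(ts, 1, 2)  # ln(1350/400) = 1.2164
#' @export
net_divergence_log <- function(series, from_bin, to_bin) {
  stopifnot(inherits(series, "trait_series"))
  nb <- nrow(series$bins)
  stopifnot(from_bin >= 1, from_bin <= nb, to_bin >= 1, to_bin <= nb)
  m_from <- series$bins$mean[from_bin]
  m_to <- series$bins$mean[to_bin]
  if (m_from <= 0 || m_to <= 0) {
    stop("log mean-ratio requires strictly positive bin means", call. = FALSE)
  }
  log(m_to / m_from)
}

#' Pooled standard deviation of two bins
#'
#' Square root of the (n - 1)-weighted average of the two sample variances;
#' the per-interval denominator of the haldane.
#'
#' @param sd_a,sd_b sample standard deviations.
#' @param n_a,n_b sample sizes (each >= 2).
#' @return Pooled SD in trait units.
#' @examples
#' pooled_sd(3, 3, 4, 3)  # sqrt((2*9 + 2*16)/4) = 3.5355
#' @export
pooled_sd <- function(sd_a, n_a, sd_b, n_b) {
  if (is.na(sd_a) || is.na(sd_b)) {
    stop("pooled SD requires both sample SDs", call. = FALSE)
  }
  if (n_a < 2 || n_b < 2) {
    stop("pooled SD requires n >= 2 in both samples", call. = FALSE)
  }
  sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
}

#' Per-generation rate of evolution over one interval
#'
#' The haldane rate is the change in trait mean per generation expressed in
#' pooled phenotypic standard deviations; the companion mean-standardized
#' rate is the per-generation change of the natural-log mean (the scale on
#' which evolvability and the drift null are expressed). The two always agree
#' in sign.
#'
#' @param mean_from,mean_to endpoint trait means (ancestor, descendant).
#' @param pooled_sd pooled phenotypic SD of the two endpoint samples
#'   (see [pooled_sd()]), > 0.
#' @param interval_generations elapsed generations, > 0.
#' @return An object of class `rate_estimate` with fields
#'   `interval_generations`, `delta_sd_units`, `rate_haldanes`,
#'   `delta_log_mean`, `rate_mean_standardized`. The mean-standardized fields
#'   are `NA` when either mean is non-positive.
#' @examples
#' haldane_rate(100, 106, pooled_sd = 10, interval_generations = 4)
#' @export
haldane_rate <- function(mean_from, mean_to, pooled_sd, interval_generations) {
  if (interval_generations <= 0) {
    stop("interval_generations must be > 0", call. = FALSE)
  }
  if (is.na(pooled_sd) || pooled_sd <= 0) {
    stop("pooled_sd must be > 0", call. = FALSE)
  }
  delta_sd <- (mean_to - mean_from) / pooled_sd
  if (mean_from > 0 && mean_to > 0) {
    dlog <- log(mean_to / mean_from)
  } else {
    dlog <- NA_real_
  }
  structure(list(interval_generations = interval_generations,
                 delta_sd_units = delta_sd,
                 rate_haldanes = delta_sd / interval_generations,
                 delta_log_mean = dlog,
                 rate_mean_standardized = dlog / interval_generations),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Rate of evolution over %g generations\n", x$interval_generations))
  cat(sprintf("  haldanes (SD/generation):        %s\n",
              format(x$rate_haldanes, digits = digits)))
  cat(sprintf("  mean-standardized (/generation): %s\n",
              format(x$rate_mean_standardized, digits = digits)))
  invisible(x)
}

#' All pairwise rate-interval pairs of a trait series
#'
#' Computes, for every ordered pair of usable bins, the elapsed interval in
#' generations and the absolute per-generation rate on the requested scale.
#' All pairwise intervals (not only adjacent bins) are returned because
#' rate-interval scaling analysis needs a spread of interval lengths.
#' On the haldane scale a bin is usable when it has `n >= 2` and a recorded
#' SD; on the mean-standardized scale when its mean is positive. Pairs whose
#' pooled SD is zero are dropped (their count is reported in the
#' `n_dropped_zero_sd` attribute).
#'
#' @param series a [trait_series()].
#' @param scale `"mean_standardized"` (default) or `"haldanes"`.
#' @param generation_time years per generation, for series with ages in
#'   years; defaults to the value stored in the series.
#' @return Data frame with columns `interval` (generations) and `rate`
#'   (absolute, per generation), attributes `scale`, `n_bins_used`,
#'   `n_dropped_zero_sd`.
#' @seealso [lri_fit()]
#' @export
rate_interval_pairs <- function(series,
                                scale = c("mean_standardized", "haldanes"),
                                generation_time = NULL) {
  stopifnot(inherits(series, "trait_series"))
  scale <- match.arg(scale)
  ages <- ages_generations(series, generation_time)
  b <- series$bins
  usable <- if (scale == "haldanes") {
    b$n >= 2 & !is.na(b$sd)
  } else {
    b$mean > 0
  }
  idx <- which(usable)
  if (length(idx) < 2L) {
    stop("need at least 2 usable bins for rate-interval pairs", call. = FALSE)
  }
  pairs <- utils::combn(idx, 2L)
  i <- pairs[1L, ]  # older bin (larger age before present)
  j <- pairs[2L, ]
  interval <- ages[i] - ages[j]
  keep <- interval > 0
  i <- i[keep]; j <- j[keep]; interval <- interval[keep]
  dropped_zero_sd <- 0L
  if (scale == "haldanes") {
    psd <- mapply(pooled_sd, b$sd[i], b$n[i], b$sd[j], b$n[j])
    ok <- psd > 0
    dropped_zero_sd <- sum(!ok)
    rate <- abs(b$mean[j[ok]] - b$mean[i[ok]]) / (psd[ok] * interval[ok])
    interval <- interval[ok]
  } else {
    rate <- abs(log(b$mean[j] / b$mean[i])) / interval
  }
  out <- data.frame(interval = interval, rate = rate)
  attr(out, "scale") <- scale
  attr(out, "n_bins_used") <- length(idx)
  attr(out, "n_dropped_zero_sd") <- dropped_zero_sd
  out
}
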