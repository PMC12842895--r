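#' Null variance of divergence under constant-heritability drift
#'
#' Under the neutral theory of phenotypic evolution with constant
#' heritability, the among-lineage variance of evolutionary outcomes on the
#' evolvability / natural-log mean scale after `t` generations is
#' `e * t / Ne`: divergence by drift is larger when the population is small
#' (stronger drift) or the trait more evolvable.
#'
#' @param params a [population_params()] (or evolvability as a number, with
#'   `effective_size_Ne` supplied).
#' @param t_generations elapsed generations, >= 0.
#' @param effective_size_Ne effective size, used when `params` is numeric.
#' @return The null variance (dimensionless, log-mean scale).
#' @examples
#' drift_null_variance(population_params(0.009, 5000), 7.4e4)  # 0.1332
#' @export
drift_null_variance <- function(params, t_generations, effective_size_Ne = NULL) {
  if (is.numeric(params)) {
    stopifnot(!is.null(effective_size_Ne))
    params <- population_params(evolvability_e = params,
                                effective_size_Ne = effective_size_Ne)
  }
  stopifnot(inherits(params, "population_params"))
  if (t_generations < 0) stop("t_generations must be >= 0", call. = FALSE)
  params$evolvability_e * t_generations / params$effective_size_Ne
}

#' Null variance of divergence under mutation-drift equilibrium
#'
#' At mutation-drift equilibrium the among-lineage variance on the
#' mean-standardized scale grows as
#' `divergence_factor * sigma^2_m * t`. The accumulation constant is an
#' explicit, reported parameter (default 2); mutation-drift equilibrium
#' typically predicts faster neutral divergence than constant-heritability
#' drift.
#'
#' @param mut a [mutation_params()].
#' @param t_generations elapsed generations, >= 0.
#' @return The null variance (dimensionless).
#' @examples
#' mutation_drift_null_variance(mutation_params(4e-6, 2), 7.4e4)  # 0.592
#' @export
mutation_drift_null_variance <- function(mut, t_generations) {
  stopifnot(inherits(mut, "mutation_params"))
  if (t_generations < 0) stop("t_generations must be >= 0", call. = FALSE)
  mut$divergence_factor * mut$mutational_variance * t_generations
}

#' Test an observed divergence against a neutral null variance
#'
#' Standardizes the observed divergence by the null SD and reports the
#' z-score with a normal tail probability. With `tails = "one"` the p-value
#' is the upper tail `P(Z >= z)` of the signed z-score (the alternative being
#' divergence beyond the observed direction); with `tails = "two"` it is
#' `2 * P(Z >= |z|)`, capped at 1. Two-tailed is the default since the
#' neutral distribution of outcomes is symmetric.
#'
#' @param observed_divergence net divergence on the same (log-mean /
#'   mean-standardized) scale as the null variance.
#' @param null_variance variance of divergence under the null, > 0 (from
#'   [drift_null_variance()] or [mutation_drift_null_variance()]).
#' @param tails `"two"` (default) or `"one"`.
#' @param null_model label recorded in the result
#'   (`"drift_constant_heritability"` or `"mutation_drift"`).
#' @return An object of class `neutrality_test` with fields `null_model`,
#'   `null_variance`, `observed_divergence`, `z_score`, `p_value`, `tails`.
#' @examples
#' v <- drift_null_variance(population_params(0.009, 5000), 7.4e4)
#' neutral_divergence_test(0.365, v, tails = "one")  # z ~ 1.00, p ~ 0.159
#' @export
neutral_divergence_test <- function(observed_divergence, null_variance,
                                    tails = c("two", "one"),
                                    null_model = c("drift_constant_heritability",
                                                   "mutation_drift")) {
  tails <- match.arg(tails)
  null_model <- match.arg(null_model)
  if (!is.numeric(null_variance) || null_variance <= 0) {
    stop("null_variance must be > 0", call. = FALSE)
  }
  z <- observed_divergence / sqrt(null_variance)
  p <- if (tails == "one") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }
  structure(list(null_model = null_model, null_variance = null_variance,
                 observed_divergence = observed_divergence,
                 z_score = z, p_value = p, tails = tails),
            class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, digits = 4, ...) {
  cat("Neutral divergence test\n")
  cat(sprintf("  null model:          %s\n", x$null_model))
  cat(sprintf("  null variance:       %s\n", format(x$null_variance, digits = digits)))
  cat(sprintf("  observed divergence: %s (log-mean scale)\n",
              format(x$observed_divergence, digits = digits)))
  cat(sprintf("  z = %s, %s-tailed p = %s\n",
              format(x$z_score, digits = digits), x$tails,
              format(x$p_value, digits = digits)))
  invisible(x)
}

#' Mean-standardized selection gradient from an observed rate
#'
#' Rearranges the univariate, evolvability-standardized form of the Lande
#' equation: the per-generation mean-standardized response equals the
#' product of evolvability and the mean-standardized selection gradient, so
#' `beta = rate / e`. A gradient of 1 equals the strength of selection on
#' fitness itself.
#'
#' @param rate_mean_standardized per-generation rate on the natural-log mean
#'   scale (sign preserved).
#' @param evolvability_e evolvability (mean-standardized additive genetic
#'   variance), > 0.
#' @return An object of class `selection_gradient` with fields
#'   `beta_mean_standardized`, `rate_used`, `evolvability_e`.
#' @examples
#' # 0.15 phenotypic SD/generation at a phenotypic CV of 0.10:
#' selection_gradient(0.15 * 0.10, 0.009)  # beta = 1.67
#' @export
selection_gradient <- function(rate_mean_standardized, evolvability_e) {
  if (!is.numeric(evolvability_e) || evolvability_e <= 0) {
    stop("evolvability_e must be > 0", call. = FALSE)
  }
  structure(list(beta_mean_standardized = rate_mean_standardized / evolvability_e,
                 rate_used = rate_mean_standardized,
                 evolvability_e = evolvability_e),
            class = "selection_gradient")
}

#' @export
print.selection_gradient <- function(x, digits = 3, ...) {
  cat(sprintf("Mean-standardized selection gradient: beta = %s\n",
              format(x$beta_mean_standardized, digits = digits)))
  cat(sprintf("  (rate %s per generation / evolvability %g)\n",
              format(x$rate_used, digits = digits), x$evolvability_e))
  invisible(x)
}

#' Selection gradient required to sustain an observed interval of change
#'
#' Composes the net log-mean divergence between two bins, the elapsed
#' generations, and the Lande rearrangement: the average per-generation
#' mean-standardized rate over the interval, divided by evolvability, is the
#' sustained directional-selection gradient that would produce the observed
#' change in the absence of drift.
#'
#' @param series a [trait_series()].
#' @param from_bin,to_bin bin indices (1 = oldest).
#' @param params a [population_params()] supplying evolvability and, for
#'   series with ages in years, the generation time.
#' @return A `selection_gradient` (see [selection_gradient()]) with the
#'   interval's generations attached as attribute `interval_generations`.
#' @export
required_beta_over_interval <- function(series, from_bin, to_bin, params) {
  stopifnot(inherits(series, "trait_series"), inherits(params, "population_params"))
  dlog <- net_divergence_log(series, from_bin, to_bin)
  ages <- ages_generations(series, params$generation_time)
  t_gen <- abs(ages[from_bin] - ages[to_bin])
  if (t_gen <= 0) stop("bins span zero generations", call. = FALSE)
  out <- selection_gradient(dlog / t_gen, params$evolvability_e)
  attr(out, "interval_generations") <- t_gen
  out
}
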