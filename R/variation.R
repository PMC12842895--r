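#' Coefficient of variation of a sample
#'
#' Sample SD (n - 1 denominator) divided by the sample mean, optionally with
#' the small-sample correction factor `(1 + 1/(4n))`. CVs are stored as
#' dimensionless proportions; multiply by 100 to render percent. By default
#' the correction is applied when `n < 30` (fossil samples are typically
#' tiny); the correction state is always recorded in the result.
#'
#' @param values numeric trait values, all > 0, length >= 2.
#' @param corrected `TRUE` / `FALSE`, or `NULL` (default) to apply the
#'   correction when `n < 30`.
#' @return An object of class `cv_estimate`: `cv`, `n`, `corrected`,
#'   `sex_pooling`.
#' @examples
#' cv_estimate(c(8, 10, 12), corrected = FALSE)  # 0.2
#' cv_estimate(c(8, 10, 12), corrected = TRUE)   # 0.2 * 13/12
#' @export
cv_estimate <- function(values, corrected = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("CV requires n >= 2", call. = FALSE)
  if (anyNA(values)) stop("CV input contains missing values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("CV requires a positive mean", call. = FALSE)
  if (is.null(corrected)) corrected <- n < 30L
  cv <- stats::sd(values) / m
  if (corrected) cv <- cv * (1 + 1 / (4 * n))
  structure(list(cv = cv, n = n, corrected = corrected, sex_pooling = "none"),
            class = "cv_estimate")
}

#' @export
print.cv_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("CV = %s (%.1f%%), n = %d, %s, sex pooling: %s\n",
              format(x$cv, digits = digits), 100 * x$cv, x$n,
              if (x$corrected) "small-sample corrected" else "uncorrected",
              x$sex_pooling))
  invisible(x)
}

# per-sex summaries (n, mean, sd) from a specimen table or species rows
.sex_summaries <- function(x) {
  if (inherits(x, "specimen_table") ||
      (is.data.frame(x) && all(c("sex", "value") %in% names(x)))) {
    excluded <- sum(x$sex == "unknown")
    x <- x[x$sex != "unknown", , drop = FALSE]
    if (nrow(x) == 0L) stop("no specimens of known sex", call. = FALSE)
    s <- split(x$value, x$sex)
    out <- data.frame(sex = names(s),
                      n = vapply(s, length, integer(1)),
                      mean = vapply(s, mean, numeric(1)),
                      sd = vapply(s, function(v) if (length(v) >= 2) stats::sd(v) else NA_real_,
                                  numeric(1)))
  } else if (is.data.frame(x) && all(c("sex", "n", "mean", "sd") %in% names(x))) {
    out <- x[x$sex %in% c("female", "male"), c("sex", "n", "mean", "sd")]
    excluded <- 0L
    if (nrow(out) == 0L) stop("no female/male rows", call. = FALSE)
  } else {
    stop("expected a specimen table (sex, value) or per-sex summary rows (sex, n, mean, sd)",
         call. = FALSE)
  }
  attr(out, "n_excluded_unknown") <- excluded
  out
}

#' Pooled within-sex coefficient of variation
#'
#' CV computed from sex-stratified variances and a sample-size-weighted grand
#' mean, removing the contribution of sexual dimorphism:
#' `CV = sqrt( sum_s (n_s - 1) sd_s^2 / sum_s (n_s - 1) ) /
#'  ( sum_s n_s mean_s / sum_s n_s )` over sex classes `s`. Whenever sex
#' means differ and within-sex SDs are comparable this is smaller than the
#' total-sample CV. Unknown-sex specimens are excluded (their count is
#' attached as attribute `n_excluded_unknown`, never imputed).
#'
#' @param x a `specimen_table` (columns `sex`, `value`) or the per-sex
#'   summary rows of one species from a `species_cv_table` (columns `sex`,
#'   `n`, `mean`, `sd`).
#' @param corrected as in [cv_estimate()]; the correction uses the total n
#'   across sex classes.
#' @return A `cv_estimate` with `sex_pooling = "within_sex"`.
#' @examples
#' st <- specimen_table(data.frame(
#'   specimen_id = 1:6, group = "a",
#'   sex = rep(c("male", "female"), each = 3),
#'   value = c(90, 100, 110, 110, 120, 130)))
#' pooled_within_sex_cv(st, corrected = FALSE)  # 10 / 110 = 0.0909
#' @export
pooled_within_sex_cv <- function(x, corrected = NULL) {
  s <- .sex_summaries(x)
  usable_var <- s$n >= 2 & !is.na(s$sd)
  if (!any(usable_var)) {
    stop("pooled within-sex CV needs at least one sex class with n >= 2",
         call. = FALSE)
  }
  w <- s$n - 1
  within_var <- sum(w[usable_var] * s$sd[usable_var]^2) / sum(w[usable_var])
  grand_mean <- sum(s$n * s$mean) / sum(s$n)
  if (grand_mean <= 0) stop("CV requires a positive mean", call. = FALSE)
  n_total <- sum(s$n)
  if (is.null(corrected)) corrected <- n_total < 30L
  cv <- sqrt(within_var) / grand_mean
  if (corrected) cv <- cv * (1 + 1 / (4 * n_total))
  out <- structure(list(cv = cv, n = n_total, corrected = corrected,
                        sex_pooling = "within_sex"),
                   class = "cv_estimate")
  attr(out, "n_excluded_unknown") <- attr(s, "n_excluded_unknown")
  out
}

# total-sample (sex-ignoring) CV from per-sex summary rows of one species
.total_cv_from_rows <- function(rows, corrected = FALSE) {
  pooled_row <- rows[rows$sex == "pooled", , drop = FALSE]
  if (nrow(pooled_row) >= 1L) {
    n <- pooled_row$n[1L]
    cv <- pooled_row$sd[1L] / pooled_row$mean[1L]
  } else {
    s <- rows[rows$sex %in% c("female", "male"), , drop = FALSE]
    n <- sum(s$n)
    M <- sum(s$n * s$mean) / n
    ss <- sum((s$n - 1) * s$sd^2 + s$n * (s$mean - M)^2)
    cv <- sqrt(ss / (n - 1)) / M
  }
  if (corrected) cv <- cv * (1 + 1 / (4 * n))
  cv
}

#' Point difference of two coefficients of variation
#'
#' `(CV_A - CV_B) * 100`, in percentage points. Antisymmetric in its
#' arguments.
#'
#' @param values_a,values_b numeric trait samples (see [cv_estimate()]).
#' @param corrected as in [cv_estimate()], applied to each sample under its
#'   own n.
#' @return The difference in percentage points (numeric scalar).
#' @export
delta_cv <- function(values_a, values_b, corrected = NULL) {
  100 * (cv_estimate(values_a, corrected)$cv - cv_estimate(values_b, corrected)$cv)
}

#' Confidence interval for a difference of CVs
#'
#' Point estimate and confidence interval for `CV_A - CV_B` (percentage
#' points). The default method resamples each group independently with
#' replacement and takes the percentile interval of the bootstrap
#' distribution of the difference; it is seeded and exactly reproducible.
#' The asymptotic method uses the large-sample approximation
#' `var(CV) ~ CV^2 (0.5 + CV^2) / n` per sample, variances summed, and a
#' normal interval.
#'
#' @inheritParams delta_cv
#' @param method `"bootstrap"` (default) or `"asymptotic"`.
#' @param level confidence level, default 0.95.
#' @param n_boot bootstrap resamples, default 10000 (minimum 1000).
#' @param seed integer seed for the bootstrap, or `NULL`.
#' @return An object of class `delta_cv` with fields `delta`, `ci_low`,
#'   `ci_high`, `level`, `method`, `n_a`, `n_b`, `n_boot`, `seed`, and
#'   `warning` when the percentile interval fails to bracket the point
#'   estimate.
#' @examples
#' a <- c(600, 650, 700, 720, 800, 850)
#' b <- c(1300, 1350, 1400, 1450, 1500, 1550)
#' delta_cv_ci(a, b, seed = 1, n_boot = 2000)
#' @export
delta_cv_ci <- function(values_a, values_b, method = c("bootstrap", "asymptotic"),
                        level = 0.95, n_boot = 10000, seed = NULL,
                        corrected = NULL) {
  method <- match.arg(method)
  est_a <- cv_estimate(values_a, corrected)
  est_b <- cv_estimate(values_b, corrected)
  delta <- 100 * (est_a$cv - est_b$cv)
  alpha <- (1 - level) / 2
  warn <- NULL
  if (method == "bootstrap") {
    if (n_boot < 1000) stop("bootstrap requires n_boot >= 1000", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    cv_a <- .boot_cvs(values_a, n_boot, est_a$corrected)
    cv_b <- .boot_cvs(values_b, n_boot, est_b$corrected)
    draws <- 100 * (cv_a - cv_b)
    ci <- unname(stats::quantile(draws, c(alpha, 1 - alpha)))
  } else {
    if (est_a$n < 5 || est_b$n < 5) {
      stop("asymptotic interval requires n >= 5 per sample", call. = FALSE)
    }
    v <- est_a$cv^2 * (0.5 + est_a$cv^2) / est_a$n +
      est_b$cv^2 * (0.5 + est_b$cv^2) / est_b$n
    half <- stats::qnorm(1 - alpha) * 100 * sqrt(v)
    ci <- c(delta - half, delta + half)
  }
  if (delta < ci[1L] || delta > ci[2L]) {
    warn <- "interval does not bracket the point estimate"
    warning(warn, call. = FALSE)
  }
  structure(list(delta = delta, ci_low = ci[1L], ci_high = ci[2L],
                 level = level, method = method,
                 n_a = est_a$n, n_b = est_b$n,
                 n_boot = if (method == "bootstrap") n_boot else NA_integer_,
                 seed = seed, corrected = c(a = est_a$corrected, b = est_b$corrected),
                 warning = warn),
            class = "delta_cv")
}

# vectorized bootstrap CVs: one column per resample; resamples with
# non-positive mean are redrawn (positivity makes this rare to impossible),
# capped at 100 passes
.boot_cvs <- function(values, n_boot, corrected) {
  n <- length(values)
  factor <- if (corrected) 1 + 1 / (4 * n) else 1
  out <- rep(NA_real_, n_boot)
  todo <- seq_len(n_boot)
  passes <- 0L
  while (length(todo) > 0L && passes < 100L) {
    m <- matrix(sample(values, n * length(todo), replace = TRUE), nrow = n)
    mu <- colMeans(m)
    ok <- mu > 0
    sds <- sqrt(pmax(0, (colSums(m^2) - n * mu^2) / (n - 1)))
    out[todo[ok]] <- factor * sds[ok] / mu[ok]
    todo <- todo[!ok]
    passes <- passes + 1L
  }
  if (length(todo) > 0L) {
    warning(sprintf("%d degenerate bootstrap resamples dropped after redraw cap",
                    length(todo)), call. = FALSE)
    out <- out[!is.na(out)]
  }
  out
}

#' @export
print.delta_cv <- function(x, digits = 3, ...) {
  cat(sprintf("Delta CV = %s percentage points (%g%% CI %s to %s)\n",
              format(x$delta, digits = digits), 100 * x$level,
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits)))
  cat(sprintf("  method: %s%s; n = %d vs %d\n", x$method,
              if (x$method == "bootstrap") sprintf(" (%d resamples, seed %s)",
                                                   x$n_boot,
                                                   if (is.null(x$seed)) "unset" else x$seed)
              else "",
              x$n_a, x$n_b))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Per-species CVs from a comparative table
#'
#' @param comparative a `species_cv_table`.
#' @param sex_pooling `"within_sex"` (pooled within-sex CV per species) or
#'   `"none"` (total CV including sex differences).
#' @param corrected apply the small-sample correction (`TRUE`/`FALSE`;
#'   default `FALSE` for comparative summaries).
#' @param min_n drop species whose total n is below this (default 2).
#' @return Named numeric vector of per-species CVs (proportions).
#' @export
species_cvs <- function(comparative, sex_pooling = c("within_sex", "none"),
                        corrected = FALSE, min_n = 2) {
  stopifnot(inherits(comparative, "species_cv_table") || is.data.frame(comparative))
  sex_pooling <- match.arg(sex_pooling)
  per_species <- split(as.data.frame(comparative), comparative$species)
  cvs <- vapply(per_species, function(rows) {
    if (sum(rows$n) < min_n) return(NA_real_)
    if (sex_pooling == "within_sex") {
      ok <- tryCatch(pooled_within_sex_cv(rows, corrected = corrected)$cv,
                     error = function(e) NA_real_)
      ok
    } else {
      .total_cv_from_rows(rows, corrected = corrected)
    }
  }, numeric(1))
  cvs[!is.na(cvs)]
}

#' Percentile placement of a focal CV in a comparative distribution
#'
#' Locates a focal species' CV within the distribution of per-species CVs
#' from a comparative table (e.g. where a fossil hominin's endocranial-volume
#' CV falls among primates). The empirical percentile uses the midpoint
#' convention for ties: `100 * (#below + #tied/2) / n`.
#'
#' @param focal_cv the focal CV (proportion).
#' @inheritParams species_cvs
#' @return An object of class `cv_percentile`: `percentile`, `n_species`,
#'   `min`, `median`, `max`, and the per-species CVs used.
#' @export
cv_percentile <- function(focal_cv, comparative,
                          sex_pooling = c("within_sex", "none"),
                          corrected = FALSE, min_n = 2) {
  cvs <- species_cvs(comparative, sex_pooling, corrected, min_n)
  if (length(cvs) < 2L) {
    stop("comparative table yields fewer than 2 species CVs", call. = FALSE)
  }
  pct <- 100 * (sum(cvs < focal_cv) + 0.5 * sum(cvs == focal_cv)) / length(cvs)
  structure(list(percentile = pct, n_species = length(cvs),
                 min = min(cvs), median = stats::median(cvs), max = max(cvs),
                 species_cvs = cvs, focal_cv = focal_cv,
                 sex_pooling = match.arg(sex_pooling)),
            class = "cv_percentile")
}

#' @export
print.cv_percentile <- function(x, digits = 3, ...) {
  cat(sprintf("Focal CV %s sits at the %.1f percentile of %d species\n",
              format(x$focal_cv, digits = digits), x$percentile, x$n_species))
  cat(sprintf("  comparative CVs: min %s, median %s, max %s (%s pooling)\n",
              format(x$min, digits = digits), format(x$median, digits = digits),
              format(x$max, digits = digits), x$sex_pooling))
  invisible(x)
}

#' @export
plot.cv_percentile <- function(x, breaks = "Sturges", ...) {
  graphics::hist(100 * x$species_cvs, breaks = breaks,
                 xlab = "CV (%)", main = "Comparative CV distribution", ...)
  graphics::rug(100 * x$focal_cv, lwd = 2, col = "red")
  invisible(x)
}
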