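#' Construct a trait time series
#'
#' A `trait_series` holds ordered per-time-bin summaries (age, sample mean,
#' sample SD, sample size) of one continuous trait in one lineage, e.g. binned
#' endocranial volume estimates through the Pleistocene. Ages are times before
#' present, in years or generations; the canonical bin order is oldest first,
#' so that divergence is reckoned ancestor to descendant.
#'
#' @param bins data frame with columns `age`, `mean`, `sd`, `n`. `sd` may be
#'   `NA` only in bins with `n = 1`; such bins are excluded from rate
#'   denominators that need a phenotypic SD.
#' @param lineage label for the lineage (character scalar).
#' @param age_unit `"years"` or `"generations"` (time before present).
#' @param generation_time years per generation; required to express ages in
#'   generations when `age_unit = "years"`.
#' @param trait_scale `"raw"` (trait units) or `"natural_log"`.
#' @return An object of class `trait_series`.
#' @examples
#' ts <- trait_series(data.frame(age = c(2e6, 1e6, 1e4),
#'                               mean = c(800, 1000, 1350),
#'                               sd = c(90, 100, 120), n = c(8, 12, 40)),
#'                    lineage = "Homo", age_unit = "years",
#'                    generation_time = 29)
#' ts
#' @seealso [read_trait_series()], [rate_interval_pairs()]
#' @export
trait_series <- function(bins, lineage = "lineage", age_unit = c("years", "generations"),
                         generation_time = NULL,
                         trait_scale = c("raw", "natural_log")) {
  age_unit <- match.arg(age_unit)
  trait_scale <- match.arg(trait_scale)
  bins <- as.data.frame(bins)
  required <- c("age", "mean", "sd", "n")
  missing_cols <- setdiff(required, names(bins))
  if (length(missing_cols) > 0L) {
    stop("trait series is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bins <- bins[required]
  for (col in required) {
    if (!is.numeric(bins[[col]]) && !all(is.na(bins[[col]]))) {
      bad <- which(is.na(suppressWarnings(as.numeric(bins[[col]]))) & !is.na(bins[[col]]))
      stop(sprintf("non-numeric value in column '%s', row %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    bins[[col]] <- as.numeric(bins[[col]])
  }
  if (anyNA(bins$age) || anyNA(bins$mean) || anyNA(bins$n)) {
    col <- c("age", "mean", "n")[c(anyNA(bins$age), anyNA(bins$mean), anyNA(bins$n))][1L]
    stop(sprintf("missing value in column '%s', row %s", col,
                 paste(which(is.na(bins[[col]])), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(bins$age)) {
    dup <- bins$age[duplicated(bins$age)][1L]
    stop(sprintf("duplicate age value %g in column 'age'", dup), call. = FALSE)
  }
  if (any(bins$n < 1)) {
    stop(sprintf("n < 1 in column 'n', row %s",
                 paste(which(bins$n < 1), collapse = ", ")), call. = FALSE)
  }
  bad_sd <- which(!is.na(bins$sd) & bins$sd < 0)
  if (length(bad_sd) > 0L) {
    stop(sprintf("negative sd in column 'sd', row %s",
                 paste(bad_sd, collapse = ", ")), call. = FALSE)
  }
  na_sd <- which(is.na(bins$sd) & bins$n >= 2)
  if (length(na_sd) > 0L) {
    stop(sprintf("missing sd with n >= 2 in column 'sd', row %s (sd may be blank only when n = 1)",
                 paste(na_sd, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(generation_time)) {
    stopifnot(is.numeric(generation_time), length(generation_time) == 1L,
              generation_time > 0)
  }
  # oldest first: largest time-before-present leads
  bins <- bins[order(bins$age, decreasing = TRUE), , drop = FALSE]
  rownames(bins) <- NULL
  structure(list(lineage = as.character(lineage)[1L], bins = bins,
                 age_unit = age_unit, generation_time = generation_time,
                 trait_scale = trait_scale),
            class = "trait_series")
}

#' @export
print.trait_series <- function(x, ...) {
  cat(sprintf("Trait series '%s': %d bins, ages in %s (oldest first), %s scale\n",
              x$lineage, nrow(x$bins), x$age_unit, x$trait_scale))
  if (!is.null(x$generation_time)) {
    cat(sprintf("  generation time: %g years\n", x$generation_time))
  }
  print(x$bins, ...)
  invisible(x)
}

#' @export
as.data.frame.trait_series <- function(x, ...) x$bins

#' @export
length.trait_series <- function(x) nrow(x$bins)

#' Bin ages in generations before present
#'
#' Converts stored ages to generations using real-valued (floor-free) division
#' by the generation time when ages are recorded in years.
#'
#' @param series a [trait_series()].
#' @param generation_time years per generation; defaults to the value stored
#'   in the series.
#' @return Numeric vector of ages in generations, oldest first.
#' @export
ages_generations <- function(series, generation_time = NULL) {
  stopifnot(inherits(series, "trait_series"))
  if (series$age_unit == "generations") return(series$bins$age)
  gt <- if (is.null(generation_time)) series$generation_time else generation_time
  if (is.null(gt)) {
    stop("ages are in years but no generation_time is available", call. = FALSE)
  }
  series$bins$age / gt
}

#' Read a trait time series from CSV
#'
#' Expects a comma-separated table with header columns `age`, `mean`, `sd`,
#' `n` (decimal point, no thousands separators). Bin order is normalized to
#' oldest first. A blank `sd` is legal only in bins with `n = 1`.
#'
#' @inheritParams trait_series
#' @param path path to the CSV file.
#' @return A validated [trait_series()].
#' @export
read_trait_series <- function(path, lineage = "lineage",
                              age_unit = c("years", "generations"),
                              generation_time = NULL,
                              trait_scale = c("raw", "natural_log")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  required <- c("age", "mean", "sd", "n")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bins <- raw[required]
  for (col in required) {
    vals <- bins[[col]]
    vals[vals == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !is.na(vals))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell in column '%s', row %s of '%s'",
                   col, paste(bad, collapse = ", "), path), call. = FALSE)
    }
    bins[[col]] <- num
  }
  trait_series(bins, lineage = lineage, age_unit = age_unit,
               generation_time = generation_time, trait_scale = trait_scale)
}
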