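#' Read a specimen table from CSV
#'
#' One record per individual: `specimen_id`, `group`, `sex`
#' (`female` / `male` / `unknown`; blank cells become `unknown`), and a
#' numeric trait `value`. Carrier for group-wise coefficient-of-variation
#' work; see [cv_estimate()] and [delta_cv_ci()].
#'
#' @param path path to the CSV file.
#' @param positive require strictly positive values (as log-scale and CV
#'   analyses do). Default `TRUE`.
#' @return A data frame of class `specimen_table`.
#' @export
read_specimen_table <- function(path, positive = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  specimen_table(raw, positive = positive)
}

#' @rdname read_specimen_table
#' @param records data frame with columns `specimen_id`, `group`, `sex`,
#'   `value`.
#' @export
specimen_table <- function(records, positive = TRUE) {
  records <- as.data.frame(records)
  required <- c("specimen_id", "group", "sex", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("specimen table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[required]
  if (nrow(records) > 0L) {
    if (anyDuplicated(records$specimen_id)) {
      dup <- records$specimen_id[duplicated(records$specimen_id)][1L]
      stop(sprintf("duplicate specimen_id '%s'", dup), call. = FALSE)
    }
    sex <- as.character(records$sex)
    sex[is.na(sex) | sex == ""] <- "unknown"
    bad_sex <- setdiff(unique(sex), c("female", "male", "unknown"))
    if (length(bad_sex) > 0L) {
      stop("invalid sex value(s) in column 'sex': ",
           paste(bad_sex, collapse = ", "), call. = FALSE)
    }
    records$sex <- sex
    num <- suppressWarnings(as.numeric(records$value))
    bad <- which(is.na(num) & !is.na(records$value))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell in column 'value', row %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    records$value <- num
    if (positive && any(!is.na(num) & num <= 0)) {
      stop(sprintf("non-positive value in column 'value', row %s",
                   paste(which(num <= 0), collapse = ", ")), call. = FALSE)
    }
  } else {
    records$value <- numeric(0)
  }
  class(records) <- c("specimen_table", "data.frame")
  records
}

#' Read a multi-species CV summary table from CSV
#'
#' Per-species, per-sex summaries used for comparative coefficient-of-
#' variation work: columns `species`, `sex` (`female` / `male` / `pooled`),
#' `n`, `mean`, `sd`. Emulates the structure of comparative primate
#' endocranial volume compilations (~48 species, two sexes, variable
#' dimorphism and sample sizes).
#'
#' @param path path to the CSV file.
#' @return A data frame of class `species_cv_table`.
#' @seealso [cv_percentile()], [simulate_species_cv_table()]
#' @export
read_species_cv_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  species_cv_table(raw)
}

#' @rdname read_species_cv_table
#' @param rows data frame with columns `species`, `sex`, `n`, `mean`, `sd`.
#' @export
species_cv_table <- function(rows) {
  rows <- as.data.frame(rows)
  required <- c("species", "sex", "n", "mean", "sd")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0L) {
    stop("species CV table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- rows[required]
  if (nrow(rows) > 0L) {
    bad_sex <- setdiff(unique(as.character(rows$sex)),
                       c("female", "male", "pooled"))
    if (length(bad_sex) > 0L) {
      stop("invalid sex value(s) in column 'sex': ",
           paste(bad_sex, collapse = ", "), call. = FALSE)
    }
    for (col in c("n", "mean", "sd")) {
      num <- suppressWarnings(as.numeric(rows[[col]]))
      bad <- which(is.na(num) & !is.na(rows[[col]]))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric cell in column '%s', row %s",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      rows[[col]] <- num
    }
    if (any(rows$mean <= 0, na.rm = TRUE)) {
      stop(sprintf("non-positive mean in column 'mean', row %s",
                   paste(which(rows$mean <= 0), collapse = ", ")), call. = FALSE)
    }
    if (any(rows$sd < 0, na.rm = TRUE)) {
      stop(sprintf("negative sd in column 'sd', row %s",
                   paste(which(rows$sd < 0), collapse = ", ")), call. = FALSE)
    }
  }
  class(rows) <- c("species_cv_table", "data.frame")
  rows
}
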