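#' Write a stage result to CSV with a run-metadata sidecar
#'
#' Every pipeline result writes as a flat comma-separated table (one row for
#' scalar results such as a neutrality test or a CV difference; the natural
#' rows otherwise) plus a JSON sidecar `<path>.meta.json` recording what was
#' written, the parameters and seed involved, the package version and a
#' timestamp. Written trait series read back identical via
#' [read_trait_series()].
#'
#' @param results a package result object (trait series, neutrality test,
#'   rate estimate, LRI fit, CV estimate, delta-CV, or a plain data frame).
#' @param path output CSV path.
#' @param parameters optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, parameters = list()) {
  UseMethod("write_results")
}

.write_with_sidecar <- function(df, path, object_class, parameters, seed = NULL) {
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(written = basename(path), class = object_class,
               parameters = parameters, seed = seed,
               package_version = as.character(utils::packageVersion("phenorate")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
write_results.trait_series <- function(results, path, parameters = list()) {
  parameters <- utils::modifyList(list(lineage = results$lineage,
                                       age_unit = results$age_unit,
                                       generation_time = results$generation_time,
                                       trait_scale = results$trait_scale),
                                  parameters)
  .write_with_sidecar(results$bins, path, "trait_series", parameters)
}

#' @export
write_results.neutrality_test <- function(results, path, parameters = list()) {
  df <- data.frame(null_model = results$null_model,
                   null_variance = results$null_variance,
                   observed_divergence = results$observed_divergence,
                   z = results$z_score, p = results$p_value,
                   tails = results$tails)
  .write_with_sidecar(df, path, "neutrality_test", parameters)
}

#' @export
write_results.delta_cv <- function(results, path, parameters = list()) {
  df <- data.frame(delta = results$delta, ci_low = results$ci_low,
                   ci_high = results$ci_high, level = results$level,
                   method = results$method, n_a = results$n_a, n_b = results$n_b,
                   n_boot = results$n_boot,
                   seed = if (is.null(results$seed)) NA_integer_ else results$seed)
  .write_with_sidecar(df, path, "delta_cv", parameters, seed = results$seed)
}

#' @export
write_results.lri_fit <- function(results, path, parameters = list()) {
  df <- data.frame(slope = results$slope, intercept = results$intercept,
                   ci_low = results$slope_interval[1L],
                   ci_high = results$slope_interval[2L],
                   conf_level = results$conf_level, n_pairs = results$n_pairs,
                   n_zero_dropped = results$n_zero_dropped,
                   mode_call = results$mode_call)
  .write_with_sidecar(df, path, "lri_fit", parameters)
}

#' @export
write_results.rate_estimate <- function(results, path, parameters = list()) {
  .write_with_sidecar(as.data.frame(unclass(results)), path, "rate_estimate",
                      parameters)
}

#' @export
write_results.selection_gradient <- function(results, path, parameters = list()) {
  df <- data.frame(beta_mean_standardized = results$beta_mean_standardized,
                   rate_used = results$rate_used,
                   evolvability_e = results$evolvability_e)
  .write_with_sidecar(df, path, "selection_gradient", parameters)
}

#' @export
write_results.cv_estimate <- function(results, path, parameters = list()) {
  df <- data.frame(cv = results$cv, n = results$n, corrected = results$corrected,
                   sex_pooling = results$sex_pooling)
  .write_with_sidecar(df, path, "cv_estimate", parameters)
}

#' @export
write_results.data.frame <- function(results, path, parameters = list()) {
  .write_with_sidecar(as.data.frame(results), path, class(results)[1L], parameters)
}

#' Run record for a command invocation
#'
#' Each pipeline command emits exactly one run record alongside its outputs:
#' the command name, its full parameter map, the seed (if any), the package
#' version and a timestamp — enough to re-run the command and reproduce its
#' outputs (byte-identical for deterministic stages, identical given the
#' recorded seed otherwise).
#'
#' @param command command name.
#' @param parameters named list of parameters as invoked.
#' @param seed integer seed or `NULL`.
#' @return A list of class `run_record`.
#' @export
run_record <- function(command, parameters = list(), seed = NULL) {
  structure(list(command = command, parameters = parameters, seed = seed,
                 package_version = as.character(utils::packageVersion("phenorate")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_record")
}

#' @rdname run_record
#' @param record a `run_record`.
#' @param path output JSON path.
#' @export
write_run_record <- function(record, path) {
  stopifnot(inherits(record, "run_record"))
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
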