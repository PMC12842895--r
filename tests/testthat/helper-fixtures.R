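# builders for small in-code fixtures

make_series <- function(means, ages = NULL, sd = 10, n = 30,
                        age_unit = "generations", generation_time = NULL) {
  k <- length(means)
  if (is.null(ages)) ages <- rev(seq(0, by = 1000, length.out = k))
  trait_series(data.frame(age = ages, mean = means,
                          sd = rep_len(sd, k), n = rep_len(n, k)),
               age_unit = age_unit, generation_time = generation_time)
}

make_specimens <- function(groups, values, sex = "unknown") {
  specimen_table(data.frame(specimen_id = sprintf("sp%03d", seq_along(values)),
                            group = groups, sex = rep_len(sex, length(values)),
                            value = values))
}

write_series_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
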