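test_that("trait series round-trips through CSV and normalizes to oldest first", {
  path <- write_series_csv(data.frame(age = c(1e4, 2e6, 1e6),
                                      mean = c(1350, 400, 900),
                                      sd = c(120, 50, 100), n = c(40, 5, 12)))
  ts <- read_trait_series(path, age_unit = "years", generation_time = 29)
  expect_s3_class(ts, "trait_series")
  expect_equal(nrow(ts$bins), 3L)
  expect_equal(ts$bins$age, c(2e6, 1e6, 1e4))  # oldest first
  expect_equal(ts$bins$mean, c(400, 900, 1350))

  out <- tempfile(fileext = ".csv")
  write_results(ts, out)
  back <- read_trait_series(out, age_unit = "years", generation_time = 29)
  expect_equal(back$bins, ts$bins)
  meta <- jsonlite::read_json(paste0(out, ".meta.json"))
  expect_equal(meta$class, "trait_series")
  expect_equal(meta$parameters$age_unit, "years")
})

test_that("blank sd is legal only for n = 1 bins", {
  ok <- write_series_csv(data.frame(age = c(200, 100), mean = c(10, 12),
                                    sd = c("", "1.5"), n = c(1, 5)))
  ts <- read_trait_series(ok, age_unit = "generations")
  expect_true(is.na(ts$bins$sd[1]))
  bad <- write_series_csv(data.frame(age = c(200, 100), mean = c(10, 12),
                                     sd = c("", "1.5"), n = c(4, 5)))
  expect_error(read_trait_series(bad, age_unit = "generations"), "n = 1")
})

test_that("trait series validation names the offending row and column", {
  dup <- write_series_csv(data.frame(age = c(100, 100), mean = c(1, 2),
                                     sd = c(0.1, 0.1), n = c(3, 3)))
  expect_error(read_trait_series(dup, age_unit = "generations"),
               "duplicate age value 100")
  nonnum <- write_series_csv(data.frame(age = c(200, 100), mean = c("1", "x"),
                                        sd = c(0.1, 0.1), n = c(3, 3)))
  expect_error(read_trait_series(nonnum, age_unit = "generations"),
               "column 'mean', row 2")
  badn <- write_series_csv(data.frame(age = c(200, 100), mean = c(1, 2),
                                      sd = c(0.1, 0.1), n = c(0, 3)))
  expect_error(read_trait_series(badn, age_unit = "generations"),
               "column 'n', row 1")
  nocol <- write_series_csv(data.frame(age = c(200, 100), mean = c(1, 2),
                                       n = c(3, 3)))
  expect_error(read_trait_series(nocol, age_unit = "generations"),
               "missing column")
})

test_that("years-to-generations conversion is real-valued division", {
  ts <- make_series(c(400, 1350), ages = c(2.146e6, 0), age_unit = "years",
                    generation_time = 29)
  expect_equal(ages_generations(ts), c(2.146e6 / 29, 0))
})

test_that("specimen tables read, validate and permit unknown sex", {
  path <- write_series_csv(data.frame(
    specimen_id = sprintf("d%d", 1:6), group = rep(c("a", "b"), each = 3),
    sex = c("female", "male", "unknown", "male", "", "female"),
    value = c(600, 650, 700, 1300, 1350, 1400)))
  st <- read_specimen_table(path)
  expect_equal(as.vector(table(st$group)), c(3L, 3L))
  expect_equal(sum(st$sex == "unknown"), 2L)

  empty <- write_series_csv(data.frame(specimen_id = character(),
                                       group = character(), sex = character(),
                                       value = numeric()))
  expect_equal(nrow(read_specimen_table(empty)), 0L)

  dup <- write_series_csv(data.frame(specimen_id = c("x", "x"),
                                     group = "a", sex = "unknown",
                                     value = c(1, 2)))
  expect_error(read_specimen_table(dup), "duplicate specimen_id 'x'")

  neg <- write_series_csv(data.frame(specimen_id = c("x", "y"), group = "a",
                                     sex = "unknown", value = c(1, -2)))
  expect_error(read_specimen_table(neg, positive = TRUE),
               "non-positive value.*row 2")
  expect_silent(read_specimen_table(neg, positive = FALSE))
})

test_that("species CV tables validate sex labels and summaries", {
  rows <- data.frame(species = rep("sp1", 2), sex = c("female", "male"),
                     n = c(10, 12), mean = c(80, 95), sd = c(6, 8))
  expect_s3_class(species_cv_table(rows), "species_cv_table")
  rows_bad <- rows; rows_bad$sex[1] <- "f"
  expect_error(species_cv_table(rows_bad), "invalid sex")
  rows_bad <- rows; rows_bad$mean[2] <- -1
  expect_error(species_cv_table(rows_bad), "non-positive mean.*row 2")
})

test_that("scalar results write as one-row tables with sidecars", {
  tst <- neutral_divergence_test(0.5, 0.04, tails = "two")
  p1 <- tempfile(fileext = ".csv")
  write_results(tst, p1)
  row <- utils::read.csv(p1)
  expect_equal(nrow(row), 1L)
  expect_named(row, c("null_model", "null_variance", "observed_divergence",
                      "z", "p", "tails"))
  expect_equal(row$z, 2.5)

  d <- delta_cv_ci(c(88, 100, 112, 95, 105), c(90, 100, 110, 99, 101),
                   method = "asymptotic", corrected = FALSE)
  p2 <- tempfile(fileext = ".csv")
  write_results(d, p2)
  row2 <- utils::read.csv(p2)
  expect_equal(nrow(row2), 1L)
  expect_true(all(c("delta", "ci_low", "ci_high") %in% names(row2)))
  expect_true(row2$ci_low <= row2$delta && row2$delta <= row2$ci_high)
})
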