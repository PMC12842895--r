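test_that("CV matches hand computation, with and without correction", {
  expect_equal(cv_estimate(c(10, 10, 10), corrected = FALSE)$cv, 0)
  est <- cv_estimate(c(8, 10, 12), corrected = FALSE)
  expect_equal(est$cv, 0.2)
  est_c <- cv_estimate(c(8, 10, 12), corrected = TRUE)
  expect_equal(est_c$cv, 0.2 * 13 / 12)
  expect_equal(round(est_c$cv, 4), 0.2167)
  expect_error(cv_estimate(5), "n >= 2")
  expect_error(cv_estimate(c(-5, 1, 1), corrected = FALSE), "positive mean")
})

test_that("correction defaults on for n < 30 and off otherwise, always recorded", {
  small <- cv_estimate(c(8, 10, 12))
  expect_true(small$corrected)
  big <- cv_estimate(rep(c(8, 10, 12), 10))
  expect_false(big$corrected)
})

test_that("CV is scale-invariant but not translation-invariant", {
  set.seed(9)
  for (i in 1:10) {
    x <- rlnorm(12, log(100), 0.2)
    k <- runif(1, 0.1, 50)
    expect_equal(cv_estimate(k * x, corrected = FALSE)$cv,
                 cv_estimate(x, corrected = FALSE)$cv)
    expect_false(isTRUE(all.equal(cv_estimate(x + 50, corrected = FALSE)$cv,
                                  cv_estimate(x, corrected = FALSE)$cv)))
  }
})

test_that("pooled within-sex CV removes the dimorphism contribution", {
  st <- make_specimens(rep("a", 6), c(90, 100, 110, 110, 120, 130),
                       sex = rep(c("male", "female"), each = 3))
  pw <- pooled_within_sex_cv(st, corrected = FALSE)
  expect_equal(pw$cv, 10 / 110)
  expect_equal(round(pw$cv, 4), 0.0909)
  expect_equal(pw$sex_pooling, "within_sex")
  total <- cv_estimate(st$value, corrected = FALSE)
  expect_equal(round(total$cv, 4), 0.1286)
  expect_lt(pw$cv, total$cv)
})

test_that("identical sexes collapse pooled within-sex CV to the single-sex CV", {
  vals <- c(95, 100, 105, 112)
  st <- make_specimens(rep("a", 8), c(vals, vals),
                       sex = rep(c("female", "male"), each = 4))
  pw <- pooled_within_sex_cv(st, corrected = FALSE)
  expect_equal(pw$cv, cv_estimate(vals, corrected = FALSE)$cv)
})

test_that("unknown-sex specimens are excluded with a reported count", {
  st <- make_specimens(rep("a", 7), c(90, 100, 110, 110, 120, 130, 500),
                       sex = c(rep(c("male", "female"), each = 3), "unknown"))
  pw <- pooled_within_sex_cv(st, corrected = FALSE)
  expect_equal(attr(pw, "n_excluded_unknown"), 1L)
  expect_equal(pw$cv, 10 / 110)
  only_unknown <- make_specimens(rep("a", 3), c(1, 2, 3), sex = "unknown")
  expect_error(pooled_within_sex_cv(only_unknown), "known sex")
})

test_that("delta CV is the difference in percentage points and antisymmetric", {
  a <- c(88, 100, 112)  # CV 0.12 exactly
  b <- c(90, 100, 110)  # CV 0.10 exactly
  expect_equal(delta_cv(a, b, corrected = FALSE), 2.0)
  expect_equal(delta_cv(a, a, corrected = FALSE), 0)
  expect_equal(delta_cv(b, a, corrected = FALSE), -delta_cv(a, b, corrected = FALSE))
})

test_that("bootstrap intervals are seeded, reproducible and bracket the estimate", {
  set.seed(21)
  a <- rlnorm(12, log(900), 0.12)
  b <- rlnorm(15, log(1300), 0.08)
  ci1 <- delta_cv_ci(a, b, n_boot = 2000, seed = 77)
  ci2 <- delta_cv_ci(a, b, n_boot = 2000, seed = 77)
  expect_identical(ci1$ci_low, ci2$ci_low)
  expect_identical(ci1$ci_high, ci2$ci_high)
  expect_lte(ci1$ci_low, ci1$delta)
  expect_gte(ci1$ci_high, ci1$delta)
  same <- delta_cv_ci(a, a, n_boot = 1000, seed = 1)
  expect_equal(same$delta, 0)
  expect_lte(same$ci_low, 0)
  expect_gte(same$ci_high, 0)
  expect_error(delta_cv_ci(a, b, n_boot = 500), "n_boot >= 1000")
})

test_that("bootstrap and asymptotic intervals agree on well-behaved large samples", {
  set.seed(31)
  a <- rlnorm(100, log(1000), sqrt(log(1 + 0.1^2)))
  b <- rlnorm(100, log(1100), sqrt(log(1 + 0.12^2)))
  cb <- delta_cv_ci(a, b, "bootstrap", n_boot = 4000, seed = 5)
  ca <- delta_cv_ci(a, b, "asymptotic")
  mid_diff <- abs((cb$ci_low + cb$ci_high) / 2 - (ca$ci_low + ca$ci_high) / 2)
  expect_lt(mid_diff, (ca$ci_high - ca$ci_low) / 4)
})

test_that("asymptotic interval uses the large-sample CV variance", {
  a <- c(88, 100, 112, 95, 105)
  b <- c(90, 100, 110, 99, 101)
  ca <- delta_cv_ci(a, b, "asymptotic", corrected = FALSE)
  cva <- sd(a) / mean(a); cvb <- sd(b) / mean(b)
  half <- qnorm(0.975) * 100 *
    sqrt(cva^2 * (0.5 + cva^2) / 5 + cvb^2 * (0.5 + cvb^2) / 5)
  expect_equal(ca$ci_high - ca$delta, half)
  expect_error(delta_cv_ci(a[1:4], b, "asymptotic"), "n >= 5")
})

test_that("percentile placement follows the midpoint tie convention", {
  rows <- do.call(rbind, lapply(1:5, function(i) {
    cv <- 0.04 + 0.02 * i  # species CVs 0.06 .. 0.14
    data.frame(species = paste0("s", i), sex = c("female", "male"),
               n = c(20, 20), mean = c(100, 100), sd = cv * c(100, 100))
  }))
  tab <- species_cv_table(rows)
  expect_equal(cv_percentile(0.2, tab)$percentile, 100)   # above the maximum
  expect_equal(cv_percentile(0.01, tab)$percentile, 0)    # below the minimum
  expect_equal(cv_percentile(0.10, tab)$percentile, 50)   # at the median
  expect_equal(cv_percentile(0.14, tab)$percentile, 90)   # tied at the maximum
  pl <- cv_percentile(0.10, tab)
  expect_equal(pl$n_species, 5L)
  expect_equal(pl$min, 0.06)
  expect_equal(pl$max, 0.14)
})

test_that("total and within-sex species CVs agree when dimorphism is absent", {
  sim <- simulate_species_cv_table(n_species = 10, n_range = c(200, 200),
                                   dimorphism_range = c(1, 1), seed = 4)
  within <- species_cvs(sim$table, "within_sex")
  total <- species_cvs(sim$table, "none")
  expect_equal(unname(within), unname(total), tolerance = 0.02)
})
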