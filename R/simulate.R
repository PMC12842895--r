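#' Configuration for synthetic trait-lineage simulation
#'
#' Bundles the generating regime and every knob the lineage simulator and
#' fossil-sampling stage use. Trait dynamics are simulated directly on the
#' log-mean scale (population-level diffusion), matching the scale on which
#' the neutral null models are expressed:
#' \describe{
#'   \item{`neutral_drift`}{increments with mean 0 and per-generation
#'     variance `e / Ne` (constant-heritability drift).}
#'   \item{`directional`}{deterministic per-generation increment
#'     `e * beta` (the Lande response to a sustained mean-standardized
#'     gradient) plus the drift increment; set `Ne = Inf` to disable drift.}
#'   \item{`mutation_drift`}{mean-0 increments with per-generation variance
#'     `divergence_factor * sigma^2_m`.}
#'   \item{`stasis`}{independent mean-0 normal perturbations (SD
#'     `stasis_sd`, log scale) about a fixed value.}
#' }
#'
#' @param regime one of `"neutral_drift"`, `"directional"`,
#'   `"mutation_drift"`, `"stasis"`.
#' @param params a [population_params()].
#' @param mut a [mutation_params()] (mutation_drift regime).
#' @param beta sustained mean-standardized selection gradient (directional
#'   regime).
#' @param t_generations simulated generations, >= 0 (the path has
#'   `t_generations + 1` points).
#' @param n_bins number of fossil time bins to sample,
#'   <= `t_generations + 1`.
#' @param n_per_bin individuals measured per bin.
#' @param within_cv within-population CV of individual values (proportion).
#' @param dimorphism_ratio male/female mean ratio, > 0.
#' @param sex_ratio proportion male, in [0, 1).
#' @param measurement_cv multiplicative measurement-error CV (proportion).
#' @param start_mean starting trait mean (trait units; default 900, an
#'   early-Homo-like endocranial volume in cc).
#' @param stasis_sd log-scale SD of the stasis perturbations.
#' @param seed integer seed; every generator is a pure function of its
#'   config including the seed (bit-identical repeats). Trajectory and
#'   sampling noise use derived sub-streams so the stages are independently
#'   reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(regime = c("neutral_drift", "directional",
                                  "mutation_drift", "stasis"),
                       params = population_params(), mut = mutation_params(),
                       beta = 0, t_generations = 1000, n_bins = 10,
                       n_per_bin = 20, within_cv = 0.1,
                       dimorphism_ratio = 1.1, sex_ratio = 0.5,
                       measurement_cv = 0, start_mean = 900,
                       stasis_sd = 0.02, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(inherits(params, "population_params"), inherits(mut, "mutation_params"),
            is.numeric(beta), length(beta) == 1L,
            t_generations >= 0, n_bins >= 1, n_bins <= t_generations + 1,
            n_per_bin >= 1,
            within_cv >= 0, within_cv < 1,
            dimorphism_ratio > 0,
            sex_ratio >= 0, sex_ratio < 1,
            measurement_cv >= 0, measurement_cv < 1,
            start_mean > 0, stasis_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(regime = regime, params = params, mut = mut, beta = beta,
                 t_generations = as.integer(t_generations),
                 n_bins = as.integer(n_bins), n_per_bin = as.integer(n_per_bin),
                 within_cv = within_cv, dimorphism_ratio = dimorphism_ratio,
                 sex_ratio = sex_ratio, measurement_cv = measurement_cv,
                 start_mean = start_mean, stasis_sd = stasis_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: regime %s, t = %d generations, %d bins x %d individuals, seed %d\n",
              x$regime, x$t_generations, x$n_bins, x$n_per_bin, x$seed))
  invisible(x)
}

#' Simulate a per-generation log-mean trajectory
#'
#' Generates the population log-mean path of one lineage under the config's
#' regime (see [sim_config()]). The path has length `t_generations + 1`,
#' starts at `log(start_mean)`, and is a deterministic function of the
#' config including its seed. Under `neutral_drift` the variance of the
#' final log-mean across replicate lineages equals `e * t / Ne`, the drift
#' null variance.
#'
#' @param config a [sim_config()].
#' @return Numeric vector: the log-mean at generations `0..t`.
#' @examples
#' cfg <- sim_config("neutral_drift", t_generations = 100, seed = 7)
#' path <- simulate_mean_trajectory(cfg)
#' length(path)  # 101
#' @export
simulate_mean_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  t <- config$t_generations
  z0 <- log(config$start_mean)
  if (t == 0L) return(z0)
  path <- switch(config$regime,
    neutral_drift = {
      sd_gen <- sqrt(config$params$evolvability_e / config$params$effective_size_Ne)
      z0 + cumsum(c(0, stats::rnorm(t, 0, sd_gen)))
    },
    directional = {
      sd_gen <- sqrt(config$params$evolvability_e / config$params$effective_size_Ne)
      step <- config$params$evolvability_e * config$beta
      z0 + cumsum(c(0, step + stats::rnorm(t, 0, sd_gen)))
    },
    mutation_drift = {
      sd_gen <- sqrt(config$mut$divergence_factor * config$mut$mutational_variance)
      z0 + cumsum(c(0, stats::rnorm(t, 0, sd_gen)))
    },
    stasis = z0 + c(0, stats::rnorm(t, 0, config$stasis_sd))
  )
  path
}

# lognormal draws with a given arithmetic mean and CV
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Sample a binned fossil series from a simulated trajectory
#'
#' Emulates binned fossil sampling of a simulated lineage: bins are placed
#' at evenly spaced generations along the path; each bin draws `n_per_bin`
#' individuals lognormally about the bin's population mean with
#' within-population CV `within_cv`, a two-sex structure set by
#' `dimorphism_ratio` and `sex_ratio` (female mean scaled so the expected
#' overall mean matches the path), and multiplicative lognormal measurement
#' error of CV `measurement_cv`. Bin summaries (sample mean, sample SD, n)
#' are returned as a [trait_series()] with ages in generations before
#' present, oldest first. Sampling noise uses a sub-stream derived from the
#' config seed, so trajectory and sampling are independently reproducible.
#'
#' @param path log-mean path from [simulate_mean_trajectory()].
#' @param config the same [sim_config()].
#' @return A [trait_series()] with `n_bins` bins.
#' @export
sample_fossil_series <- function(path, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_bins > length(path)) {
    stop("n_bins exceeds the trajectory length", call. = FALSE)
  }
  set.seed(config$seed + 1000003L)
  idx <- unique(round(seq(1L, length(path), length.out = config$n_bins)))
  ages <- length(path) - idx  # generations before present
  n <- config$n_per_bin
  p_male <- config$sex_ratio
  r <- config$dimorphism_ratio
  bins <- lapply(seq_along(idx), function(k) {
    mu <- exp(path[idx[k]])
    mu_f <- mu / ((1 - p_male) + r * p_male)
    n_male <- stats::rbinom(1L, n, p_male)
    means <- c(rep(mu_f * r, n_male), rep(mu_f, n - n_male))
    vals <- .rlnorm_mean_cv(n, 1, config$within_cv) * means
    if (config$measurement_cv > 0) {
      vals <- vals * .rlnorm_mean_cv(n, 1, config$measurement_cv)
    }
    data.frame(age = ages[k], mean = mean(vals),
               sd = if (n >= 2) stats::sd(vals) else NA_real_, n = n)
  })
  trait_series(do.call(rbind, bins), lineage = config$regime,
               age_unit = "generations",
               generation_time = config$params$generation_time)
}

#' Simulate a trait lineage end to end
#'
#' Convenience wrapper: [simulate_mean_trajectory()] then
#' [sample_fossil_series()] under one config.
#'
#' @param config a [sim_config()].
#' @return A [trait_series()].
#' @export
simulate_lineage_series <- function(config) {
  sample_fossil_series(simulate_mean_trajectory(config), config)
}

#' Simulate a comparative species CV table
#'
#' Generates a multi-species, two-sex summary table with the structure of
#' comparative primate endocranial-volume compilations: per species a true
#' within-sex CV drawn from a lognormal distribution, a dimorphism ratio
#' drawn uniformly, species means spanning orders of magnitude, and per-sex
#' sample sizes drawn from a stated range; observed per-sex mean/SD/n come
#' from actual lognormal samples so the table carries realistic sampling
#' error. The generating truth is returned alongside for recovery tests.
#'
#' @param n_species number of species, >= 2 (default 48).
#' @param n_range integer range of per-sex sample sizes (default 5 to 30).
#' @param cv_meanlog,cv_sdlog lognormal parameters of the true within-sex
#'   CV distribution (defaults give CVs centred near 0.08).
#' @param dimorphism_range uniform range of male/female mean ratios.
#' @param mean_meanlog,mean_sdlog lognormal parameters of species female
#'   means (defaults span marmoset-to-ape-like volumes).
#' @param seed integer seed.
#' @return A list: `table` (a `species_cv_table`, two rows per species) and
#'   `truth` (one row per species: `species`, `true_cv`, `dimorphism`,
#'   `mean_female`, `mean_male`, `n_female`, `n_male`).
#' @examples
#' sim <- simulate_species_cv_table(n_species = 6, seed = 2)
#' nrow(sim$table); nrow(sim$truth)  # 12, 6
#' @export
simulate_species_cv_table <- function(n_species = 48, n_range = c(5L, 30L),
                                      cv_meanlog = log(0.08), cv_sdlog = 0.35,
                                      dimorphism_range = c(1, 1.35),
                                      mean_meanlog = log(80), mean_sdlog = 1.2,
                                      seed = 1L) {
  stopifnot(n_species >= 2,
            length(n_range) == 2L, n_range[1L] >= 2, n_range[1L] <= n_range[2L],
            length(dimorphism_range) == 2L, dimorphism_range[1L] > 0,
            dimorphism_range[1L] <= dimorphism_range[2L],
            cv_sdlog >= 0, mean_sdlog >= 0)
  set.seed(seed)
  species <- sprintf("species_%02d", seq_len(n_species))
  true_cv <- stats::rlnorm(n_species, cv_meanlog, cv_sdlog)
  dimorphism <- stats::runif(n_species, dimorphism_range[1L], dimorphism_range[2L])
  mean_f <- stats::rlnorm(n_species, mean_meanlog, mean_sdlog)
  mean_m <- mean_f * dimorphism
  n_f <- sample(seq(n_range[1L], n_range[2L]), n_species, replace = TRUE)
  n_m <- sample(seq(n_range[1L], n_range[2L]), n_species, replace = TRUE)
  rows <- lapply(seq_len(n_species), function(i) {
    vf <- .rlnorm_mean_cv(n_f[i], mean_f[i], true_cv[i])
    vm <- .rlnorm_mean_cv(n_m[i], mean_m[i], true_cv[i])
    data.frame(species = species[i], sex = c("female", "male"),
               n = c(n_f[i], n_m[i]), mean = c(mean(vf), mean(vm)),
               sd = c(stats::sd(vf), stats::sd(vm)))
  })
  list(table = species_cv_table(do.call(rbind, rows)),
       truth = data.frame(species = species, true_cv = true_cv,
                          dimorphism = dimorphism, mean_female = mean_f,
                          mean_male = mean_m, n_female = n_f, n_male = n_m))
}
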