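#' Forward-simulation configuration
#'
#' Configures a forward-time run of the pooled obesogenic allele frequency
#' across an obstetrics transition. Generations are indexed 0 ..
#' `n_generations - 1`; the update producing generation `g` uses the
#' pre-transition schedule while `g <= transition_generation` and the
#' post-transition schedule afterwards, so the first generation showing the
#' relaxed regime is `transition_generation + 1`.
#'
#' @param arch A [genetic_architecture()].
#' @param pre_schedule,post_schedule [mortality_schedule()]s active before
#'   and after the obstetrics transition.
#' @param transition_generation Generation index at which obstetrics is
#'   introduced.
#' @param n_generations Number of generations simulated (>= 1).
#' @param initial_freq Pooled obesogenic frequency at generation 0.
#' @param generation_years Calendar years per generation (default 25).
#' @param transition_year Calendar year mapped to `transition_generation`
#'   (default 1940, midpoint of the 1935-1945 obstetrics window).
#' @param mode `"deterministic"` (balance-model recursion) or
#'   `"wright_fisher"` (finite-population stochastic counterpart).
#' @param pop_size Number of individuals per generation (Wright-Fisher mode;
#'   >= 2).
#' @param seed Integer RNG seed (Wright-Fisher mode).
#' @param gain Stabilising gain; `NULL` (default) calibrates it to the
#'   pre-transition schedule so the pre-obstetrics frequency is stationary.
#' @param convention Reproductive-output convention, `"terminal"` or
#'   `"midpoint"` (see [reproductive_output()]).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(arch = genetic_architecture(),
                              pre_schedule,
                              post_schedule,
                              transition_generation,
                              n_generations,
                              initial_freq = 0.10,
                              generation_years = 25,
                              transition_year = 1940,
                              mode = c("deterministic", "wright_fisher"),
                              pop_size = NULL,
                              seed = NULL,
                              gain = NULL,
                              convention = c("terminal", "midpoint")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  stopifnot(inherits(arch, "genetic_architecture"),
            inherits(pre_schedule, "mortality_schedule"),
            inherits(post_schedule, "mortality_schedule"))
  if (missing(transition_generation)) {
    stop("config key `transition_generation` is required", call. = FALSE)
  }
  if (missing(n_generations)) {
    stop("config key `n_generations` is required", call. = FALSE)
  }
  check_scalar(transition_generation, "transition_generation", lower = 0)
  check_scalar(n_generations, "n_generations", lower = 1)
  check_scalar(initial_freq, "initial_freq", lower = 0, upper = 1)
  check_scalar(generation_years, "generation_years", lower = 1)
  if (mode == "wright_fisher") {
    if (is.null(pop_size) || pop_size < 2) {
      stop("`pop_size` must be >= 2 in wright_fisher mode", call. = FALSE)
    }
    if (is.null(seed)) seed <- 1L
  }
  if (is.null(gain)) gain <- calibrate_gain(pre_schedule, convention)
  check_scalar(gain, "gain", lower = 0)
  structure(
    list(arch = arch, pre_schedule = pre_schedule,
         post_schedule = post_schedule,
         transition_generation = as.integer(transition_generation),
         n_generations = as.integer(n_generations),
         initial_freq = initial_freq,
         generation_years = generation_years,
         transition_year = transition_year,
         mode = mode,
         pop_size = if (is.null(pop_size)) NA_integer_ else as.integer(pop_size),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         gain = gain, convention = convention),
    class = "simulation_config"
  )
}

active_schedule <- function(config, g) {
  if (g > config$transition_generation) config$post_schedule
  else config$pre_schedule
}

trajectory_frame <- function(config, freq, bmi, prev) {
  g <- seq_len(config$n_generations) - 1L
  data.frame(
    generation = g,
    calendar_year = config$transition_year +
      (g - config$transition_generation) * config$generation_years,
    allele_freq = freq,
    mean_bmi = bmi,
    cohort_obesity_prevalence = prev
  )
}

#' Deterministic allele-frequency trajectory across the obstetrics transition
#'
#' Iterates the balance-model recursion `p' = p (1 + gain - loss)` with
#' `loss = loss_from_mortality(active schedule)` and `gain` calibrated to
#' the pre-transition schedule (unless overridden), switching schedules at
#' the transition generation. Mean BMI and cohort obesity prevalence are
#' derived from the polygenic architecture at each generation.
#'
#' @param config A [simulation_config()].
#' @return A `trajectory_result`: a data.frame with one row per generation
#'   (`generation`, `calendar_year`, `allele_freq`, `mean_bmi`,
#'   `cohort_obesity_prevalence`) carrying the config as an attribute.
#' @export
deterministic_trajectory <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_generations
  freq <- numeric(n)
  freq[1] <- config$initial_freq
  loss_pre <- loss_from_mortality(config$pre_schedule, config$convention)
  loss_post <- loss_from_mortality(config$post_schedule, config$convention)
  if (n > 1) {
    for (g in seq(1L, n - 1L)) {
      loss <- if (g > config$transition_generation) loss_post else loss_pre
      freq[g + 1L] <- balance_update(freq[g],
                                     balance_model(config$gain, loss))
    }
  }
  res <- trajectory_frame(config, freq,
                          mean_bmi(config$arch, freq),
                          obesity_prevalence(config$arch, freq))
  structure(res, config = config, mode = "deterministic",
            class = c("trajectory_result", "data.frame"))
}

#' Wright-Fisher allele-frequency trajectory
#'
#' Finite-population stochastic counterpart of
#' [deterministic_trajectory()]. Each generation, every individual's
#' additive genetic value is drawn from the exchangeable-loci binomial,
#' environmental noise is added, obesity status is assigned by threshold,
#' and stratum fitnesses from the active [mortality_schedule()] weight the
#' parental contributions; the next generation's per-individual allele
#' counts are binomial draws at the selection-weighted frequency plus the
#' stabilising gain influx (`p_next = w-weighted freq + gain * p`). The run
#' is fully reproducible from `config$seed`.
#'
#' Note: selection here acts only on alleles actually carried by obese
#' individuals (the covariance between fitness and allele count), so the
#' expected per-generation loss is weaker than the pooled-accounting loss of
#' the deterministic recursion whenever obesity prevalence is below 1; the
#' two modes agree in expectation when the selection differential is off
#' (relative risks 1, or post-transition relaxation).
#'
#' @param config A [simulation_config()] with `mode = "wright_fisher"`.
#' @return A `trajectory_result` (realised allele frequency, mean phenotype
#'   and obesity share per generation).
#' @export
wright_fisher_trajectory <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$mode != "wright_fisher") {
    stop("config mode must be 'wright_fisher'", call. = FALSE)
  }
  arch <- config$arch
  n <- config$n_generations
  N <- config$pop_size
  if (is.na(N) || N < 2) stop("`pop_size` must be >= 2", call. = FALSE)
  set.seed(config$seed)
  copies <- dosage_mult(arch) * arch$n_loci
  a <- arch$effect_per_allele
  freq <- bmi <- prev <- numeric(n)
  counts <- stats::rbinom(N, copies, config$initial_freq)
  for (g in seq_len(n) - 1L) {
    phen <- arch$baseline_bmi +
      a * (counts - copies * arch$reference_freq) +
      stats::rnorm(N, 0, arch$env_sd)
    obese <- phen > arch$obesity_threshold
    freq[g + 1L] <- mean(counts) / copies
    bmi[g + 1L] <- mean(phen)
    prev[g + 1L] <- mean(obese)
    if (g == n - 1L) break
    sched <- active_schedule(config, g + 1L)
    w <- ifelse(obese,
                reproductive_output(sched, TRUE, config$convention),
                reproductive_output(sched, FALSE, config$convention))
    if (sum(w) == 0) {
      stop("all parental fitnesses are zero; population extinct",
           call. = FALSE)
    }
    p_sel <- sum(w * counts) / (copies * sum(w))
    p_next <- min(max(p_sel + config$gain * freq[g + 1L], 0), 1)
    counts <- stats::rbinom(N, copies, p_next)
  }
  res <- trajectory_frame(config, freq, bmi, prev)
  structure(res, config = config, mode = "wright_fisher",
            class = c("trajectory_result", "data.frame"))
}

#' Run a trajectory in the mode named by the config
#'
#' @param config A [simulation_config()].
#' @return A `trajectory_result`.
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$mode == "wright_fisher") wright_fisher_trajectory(config)
  else deterministic_trajectory(config)
}

#' Adult obesity prevalence from birth-cohort mixing
#'
#' Adult prevalence in a calendar year is the share-weighted mean of
#' cohort-specific prevalences: cohorts born after the obstetrics transition
#' carry higher obesity rates, and population prevalence rises as those
#' cohorts become a larger share of the adult population.
#'
#' @param shares Either a numeric vector of cohort shares (one calendar
#'   year) or a matrix with one row per calendar year; columns named by
#'   cohort. Each row must be non-negative and sum to 1.
#' @param cohort_rates Named numeric vector of cohort obesity prevalences;
#'   names must match the share names.
#' @return Prevalence per calendar year.
#' @export
#' @examples
#' adult_prevalence(c(post1945 = 0.10, pre1945 = 0.90),
#'                  c(post1945 = 0.20, pre1945 = 0.10)) # 0.11
adult_prevalence <- function(shares, cohort_rates) {
  if (is.vector(shares)) shares <- matrix(shares, nrow = 1,
                                          dimnames = list(NULL, names(shares)))
  if (is.null(colnames(shares)) || is.null(names(cohort_rates)) ||
      !setequal(colnames(shares), names(cohort_rates))) {
    stop("cohort labels of `shares` and `cohort_rates` must match",
         call. = FALSE)
  }
  if (any(shares < 0)) stop("cohort shares must be >= 0", call. = FALSE)
  sums <- rowSums(shares)
  if (any(abs(sums - 1) > 1e-8)) {
    stop("cohort shares must sum to 1 per year", call. = FALSE)
  }
  as.numeric(shares[, names(cohort_rates), drop = FALSE] %*% cohort_rates)
}

#' Cohort-mixed adult prevalence series from a trajectory
#'
#' Builds, for each requested calendar year, the share of the adult
#' population (uniform age distribution between `adult_min_age` and
#' `adult_max_age`) belonging to each simulated birth cohort (a cohort
#' occupies one generation-length birth window), then mixes the per-cohort
#' obesity prevalences with [adult_prevalence()]. Years whose adult window
#' is not fully covered by simulated cohorts renormalise over the covered
#' part.
#'
#' @param traj A `trajectory_result`.
#' @param years Calendar years to evaluate (default: the trajectory's
#'   years).
#' @param adult_min_age,adult_max_age Age window defining "adult"
#'   (defaults 20 and 60).
#' @return data.frame with `calendar_year`, `adult_obesity_prevalence`, and
#'   `post_transition_share` (share of adults born after the transition).
#' @export
adult_prevalence_series <- function(traj, years = NULL,
                                    adult_min_age = 20,
                                    adult_max_age = 60) {
  stopifnot(inherits(traj, "trajectory_result"))
  config <- attr(traj, "config")
  gy <- config$generation_years
  birth_start <- traj$calendar_year
  birth_end <- birth_start + gy
  if (is.null(years)) years <- traj$calendar_year
  out <- vapply(years, function(y) {
    lo <- y - adult_max_age
    hi <- y - adult_min_age
    overlap <- pmax(0, pmin(birth_end, hi) - pmax(birth_start, lo))
    tot <- sum(overlap)
    if (tot == 0) return(c(NA_real_, NA_real_))
    w <- overlap / tot
    # elevated cohorts: generations strictly after the transition (the
    # transition generation itself was born under the old regime)
    post <- traj$generation > config$transition_generation
    c(sum(w * traj$cohort_obesity_prevalence), sum(w[post]))
  }, numeric(2))
  data.frame(calendar_year = years,
             adult_obesity_prevalence = out[1, ],
             post_transition_share = out[2, ])
}
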