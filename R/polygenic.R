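#' Polygenic architecture of BMI
#'
#' Describes the additive large-standing-variation genetic architecture used
#' throughout the package: `n_loci` exchangeable loci, each copy of the
#' obesogenic allele adding `effect_per_allele` kg/m^2 to BMI. The population
#' mean BMI is anchored at `baseline_bmi` when the pooled obesogenic allele
#' frequency equals `reference_freq`.
#'
#' Two dosage conventions are supported. `"haploid"` counts one allele per
#' locus per individual, so a frequency shift `dp` moves mean BMI by
#' `n_loci * effect_per_allele * dp` (the convention under which
#' 1000 loci x 0.1 kg/m^2 x 5% = 5 kg/m^2). `"diploid"` counts two copies
#' per locus and doubles the shift (and the binomial genetic variance).
#'
#' @param n_loci Number of obesogenic loci (integer >= 1; default 1000).
#' @param effect_per_allele BMI increment per obesogenic allele copy, kg/m^2
#'   (>= 0; default 0.1).
#' @param baseline_bmi Mean BMI (kg/m^2) at `reference_freq` (default 25).
#' @param reference_freq Pooled allele frequency anchoring `baseline_bmi`
#'   (in \[0, 1\]; default 0.10).
#' @param dosage `"haploid"` (default) or `"diploid"` allele accounting.
#' @param env_sd Environmental (non-genetic) phenotype standard deviation,
#'   kg/m^2 (>= 0; default 3).
#' @param obesity_threshold BMI cutoff defining obesity (default 30, the
#'   clinical convention).
#' @return An object of class `genetic_architecture`.
#' @seealso [bmi_shift()], [mean_bmi()], [obesity_prevalence()]
#' @export
#' @examples
#' arch <- genetic_architecture()
#' bmi_shift(arch, 0.05) # 5 kg/m^2
genetic_architecture <- function(n_loci = 1000L,
                                 effect_per_allele = 0.1,
                                 baseline_bmi = 25,
                                 reference_freq = 0.10,
                                 dosage = c("haploid", "diploid"),
                                 env_sd = 3,
                                 obesity_threshold = 30) {
  dosage <- match.arg(dosage)
  if (!is.numeric(n_loci) || length(n_loci) != 1L || !is.finite(n_loci) ||
      n_loci < 1 || n_loci != round(n_loci)) {
    stop("`n_loci` must be a single integer >= 1", call. = FALSE)
  }
  check_scalar(effect_per_allele, "effect_per_allele", lower = 0)
  check_scalar(baseline_bmi, "baseline_bmi")
  check_scalar(reference_freq, "reference_freq", lower = 0, upper = 1)
  check_scalar(env_sd, "env_sd", lower = 0)
  check_scalar(obesity_threshold, "obesity_threshold")
  structure(
    list(
      n_loci = as.integer(n_loci),
      effect_per_allele = effect_per_allele,
      baseline_bmi = baseline_bmi,
      reference_freq = reference_freq,
      dosage = dosage,
      env_sd = env_sd,
      obesity_threshold = obesity_threshold
    ),
    class = "genetic_architecture"
  )
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat("Polygenic BMI architecture\n")
  cat(sprintf("  loci: %d, effect/allele: %g kg/m^2 (%s accounting)\n",
              x$n_loci, x$effect_per_allele, x$dosage))
  cat(sprintf("  baseline BMI %g at frequency %g; env sd %g; obesity > %g\n",
              x$baseline_bmi, x$reference_freq, x$env_sd,
              x$obesity_threshold))
  invisible(x)
}

#' Pooled obesogenic allele-frequency state
#'
#' @param freq Pooled obesogenic allele frequency in \[0, 1\].
#' @param generation Non-negative integer generation index.
#' @return An object of class `allele_state`.
#' @export
allele_state <- function(freq, generation = 0L) {
  check_scalar(freq, "freq", lower = 0, upper = 1)
  if (!is.numeric(generation) || length(generation) != 1L ||
      generation < 0 || generation != round(generation)) {
    stop("`generation` must be a single integer >= 0", call. = FALSE)
  }
  structure(list(freq = freq, generation = as.integer(generation)),
            class = "allele_state")
}

dosage_mult <- function(arch) if (arch$dosage == "diploid") 2 else 1

as_freq <- function(state) {
  if (inherits(state, "allele_state")) return(state$freq)
  if (is.numeric(state) && all(is.finite(state)) &&
      all(state >= 0) && all(state <= 1)) {
    return(state)
  }
  stop("`state` must be an allele_state or frequencies in [0, 1]",
       call. = FALSE)
}

#' Mean-BMI shift from an allele-frequency shift
#'
#' Linear additive-model arithmetic: a pooled frequency shift `delta_freq`
#' moves mean BMI by `n_loci * effect_per_allele * delta_freq` under haploid
#' accounting (doubled under diploid).
#'
#' @param arch A [genetic_architecture()].
#' @param delta_freq Frequency shift(s) in \[-1, 1\].
#' @return BMI shift(s) in kg/m^2.
#' @export
#' @examples
#' bmi_shift(genetic_architecture(), 0.05) # 5
bmi_shift <- function(arch, delta_freq) {
  stopifnot(inherits(arch, "genetic_architecture"))
  if (!is.numeric(delta_freq) || !all(is.finite(delta_freq))) {
    stop("`delta_freq` must be finite numeric", call. = FALSE)
  }
  if (any(abs(delta_freq) > 1)) {
    stop("|delta_freq| must be <= 1", call. = FALSE)
  }
  dosage_mult(arch) * arch$n_loci * arch$effect_per_allele * delta_freq
}

#' Population mean BMI at an allele-frequency state
#'
#' @inheritParams bmi_shift
#' @param state An [allele_state()] or numeric frequency vector.
#' @return Mean BMI (kg/m^2).
#' @export
#' @examples
#' arch <- genetic_architecture(baseline_bmi = 25, reference_freq = 0.10)
#' mean_bmi(arch, 0.15) # 30
mean_bmi <- function(arch, state) {
  stopifnot(inherits(arch, "genetic_architecture"))
  p <- as_freq(state)
  arch$baseline_bmi + bmi_shift(arch, p - arch$reference_freq)
}

#' Additive genetic variance of BMI at frequency p
#'
#' Binomial variance across exchangeable loci:
#' `p(1-p) a^2 L` under haploid accounting, `2 p(1-p) a^2 L` under diploid.
#'
#' @inheritParams mean_bmi
#' @return Genetic variance in (kg/m^2)^2.
#' @export
genetic_variance <- function(arch, state) {
  stopifnot(inherits(arch, "genetic_architecture"))
  p <- as_freq(state)
  dosage_mult(arch) * p * (1 - p) * arch$effect_per_allele^2 * arch$n_loci
}

#' Obesity prevalence under the normal approximation
#'
#' Phenotypes are additive genetic value plus independent normal
#' environmental noise; with >= 100 exchangeable loci the genetic value is
#' itself close to normal, so prevalence is approximated as
#' `1 - pnorm((threshold - mean) / total_sd)` with
#' `total_sd^2 = genetic_variance + env_sd^2`.
#'
#' In the degenerate zero-variance case the prevalence is 0 or 1 by
#' comparing mean to threshold (0.5 at exact equality).
#'
#' @inheritParams mean_bmi
#' @return Prevalence(s) in \[0, 1\].
#' @export
obesity_prevalence <- function(arch, state) {
  stopifnot(inherits(arch, "genetic_architecture"))
  p <- as_freq(state)
  mu <- mean_bmi(arch, p)
  total_sd <- sqrt(genetic_variance(arch, p) + arch$env_sd^2)
  out <- numeric(length(mu))
  zero <- total_sd == 0
  out[zero] <- ifelse(mu[zero] > arch$obesity_threshold, 1,
                      ifelse(mu[zero] < arch$obesity_threshold, 0, 0.5))
  if (any(!zero)) {
    out[!zero] <- stats::pnorm(mu[!zero], mean = arch$obesity_threshold,
                               sd = total_sd[!zero])
  }
  out
}

# internal: scalar validation shared across constructors
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
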