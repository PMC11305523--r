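#' Childbirth mortality schedule
#'
#' Parameterises the selective regime childbirth imposed on obesity before
#' (and after) modern obstetrics: a woman's lifetime maternal death rate
#' (LMDR), first-month newborn mortality, the relative risks obesity adds to
#' each, and completed fertility.
#'
#' @param lmdr Lifetime maternal death rate as a proportion in \[0, 1\]
#'   (e.g. 0.15 for a pre-obstetrics population, 0.0001 for a modern one).
#' @param neonatal_rate First-month newborn mortality, proportion in \[0, 1\].
#' @param rr_maternal Relative risk of maternal death for obese women
#'   (>= 0; empirically about 3-4).
#' @param rr_perinatal Relative risk of newborn death for obese mothers
#'   (>= 0).
#' @param fertility Live births per woman (>= 0).
#' @return An object of class `mortality_schedule`.
#' @export
#' @examples
#' pre <- mortality_schedule(lmdr = 0.15, neonatal_rate = 0.14,
#'                           rr_maternal = 4, rr_perinatal = 4,
#'                           fertility = 6)
#' fitness_ratio(pre) # about 0.24: obese women leave ~1/4 the offspring
mortality_schedule <- function(lmdr,
                               neonatal_rate = 0,
                               rr_maternal = 1,
                               rr_perinatal = 1,
                               fertility = 6) {
  check_scalar(lmdr, "lmdr", lower = 0, upper = 1)
  check_scalar(neonatal_rate, "neonatal_rate", lower = 0, upper = 1)
  check_scalar(rr_maternal, "rr_maternal", lower = 0)
  check_scalar(rr_perinatal, "rr_perinatal", lower = 0)
  check_scalar(fertility, "fertility", lower = 0)
  structure(
    list(lmdr = lmdr, neonatal_rate = neonatal_rate,
         rr_maternal = rr_maternal, rr_perinatal = rr_perinatal,
         fertility = fertility),
    class = "mortality_schedule"
  )
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat(sprintf(
    "Mortality schedule: LMDR %g, neonatal %g, RR maternal %g, RR perinatal %g, fertility %g\n",
    x$lmdr, x$neonatal_rate, x$rr_maternal, x$rr_perinatal, x$fertility))
  invisible(x)
}

#' Relative-risk-adjusted mortality rate
#'
#' Multiplies a baseline rate by a relative risk and caps the result at 1
#' (the paper-style arithmetic 4 x 15% = 60% is only capped once
#' `base_rate * rr` exceeds 1).
#'
#' @param base_rate Baseline rate(s), proportions in \[0, 1\].
#' @param rr Relative risk(s), >= 0.
#' @return Adjusted rate(s) in \[0, 1\].
#' @export
#' @examples
#' adjusted_rate(0.15, 4) # 0.60
adjusted_rate <- function(base_rate, rr) {
  if (!is.numeric(base_rate) || !all(is.finite(base_rate)) ||
      any(base_rate < 0) || any(base_rate > 1)) {
    stop("`base_rate` must be proportions in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(rr) || !all(is.finite(rr)) || any(rr < 0)) {
    stop("`rr` must be >= 0", call. = FALSE)
  }
  pmin(base_rate * rr, 1)
}

#' Expected surviving offspring per woman
#'
#' With stratum-adjusted lifetime maternal death rate `L*` and newborn
#' mortality `N*`:
#' * `"terminal"`: `fertility * (1 - L*) * (1 - N*)` — a maternal death
#'   forfeits the whole reproductive output (death early in reproductive
#'   life, or the orphaned-offspring penalty absorbed into the term);
#' * `"midpoint"`: `fertility * (1 - L*/2) * (1 - N*)` — maternal death
#'   occurs on average halfway through reproduction, so half the births
#'   are already realised.
#'
#' @param sched A [mortality_schedule()].
#' @param obese Logical: apply the obesity relative risks?
#' @param convention `"terminal"` (default) or `"midpoint"`.
#' @return Expected surviving offspring per woman.
#' @export
#' @examples
#' s <- mortality_schedule(0.15, 0.14, 4, 4, fertility = 6)
#' reproductive_output(s, obese = TRUE)  # 6 * 0.40 * 0.44 = 1.056
#' reproductive_output(s, obese = FALSE) # 6 * 0.85 * 0.86 = 4.386
reproductive_output <- function(sched, obese,
                                convention = c("terminal", "midpoint")) {
  stopifnot(inherits(sched, "mortality_schedule"), is.logical(obese))
  convention <- match.arg(convention)
  l <- if (obese) adjusted_rate(sched$lmdr, sched$rr_maternal) else sched$lmdr
  n <- if (obese) adjusted_rate(sched$neonatal_rate, sched$rr_perinatal)
       else sched$neonatal_rate
  maternal_survival <- if (convention == "terminal") 1 - l else 1 - l / 2
  sched$fertility * maternal_survival * (1 - n)
}

#' Fitness of obese relative to non-obese women
#'
#' Ratio of expected surviving offspring (obese / non-obese); fertility
#' cancels. Values below 1 quantify the childbirth-mortality selection
#' differential against obesity.
#'
#' @inheritParams reproductive_output
#' @return Dimensionless ratio.
#' @export
fitness_ratio <- function(sched, convention = c("terminal", "midpoint")) {
  convention <- match.arg(convention)
  denom <- reproductive_output(sched, obese = FALSE, convention = convention)
  if (denom == 0) {
    stop("non-obese reproductive output is zero; fitness ratio undefined",
         call. = FALSE)
  }
  reproductive_output(sched, obese = TRUE, convention = convention) / denom
}

#' Per-generation loss rate of obesogenic alleles from childbirth mortality
#'
#' `1 - fitness_ratio(sched)`: the proportional per-generation removal of
#' obesogenic alleles if the whole obesogenic pool carried the obese-stratum
#' fitness deficit (the pooled accounting used by the deterministic
#' recursion).
#'
#' @inheritParams reproductive_output
#' @return Loss rate in \[0, 1\] when relative risks are >= 1.
#' @export
#' @examples
#' s <- mortality_schedule(0.15, 0, rr_maternal = 4, rr_perinatal = 1)
#' loss_from_mortality(s) # 1 - 0.40/0.85 = 0.529...
loss_from_mortality <- function(sched,
                                convention = c("terminal", "midpoint")) {
  1 - fitness_ratio(sched, match.arg(convention))
}

#' Gain/loss balance model of the obesogenic gene pool
#'
#' The pooled obesogenic allele frequency is updated each generation as
#' `p' = clamp(p * (1 + gain - loss), 0, 1)`: `loss` is the
#' childbirth-mortality removal rate, `gain` the stabilising positive
#' pressure replenishing obesogenic alleles. The frequency is stationary
#' when `gain == loss`.
#'
#' @param gain Per-generation proportional influx (>= 0).
#' @param loss Per-generation proportional removal (>= 0).
#' @return An object of class `balance_model`.
#' @export
#' @examples
#' balance_update(0.10, balance_model(gain = 0.5, loss = 0.5)) # 0.10
#' balance_update(0.10, balance_model(gain = 0.5, loss = 0))   # 0.15
balance_model <- function(gain, loss) {
  check_scalar(gain, "gain", lower = 0)
  check_scalar(loss, "loss", lower = 0)
  structure(list(gain = gain, loss = loss), class = "balance_model")
}

#' One-generation balance-model frequency update
#'
#' @param freq Current pooled frequency in \[0, 1\].
#' @param model A [balance_model()].
#' @return Updated frequency, clamped to \[0, 1\].
#' @export
balance_update <- function(freq, model) {
  stopifnot(inherits(model, "balance_model"))
  if (!is.numeric(freq) || !all(is.finite(freq)) ||
      any(freq < 0) || any(freq > 1)) {
    stop("`freq` must be in [0, 1]", call. = FALSE)
  }
  pmin(pmax(freq * (1 + model$gain - model$loss), 0), 1)
}

#' Calibrate the stabilising gain to a mortality schedule
#'
#' Returns the gain that makes the balance model stationary under `sched`
#' (`gain := loss_from_mortality(sched)`), i.e. the pre-obstetrics
#' equilibrium assumption.
#'
#' @inheritParams reproductive_output
#' @return Calibrated gain.
#' @export
calibrate_gain <- function(sched, convention = c("terminal", "midpoint")) {
  loss_from_mortality(sched, match.arg(convention))
}
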