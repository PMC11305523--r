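# Independent oracles used by the unit and acceptance suites. These stay
# deliberately naive and separate from the implementation paths they check.

# partial correlation by the classical recursive formula, peeling one
# control at a time: r_xy.z = (r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2))
oracle_partial_cor <- function(dat, x, y, controls) {
  dat <- dat[stats::complete.cases(dat[c(x, y, controls)]), , drop = FALSE]
  pcor <- function(a, b, zs) {
    if (!length(zs)) return(stats::cor(dat[[a]], dat[[b]]))
    z <- zs[1]
    rest <- zs[-1]
    rab <- pcor(a, b, rest)
    raz <- pcor(a, z, rest)
    rbz <- pcor(b, z, rest)
    (rab - raz * rbz) / sqrt((1 - raz^2) * (1 - rbz^2))
  }
  pcor(x, y, controls)
}

# Pearson chi-squared by an explicit O/E loop
oracle_chi_squared <- function(counts) {
  counts <- as.matrix(counts)
  total <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / total
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  }
  stat
}

# all stepwise-stable subsets under the partial-F criterion: every included
# variable would survive removal (p < p_remove) and no excluded variable
# qualifies for entry (p > p_enter). p-values via the squared-t equivalence.
oracle_stable_subsets <- function(dat, response, candidates,
                                  p_enter = 0.05, p_remove = 0.10) {
  dat <- dat[stats::complete.cases(dat[c(response, candidates)]), ,
             drop = FALSE]
  term_p <- function(in_model, term) {
    fml <- stats::reformulate(c(in_model, term), response)
    cf <- summary(stats::lm(fml, data = dat))$coefficients
    if (!term %in% rownames(cf)) return(NA_real_)
    cf[term, "Pr(>|t|)"]
  }
  k <- length(candidates)
  stable <- list()
  for (mask in 0:(2^k - 1)) {
    subset <- candidates[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    rest <- setdiff(candidates, subset)
    keep_ok <- all(vapply(subset, function(v)
      term_p(setdiff(subset, v), v) < p_remove, logical(1)))
    enter_ok <- all(vapply(rest, function(v) {
      p <- term_p(subset, v)
      is.na(p) || p > p_enter
    }, logical(1)))
    if (keep_ok && enter_ok) stable[[length(stable) + 1]] <- subset
  }
  stable
}

# default-shaped logged data.frame for stats tests: planted linear model
# on two of five candidates, fixed seed
make_planted_regression <- function(n = 40, seed = 42,
                                    beta = c(x1 = 1.5, x2 = -1.2),
                                    noise_sd = 1) {
  set.seed(seed)
  dat <- as.data.frame(matrix(rnorm(n * 5), n,
                              dimnames = list(NULL, paste0("x", 1:5))))
  dat$y <- beta[["x1"]] * dat$x1 + beta[["x2"]] * dat$x2 +
    rnorm(n, 0, noise_sd)
  dat
}

# small deterministic country table for IO round-trips
make_mini_country_df <- function() {
  data.frame(
    nation = c("alpha", "beta", "gamma"),
    lmdr = c(0.001, 0.05, 0.12),
    mmr = c(0.0002, 0.009, 0.02),
    neonatal = c(0.003, 0.04, 0.09),
    obesity_1990 = c(0.12, 0.04, 0.03),
    obesity_2016 = c(0.25, 0.09, 0.06),
    gdp = c(40000, 2500, 900),
    calories = c(3400, 2500, 2100),
    inactivity = c(0.35, 0.22, 0.15),
    antibiotics = c(22, 9, 4),
    development_class = c("developed", "developing", "least_developed"),
    stringsAsFactors = FALSE
  )
}
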