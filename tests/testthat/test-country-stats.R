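logged_planted <- function(...) {
  dat <- make_planted_regression(...)
  dat # already continuous; used directly as "logged" data
}

test_that("log_transform logs, floors non-positives, records provenance", {
  df <- data.frame(a = c(1, exp(1), 10), b = c(0.5, 0, -2))
  out <- log_transform(df, "a")
  expect_equal(out$a, c(0, 1, log(10)))
  expect_warning(out2 <- log_transform(df, c("a", "b")), "floored")
  # floor: half the smallest positive value (0.5 / 2)
  expect_equal(out2$b, log(c(0.5, 0.25, 0.25)))
  expect_equal(attr(out2, "log_transform")$adjusted[["b"]], 2L)
  expect_warning(out3 <- log_transform(df, "b", zero_policy = "na"),
                 "missing")
  expect_equal(out3$b, c(log(0.5), NA, NA))
  expect_error(log_transform(df, "zzz"), "unknown")
  # element-wise agreement with plain log on a clean 10-row fixture
  set.seed(8)
  fix <- data.frame(v = rlnorm(10))
  expect_equal(log_transform(fix, "v")$v, log(fix$v))
})

test_that("correlation matrices: diagonal, monotone data, formula oracle", {
  set.seed(21)
  df <- data.frame(x = rlnorm(10))
  df$y <- 2 * df$x
  cm <- correlation_matrix(df, c("x", "y"), "pearson_on_logs")
  expect_equal(unname(diag(cm$r)), c(1, 1))
  expect_equal(cm$r["x", "y"], 1.0)
  sm <- correlation_matrix(df, c("x", "y"), "spearman_on_raw")
  expect_equal(sm$r["x", "y"], 1.0)

  # 20-row fixture against the explicit covariance formula
  set.seed(22)
  fix <- data.frame(a = rlnorm(20), b = rlnorm(20), c = rlnorm(20))
  cm <- correlation_matrix(fix, c("a", "b", "c"), "pearson_on_logs")
  la <- log(fix$a); lb <- log(fix$b)
  manual <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(cm$r["a", "b"], manual)
  expect_equal(unname(cm$n["a", "b"]), 20)
  expect_true(isSymmetric(cm$r))

  # pairwise-complete n bookkeeping and unavailable cells
  fix$b[1:18] <- NA
  cm2 <- correlation_matrix(fix, c("a", "b", "c"), "pearson_on_logs")
  expect_equal(unname(cm2$n["a", "b"]), 2)
  expect_true(is.na(cm2$r["a", "b"])) # below min_pairs
  expect_false(is.na(cm2$r["a", "c"]))
})

test_that("partial correlation: reduction, oracle equality, rank check", {
  dat <- logged_planted(n = 12, seed = 7)
  # no controls reduces to the simple Pearson correlation
  pc0 <- partial_correlation(dat, "x1", "y")
  expect_equal(pc0$r, cor(dat$x1, dat$y))
  expect_equal(pc0$df, 10)
  # residual method == recursive formula, several control sets
  for (ctl in list("x2", c("x2", "x3"), c("x2", "x3", "x4"))) {
    pc <- partial_correlation(dat, "x1", "y", ctl)
    expect_equal(pc$r, oracle_partial_cor(dat, "x1", "y", ctl),
                 tolerance = 1e-10)
    expect_equal(pc$df, nrow(dat) - length(ctl) - 2)
  }
  # controls independent of x and y leave r approximately unchanged
  set.seed(30)
  big <- data.frame(x = rnorm(500), z = rnorm(500))
  big$y <- 0.5 * big$x + rnorm(500)
  expect_equal(partial_correlation(big, "x", "y", "z")$r,
               cor(big$x, big$y), tolerance = 0.02)
  # duplicated control column is rank deficient
  dat$x2b <- dat$x2
  expect_error(partial_correlation(dat, "x1", "y", c("x2", "x2b")),
               "rank deficient")
  # too few rows
  expect_error(partial_correlation(dat[1:4, ], "x1", "y",
                                   c("x2", "x3", "x4")), "rows")
})

test_that("OLS regression: exact fit, null predictor, normal equations", {
  dat <- logged_planted(n = 20, seed = 3, noise_sd = 0)
  fit <- suppressWarnings(ols_regression(dat, "y", c("x1", "x2")))
  expect_equal(fit$coefficients$beta[fit$coefficients$term == "x1"], 1.5)
  expect_equal(fit$coefficients$beta[fit$coefficients$term == "x2"], -1.2)
  expect_equal(fit$adjusted_r2, 1)
  expect_equal(fit$df2, 20 - 2 - 1)
  # pure-noise response: coefficient near zero, p large
  set.seed(40)
  noise <- data.frame(x = rnorm(2000), y = rnorm(2000))
  nf <- ols_regression(noise, "y", "x")
  expect_lt(abs(nf$coefficients$beta[2]), 0.08)
  # 8-row worked fixture against the normal-equations solution
  dat8 <- logged_planted(n = 8, seed = 9)
  X <- cbind(1, as.matrix(dat8[c("x1", "x2")]))
  beta_hat <- solve(t(X) %*% X, t(X) %*% dat8$y)
  fit8 <- ols_regression(dat8, "y", c("x1", "x2"))
  expect_equal(fit8$coefficients$beta, as.numeric(beta_hat))
  # collinear predictors rejected
  dat8$x1b <- dat8$x1
  expect_error(ols_regression(dat8, "y", c("x1", "x1b")), "collinear")
})

test_that("stepwise selection: thresholds, planted recovery, oracle", {
  # single strong candidate enters; single weak candidate does not
  set.seed(50)
  strong <- data.frame(x = rnorm(40))
  strong$y <- strong$x + rnorm(40, 0, 0.5)
  expect_equal(stepwise_ols(strong, "y", "x")$selected, "x")
  weak <- data.frame(x = rnorm(40), y = rnorm(40))
  p_single <- summary(lm(y ~ x, weak))$coefficients["x", 4]
  sw_weak <- stepwise_ols(weak, "y", "x")
  expect_equal(length(sw_weak$selected) == 1, p_single <= 0.05)
  expect_null(if (length(sw_weak$selected)) NULL else sw_weak$fit)

  # planted pair among five candidates: exact recovery, matches the
  # exhaustive stable-subset oracle
  dat <- make_planted_regression(n = 40, seed = 42)
  sw <- stepwise_ols(dat, "y", paste0("x", 1:5))
  expect_setequal(sw$selected, c("x1", "x2"))
  stable <- oracle_stable_subsets(dat, "y", paste0("x", 1:5))
  expect_true(any(vapply(stable, setequal, logical(1), y = sw$selected)))
  # selection path is deterministic
  sw2 <- stepwise_ols(dat, "y", paste0("x", 1:5))
  expect_identical(sw$path, sw2$path)
  expect_error(stepwise_ols(dat, "y", character(0)), "candidate")
})

test_that("median split: halves, tie rule, reported median", {
  df <- data.frame(v = 1:4)
  ms <- median_split(df, "v")
  expect_equal(ms$median_value, 2.5)
  expect_equal(nrow(ms$below), 2)
  expect_equal(nrow(ms$above), 2)
  # ties at the median go below
  df2 <- data.frame(v = c(1, 2, 2, 3, 5))
  ms2 <- median_split(df2, "v")
  expect_equal(ms2$median_value, 2)
  expect_equal(sort(ms2$below$v), c(1, 2, 2))
  expect_equal(sort(ms2$above$v), c(3, 5))
  # above-group strictly exceeds the median on a continuous fixture
  set.seed(60)
  df3 <- data.frame(v = c(rlnorm(20), NA))
  ms3 <- median_split(df3, "v")
  expect_gt(min(ms3$above$v), ms3$median_value)
  expect_equal(ms3$n, 20)
  expect_error(median_split(data.frame(v = c(NA, 3)), "v"), "non-missing")
})

test_that("exponential fit: exact recovery, flat data, log-level oracle", {
  x <- seq(0, 2, length.out = 15)
  exact <- data.frame(x = x, y = exp(1 - 2 * x))
  fit <- suppressWarnings(fit_exponential(exact, "x", "y"))
  expect_equal(fit$intercept, 1)
  expect_equal(fit$rate, -2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$R, -1)
  expect_equal(fit$predict(0.5), exp(0))
  # flat response: rate ~ 0
  flat <- data.frame(x = x, y = rep(2.5, 15))
  expect_equal(suppressWarnings(fit_exponential(flat, "x", "y"))$rate, 0)
  # noisy fixture equals the log-level lm oracle; non-positive rows dropped
  set.seed(70)
  noisy <- data.frame(x = runif(30))
  noisy$y <- exp(0.5 - 1.5 * noisy$x + rnorm(30, 0, 0.2))
  noisy$y[c(3, 11)] <- c(0, -1)
  expect_equal(fit_exponential(noisy, "x", "y")$n_dropped, 2)
  keep <- noisy$y > 0
  oracle <- lm(log(y) ~ x, noisy[keep, ])
  f <- fit_exponential(noisy, "x", "y")
  expect_equal(f$rate, unname(coef(oracle)[2]))
  expect_equal(f$r_squared, summary(oracle)$r.squared)
})

test_that("variance explained squares the correlation onto percent", {
  expect_equal(variance_explained(-0.336), 11.2896)
  expect_equal(variance_explained(-0.573), 32.8329)
  expect_equal(variance_explained(0), 0)
  expect_error(variance_explained(1.01), "<= 1")
})

test_that("Fisher z comparison: null, separation, df correction", {
  eq <- fisher_z_compare(0.4, 50, 0.4, 80)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_two_sided, 1)
  sep <- fisher_z_compare(0.5, 1000, 0, 1000)
  expect_lt(sep$p_two_sided, 0.01)
  # partial-correlation df correction reduces the effective n
  part <- fisher_z_compare(0.5, 50, 0.2, 50, controls1 = 4, controls2 = 4)
  plain <- fisher_z_compare(0.5, 50, 0.2, 50)
  expect_lt(abs(part$z), abs(plain$z))
  expect_error(fisher_z_compare(1, 10, 0.5, 10), "\\|r\\| < 1")
})

test_that("the above-vs-all correlation contrast lands near p = 0.03 one-sided", {
  # r = -0.573 (above-median partial, n = 64, 4 controls) vs r = -0.336
  # (all nations, n = 133, 4 controls): the printed p = 0.03 is the
  # one-sided Fisher z probability under the partial-correlation df
  cmp <- fisher_z_compare(-0.573, 64, -0.336, 133,
                          controls1 = 4, controls2 = 4)
  expect_gt(cmp$p_one_sided, 0.02)
  expect_lt(cmp$p_one_sided, 0.04)
})

test_that("chi-squared equals the O/E loop and honours the Yates flag", {
  printed <- matrix(c(58, 1, 22, 47), 2,
                    dimnames = list(c("low_mmr", "high_mmr"),
                                    c("high_obesity", "low_obesity")))
  res <- chi_squared_test(printed)
  expect_equal(res$chi_squared, oracle_chi_squared(printed))
  expect_equal(res$chi_squared,
               unname(chisq.test(printed, correct = FALSE)$statistic))
  yates <- chi_squared_test(printed, correct = TRUE)
  expect_equal(yates$chi_squared,
               unname(chisq.test(printed, correct = TRUE)$statistic))
  expect_lt(yates$chi_squared, res$chi_squared)
  # equal cells: no association
  expect_equal(chi_squared_test(matrix(5, 2, 2))$chi_squared, 0)
  expect_error(chi_squared_test(rbind(c(0, 0), c(3, 4))), "all-zero")
})

test_that("row percentages match the printed shares", {
  counts <- matrix(c(58, 1, 22, 47), 2)
  pct <- row_percentages(counts)
  expect_equal(pct[1, 1], 72.5)
  expect_equal(pct[2, 1], 100 * 1 / 48)
  expect_equal(row_percentages(matrix(c(7, 1, 0, 1), 2))[1, ],
               c(100, 0))
  expect_error(row_percentages(rbind(c(0, 0), c(1, 2))), "row totals")
  expect_error(row_percentages(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("contingency classification thresholds and subsetting work", {
  tab <- generate_countries(country_gen_spec(seed = 80))
  developing <- c("developing", "least_developed", "low_income",
                  "low_middle_income")
  res <- classify_and_contingency(tab, subset_classes = developing)
  expect_equal(sum(res$counts), res$n)
  expect_equal(res$chi_squared, oracle_chi_squared(res$counts))
  # counts respect the thresholds on the internal proportion scale
  sub <- tab[tab$development_class %in% developing &
               complete.cases(tab$mmr, tab$obesity_2016), ]
  expect_equal(unname(res$counts["high_mmr", "high_obesity"]),
               sum(sub$mmr * 1e5 > 500 & sub$obesity_2016 * 100 > 19.5))
  # the developing-nation restriction shrinks the sample
  all_nations <- classify_and_contingency(tab)
  expect_lt(res$n, all_nations$n)
  expect_error(classify_and_contingency(tab, subset_classes = "nowhere"),
               "no rows")
})
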