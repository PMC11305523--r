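#' Country-level ecological table
#'
#' Validates a data.frame as the country table consumed by the statistics
#' pipeline. Internally all rates are stored as proportions: `lmdr`,
#' `neonatal`, `obesity_1990`, `obesity_2016`, `inactivity` in \[0, 1\] and
#' `mmr` as a per-birth proportion. The CSV boundary
#' ([read_country_csv()] / [write_country_csv()]) converts to and from the
#' conventional printed units (LMDR/obesity/inactivity in percent, MMR per
#' 100,000 live births, neonatal per 1,000 live births).
#'
#' @param df data.frame with columns `nation`, `lmdr`, `mmr`, `neonatal`,
#'   `obesity_1990`, `obesity_2016`, `gdp`, `calories`, `inactivity`,
#'   `antibiotics`, `development_class`. Missing values are permitted in
#'   numeric columns.
#' @return The validated data.frame with class `country_table`.
#' @export
country_table <- function(df) {
  req <- c("nation", "lmdr", "mmr", "neonatal", "obesity_1990",
           "obesity_2016", "gdp", "calories", "inactivity", "antibiotics",
           "development_class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("country table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$nation)) {
    stop("nation labels must be unique", call. = FALSE)
  }
  num <- setdiff(req, c("nation", "development_class"))
  for (v in num) {
    if (!is.numeric(df[[v]])) df[[v]] <- as.numeric(df[[v]])
    bad <- !is.na(df[[v]]) & df[[v]] < 0
    if (any(bad)) {
      stop(sprintf("column `%s` has %d negative value(s)", v, sum(bad)),
           call. = FALSE)
    }
  }
  classes <- c("developed", "developing", "least_developed", "low_income",
               "low_middle_income", "other")
  unknown <- setdiff(unique(stats::na.omit(df$development_class)), classes)
  if (length(unknown)) {
    warning("unrecognised development_class value(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("country_table", "data.frame")
  df
}

# columns of a country_table that the pipeline treats as analysis variables
country_numeric_vars <- function() {
  c("lmdr", "mmr", "neonatal", "obesity_1990", "obesity_2016", "gdp",
    "calories", "inactivity", "antibiotics")
}

#' Natural-log transform of selected columns
#'
#' Applies `log()` to the named columns. Non-positive cells cannot be
#' logged; under the default `zero_policy = "floor_half_min"` they are
#' floored at half the smallest positive value observed in that column
#' (standard below-detection handling, matching markers such as an LMDR
#' printed as "<0.01%") with a warning; under `"na"` they are set missing.
#' The number of floored/dropped cells per column is recorded in the
#' `log_transform` attribute of the result.
#'
#' @param table A [country_table()] or data.frame.
#' @param variables Character vector of column names to log.
#' @param zero_policy `"floor_half_min"` (default) or `"na"`.
#' @return The table with the named columns logged.
#' @export
log_transform <- function(table, variables,
                          zero_policy = c("floor_half_min", "na")) {
  zero_policy <- match.arg(zero_policy)
  missing_cols <- setdiff(variables, names(table))
  if (length(missing_cols)) {
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  adjusted <- integer(0)
  for (v in variables) {
    x <- table[[v]]
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      if (zero_policy == "floor_half_min") {
        pos <- x[!is.na(x) & x > 0]
        if (!length(pos)) {
          stop(sprintf("column `%s` has no positive values to anchor the log floor", v),
               call. = FALSE)
        }
        x[bad] <- min(pos) / 2
        warning(sprintf("log_transform: %d non-positive value(s) in `%s` floored at half the minimum positive value",
                        sum(bad), v), call. = FALSE)
      } else {
        x[bad] <- NA_real_
        warning(sprintf("log_transform: %d non-positive value(s) in `%s` set missing",
                        sum(bad), v), call. = FALSE)
      }
      adjusted[v] <- sum(bad)
    }
    table[[v]] <- log(x)
  }
  attr(table, "log_transform") <- list(variables = variables,
                                       zero_policy = zero_policy,
                                       adjusted = adjusted)
  table
}

#' Pairwise-complete correlation matrix
#'
#' Computes the correlation matrix the pipeline reports: Pearson
#' moment-product correlations of log-transformed values
#' (`"pearson_on_logs"`) or Spearman rank correlations of the raw values
#' (`"spearman_on_raw"`), each over pairwise-complete observations, with
#' per-pair sample sizes and two-sided p-values.
#'
#' @param table A [country_table()] or data.frame.
#' @param variables Columns to correlate (>= 2).
#' @param method `"pearson_on_logs"` or `"spearman_on_raw"`.
#' @param min_pairs Minimum complete pairs per cell (default 3); cells with
#'   fewer are marked unavailable (`NA`).
#' @return An object of class `correlation_matrix`: list with `r`, `n`,
#'   `p` matrices, `method`, and `stars` (significance markers).
#' @export
correlation_matrix <- function(table, variables,
                               method = c("pearson_on_logs",
                                          "spearman_on_raw"),
                               min_pairs = 3L) {
  method <- match.arg(method)
  if (length(variables) < 2) stop("need >= 2 variables", call. = FALSE)
  if (method == "pearson_on_logs") {
    table <- suppressWarnings(log_transform(table, variables))
    cor_method <- "pearson"
  } else {
    cor_method <- "spearman"
  }
  k <- length(variables)
  r <- n <- p <- matrix(NA_real_, k, k,
                        dimnames = list(variables, variables))
  diag(r) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- table[[variables[i]]]
      y <- table[[variables[j]]]
      ok <- stats::complete.cases(x, y)
      n[i, j] <- sum(ok)
      if (i == j) next
      if (n[i, j] < min_pairs) next
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = cor_method, exact = FALSE)
      )
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  structure(list(r = r, n = n, p = p, stars = stars, method = method),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Correlation matrix (%s), pairwise complete\n", x$method))
  m <- matrix(paste0(format(round(x$r, digits)), x$stars),
              nrow(x$r), dimnames = dimnames(x$r))
  m[is.na(x$r)] <- "NA"
  print(noquote(m))
  cat("n range:", min(x$n), "-", max(x$n), "\n")
  invisible(x)
}

#' Partial correlation via residuals
#'
#' Correlation between `x` and `y` after removing the linear dependence of
#' each on the control variables: `x` and `y` are regressed on the controls
#' plus an intercept over listwise-complete rows and the Pearson
#' correlation of the residuals is returned, with a two-sided p-value from
#' the t distribution on `n - k - 2` degrees of freedom (`k` controls).
#' With no controls this reduces to the simple Pearson correlation.
#'
#' @param table A data.frame (typically already log-transformed).
#' @param x,y Column names of the two focal variables.
#' @param controls Character vector of control column names (may be empty).
#' @return List of class `partial_correlation` with `r`, `p_value`, `n`,
#'   `df`, `controls`.
#' @export
partial_correlation <- function(table, x, y, controls = character(0)) {
  vars <- c(x, y, controls)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- table[stats::complete.cases(table[vars]), vars, drop = FALSE]
  n <- nrow(dat)
  k <- length(controls)
  if (n < k + 3) {
    stop(sprintf("need >= %d listwise-complete rows, have %d", k + 3, n),
         call. = FALSE)
  }
  if (k > 0) {
    Z <- cbind(1, as.matrix(dat[controls]))
    if (qr(Z)$rank < ncol(Z)) {
      stop("control variables are rank deficient (collinear)",
           call. = FALSE)
    }
    rx <- stats::lm.fit(Z, dat[[x]])$residuals
    ry <- stats::lm.fit(Z, dat[[y]])$residuals
  } else {
    rx <- dat[[x]] - mean(dat[[x]])
    ry <- dat[[y]] - mean(dat[[y]])
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, p_value = p, n = n, df = df, controls = controls),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("Partial correlation r = %.3f (p = %.3g, n = %d, df = %d)\n",
              x$r, x$p_value, x$n, x$df))
  if (length(x$controls)) {
    cat("  controlling for:", paste(x$controls, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ordinary least-squares regression fit
#'
#' Listwise-complete multiple linear regression with per-term coefficient,
#' standard error and two-sided p-value, plus adjusted R-squared and the
#' (df1, df2) layout conventional in regression tables
#' (`df1 =` predictors, `df2 = n - predictors - 1`).
#'
#' @param table A data.frame (typically log-transformed).
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return List of class `regression_fit` with `coefficients` (data.frame:
#'   term, beta, std_error, p), `adjusted_r2`, `r2`, `df1`, `df2`, `n`.
#' @export
ols_regression <- function(table, response, predictors) {
  vars <- c(response, predictors)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- table[stats::complete.cases(table[vars]), vars, drop = FALSE]
  n <- nrow(dat)
  if (n <= length(predictors) + 1) {
    stop("too few listwise-complete rows for the model", call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("predictors are collinear; model is rank deficient", call. = FALSE)
  }
  s <- summary(fit)
  cf <- s$coefficients
  structure(
    list(
      coefficients = data.frame(
        term = rownames(cf),
        beta = cf[, "Estimate"],
        std_error = cf[, "Std. Error"],
        p = cf[, "Pr(>|t|)"],
        row.names = NULL
      ),
      adjusted_r2 = s$adj.r.squared,
      r2 = s$r.squared,
      df1 = length(predictors),
      df2 = n - length(predictors) - 1L,
      n = n,
      model = fit
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, adjusted R^2 = %.3f (df1 = %d, df2 = %d)\n",
              x$n, x$adjusted_r2, x$df1, x$df2))
  print(x$coefficients, digits = 3)
  invisible(x)
}

# partial-F p-value of a single candidate given a fitted base model:
# with 1 numerator df the partial F equals the squared t of the candidate's
# coefficient in the augmented model, so the t-test p is used directly.
partial_f_p <- function(dat, response, in_model, candidate) {
  fml <- stats::reformulate(c(in_model, candidate), response)
  cf <- summary(stats::lm(fml, data = dat))$coefficients
  if (!candidate %in% rownames(cf)) return(NA_real_) # collinear: never enters
  cf[candidate, "Pr(>|t|)"]
}

#' Stepwise OLS with partial-F entry and removal
#'
#' Forward selection with backward elimination on partial-F p-values, the
#' procedure classical statistics packages call "stepwise": at each step
#' the not-yet-included candidate with the smallest partial-F p enters if
#' `p <= p_enter`; after every entry, included variables with partial-F
#' `p >= p_remove` are removed (largest p first). Ties are broken by the
#' smaller p, then by candidate input order. Rows are listwise-complete on
#' the response and all candidates so the sample is fixed across steps.
#'
#' @param table A data.frame (typically log-transformed).
#' @param response Response column name.
#' @param candidates Candidate predictor column names (>= 1).
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @return List of class `stepwise_fit` with `selected` (ordered character
#'   vector, possibly empty), `path` (data.frame of step, action, variable,
#'   p), `fit` (a [ols_regression()] result, or `NULL` if nothing was
#'   selected), and `n`.
#' @export
stepwise_ols <- function(table, response, candidates,
                         p_enter = 0.05, p_remove = 0.10) {
  if (!length(candidates)) stop("need >= 1 candidate", call. = FALSE)
  vars <- c(response, candidates)
  dat <- table[stats::complete.cases(table[vars]), vars, drop = FALSE]
  n <- nrow(dat)
  if (n <= length(candidates) + 1) {
    stop("too few listwise-complete rows for stepwise selection",
         call. = FALSE)
  }
  in_model <- character(0)
  path <- data.frame(step = integer(0), action = character(0),
                     variable = character(0), p = numeric(0))
  step <- 0L
  repeat {
    if (step > 2L * length(candidates) + 10L) {
      warning("stepwise selection did not stabilise; stopping",
              call. = FALSE)
      break
    }
    out_model <- setdiff(candidates, in_model)
    if (!length(out_model)) break
    p_in <- vapply(out_model, function(v)
      partial_f_p(dat, response, in_model, v), numeric(1))
    if (all(is.na(p_in)) || min(p_in, na.rm = TRUE) > p_enter) break
    enter <- out_model[which.min(p_in)] # which.min: smallest p, first on tie
    in_model <- c(in_model, enter)
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, action = "enter",
                                   variable = enter,
                                   p = min(p_in, na.rm = TRUE)))
    # backward pass: drop variables whose partial F no longer holds up
    repeat {
      cf <- summary(stats::lm(stats::reformulate(in_model, response),
                              data = dat))$coefficients
      p_cur <- cf[in_model, "Pr(>|t|)"]
      # a zero-estimate/zero-se term (perfect fit) is uninformative: remove
      p_cur[is.na(p_cur)] <- 1
      if (all(p_cur < p_remove)) break
      drop_var <- in_model[which.max(p_cur)]
      in_model <- setdiff(in_model, drop_var)
      step <- step + 1L
      path <- rbind(path, data.frame(step = step, action = "remove",
                                     variable = drop_var,
                                     p = max(p_cur)))
      if (!length(in_model)) break
    }
  }
  fit <- if (length(in_model)) ols_regression(dat, response, in_model)
         else NULL
  structure(list(selected = in_model, path = path, fit = fit, n = n,
                 p_enter = p_enter, p_remove = p_remove),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("Stepwise OLS (enter p <= %g, remove p >= %g), n = %d\n",
              x$p_enter, x$p_remove, x$n))
  if (nrow(x$path)) print(x$path, digits = 3) else cat("  (no steps)\n")
  cat("selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Median split of a table on one variable
#'
#' Splits rows at the median of the non-missing values of `variable`:
#' rows strictly above the median go to `above`, rows at or below (ties
#' included) go to `below`; rows missing the variable are dropped.
#'
#' @param table A data.frame.
#' @param variable Column to split on.
#' @return List with `below`, `above` (tables), `median_value`, and `n`
#'   (non-missing rows used).
#' @export
median_split <- function(table, variable) {
  x <- table[[variable]]
  if (is.null(x)) stop("unknown variable: ", variable, call. = FALSE)
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need >= 2 non-missing values", call. = FALSE)
  med <- stats::median(x[ok])
  list(below = table[ok & x <= med, , drop = FALSE],
       above = table[ok & x > med, , drop = FALSE],
       median_value = med,
       n = sum(ok))
}

#' Exponential (log-linear) curve fit
#'
#' Fits `ln(y) = alpha + beta * x` by least squares — the exponential
#' regression form `y = exp(alpha) * exp(beta * x)` used for
#' obesity-versus-mortality scatter fits. Rows with non-positive `y` are
#' dropped and counted.
#'
#' @param table A data.frame.
#' @param x,y Column names of predictor and (positive) response.
#' @return List of class `exponential_fit` with `intercept` (alpha),
#'   `rate` (beta), `R` (signed correlation of the log-level fit),
#'   `r_squared`, `n`, `n_dropped`, and `predict` (function of x on the
#'   original scale).
#' @export
fit_exponential <- function(table, x, y) {
  missing_cols <- setdiff(c(x, y), names(table))
  if (length(missing_cols)) {
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  xv <- table[[x]]; yv <- table[[y]]
  ok <- stats::complete.cases(xv, yv)
  droppable <- ok & yv <= 0
  use <- ok & yv > 0
  if (sum(use) < 3) stop("need >= 3 rows with positive response",
                         call. = FALSE)
  fit <- stats::lm(log(yv[use]) ~ xv[use])
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(
    list(intercept = alpha, rate = beta,
         R = sign(beta) * sqrt(r2), r_squared = r2,
         n = sum(use), n_dropped = sum(droppable),
         predict = function(newx) exp(alpha + beta * newx)),
    class = "exponential_fit"
  )
}

#' Percent of variance explained by a correlation
#'
#' `100 * r^2`: the share of between-nation variance in one variable
#' statistically accounted for by another, as conventionally quoted from a
#' (partial) correlation coefficient.
#'
#' @param r Correlation(s) with `|r| <= 1`.
#' @return Percent(s) in \[0, 100\].
#' @export
#' @examples
#' variance_explained(-0.336) # 11.29 ("approximately 11%")
variance_explained <- function(r) {
  if (!is.numeric(r) || !all(is.finite(r)) || any(abs(r) > 1)) {
    stop("`r` must be numeric with |r| <= 1", call. = FALSE)
  }
  100 * r^2
}

#' Fisher z comparison of two independent correlations
#'
#' Tests the difference between two independent (partial) correlations via
#' the Fisher z transform: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3-k1)
#' + 1/(n2-3-k2))`, where `k` is the number of control variables of each
#' partial correlation (0 for simple correlations). Both the two-sided and
#' the one-sided p-value are reported, with the sidedness explicit in the
#' output.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes.
#' @param controls1,controls2 Number of control variables behind each
#'   correlation (default 0).
#' @return List of class `fisher_z` with `z`, `p_two_sided`, `p_one_sided`,
#'   `df1`, `df2`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2,
                             controls1 = 0L, controls2 = 0L) {
  for (r in c(r1, r2)) {
    if (!is.finite(r) || abs(r) >= 1) {
      stop("correlations must satisfy |r| < 1", call. = FALSE)
    }
  }
  d1 <- n1 - 3 - controls1
  d2 <- n2 - 3 - controls2
  if (d1 <= 0 || d2 <= 0) {
    stop("sample sizes too small for the Fisher z comparison",
         call. = FALSE)
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / d1 + 1 / d2)
  structure(list(z = z,
                 p_two_sided = 2 * stats::pnorm(-abs(z)),
                 p_one_sided = stats::pnorm(-abs(z)),
                 df1 = d1, df2 = d2),
            class = "fisher_z")
}

#' @export
print.fisher_z <- function(x, ...) {
  cat(sprintf("Fisher z = %.3f; two-sided p = %.4f; one-sided p = %.4f\n",
              x$z, x$p_two_sided, x$p_one_sided))
  invisible(x)
}

#' Row percentages of a contingency table
#'
#' @param counts Non-negative count matrix with positive row totals.
#' @return Matrix of `100 * cell / row total`.
#' @export
#' @examples
#' row_percentages(matrix(c(58, 1, 22, 47), 2)) # 72.5% of low-MMR nations...
row_percentages <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("row totals must be > 0", call. = FALSE)
  100 * counts / tot
}

#' Pearson chi-squared statistic for a contingency table
#'
#' Standard Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the margins; the Yates continuity correction (2x2 only) is off by
#' default and available by flag.
#'
#' @param counts Count matrix.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List with `chi_squared`, `df`, `p_value`, `expected`.
#' @export
chi_squared_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has an all-zero row or column", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  dev <- abs(counts - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chi_squared = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' High-MMR by high-obesity contingency analysis
#'
#' Classifies nations as high/low maternal mortality (MMR above
#' `mmr_threshold` deaths per 100,000 live births; WHO's very-high cutoff
#' 500 by default) and high/low obesity (2016 adult obesity above
#' `obesity_threshold` percent; 19.5 by default, the OECD-average
#' convention), optionally restricted to a set of development classes, and
#' tests the association with the Pearson chi-squared statistic.
#'
#' @param table A [country_table()] (rates stored as proportions; the
#'   thresholds are given in the conventional printed units and converted
#'   internally).
#' @param mmr_threshold High-MMR cutoff, deaths per 100,000 live births.
#' @param obesity_threshold High-obesity cutoff, percent of adults.
#' @param subset_classes Optional character vector of `development_class`
#'   values to keep (e.g. the developing-nation classes).
#' @param correct Yates continuity correction flag (default FALSE).
#' @return List of class `contingency_result` with `counts` (rows low/high
#'   MMR, columns high/low obesity), `row_pct`, `chi_squared`, `p_value`,
#'   `n`, and the thresholds used.
#' @export
classify_and_contingency <- function(table,
                                     mmr_threshold = 500,
                                     obesity_threshold = 19.5,
                                     subset_classes = NULL,
                                     correct = FALSE) {
  stopifnot(inherits(table, "data.frame"))
  if (!is.null(subset_classes)) {
    table <- table[table$development_class %in% subset_classes, ,
                   drop = FALSE]
  }
  ok <- stats::complete.cases(table$mmr, table$obesity_2016)
  table <- table[ok, , drop = FALSE]
  if (!nrow(table)) {
    stop("no rows with both MMR and 2016 obesity after subsetting",
         call. = FALSE)
  }
  high_mmr <- table$mmr * 1e5 > mmr_threshold
  high_obesity <- table$obesity_2016 * 100 > obesity_threshold
  counts <- rbind(
    low_mmr = c(high_obesity = sum(!high_mmr & high_obesity),
                low_obesity = sum(!high_mmr & !high_obesity)),
    high_mmr = c(high_obesity = sum(high_mmr & high_obesity),
                 low_obesity = sum(high_mmr & !high_obesity))
  )
  test <- chi_squared_test(counts, correct = correct)
  structure(
    list(counts = counts, row_pct = row_percentages(counts),
         chi_squared = test$chi_squared, p_value = test$p_value,
         df = test$df, n = sum(counts),
         mmr_threshold = mmr_threshold,
         obesity_threshold = obesity_threshold,
         correction = correct),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("MMR > %g per 100,000 x obesity > %g%% (n = %d)\n",
              x$mmr_threshold, x$obesity_threshold, x$n))
  print(x$counts)
  cat(sprintf("chi-squared = %.3f (df = %d), p = %.3g%s\n",
              x$chi_squared, x$df, x$p_value,
              if (x$correction) " [Yates-corrected]" else ""))
  invisible(x)
}
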