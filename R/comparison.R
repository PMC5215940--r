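#' Log-transform minute-valued variables
#'
#' Natural log of `x + offset`. Minute-per-day variables are heavily
#' right-skewed with a point mass at zero, so correlations and regressions
#' operate on this scale; the default offset of 1 maps zero to zero and
#' preserves rank order.
#'
#' @param x non-negative numeric vector (min/day).
#' @param offset positive shift added before the log (default 1).
#' @return `log(x + offset)`.
#' @export
log_minutes <- function(x, offset = 1) {
  if (any(x < 0, na.rm = TRUE)) stop("minute values must be non-negative")
  stopifnot(offset > 0 || all(x > 0, na.rm = TRUE))
  log(x + offset)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Correlates every `rows` variable with every `cols` variable using all
#' subjects complete for that pair, reporting per cell the coefficient, the
#' pair n, and the two-sided p-value from the t approximation
#' `t = r sqrt(n-2) / sqrt(1-r^2)`. Variables named in `log_vars` are
#' transformed by [log_minutes()] first. Cells with fewer than 3 complete
#' pairs are missing.
#'
#' @param table data frame with one row per subject.
#' @param rows,cols character vectors of variable names.
#' @param log_vars variables to log-transform before correlating (default:
#'   all of `rows` and `cols`).
#' @param offset log offset passed to [log_minutes()].
#' @return List of class `"correlation_matrix"` with matrices `r`, `n`, `p`.
#' @export
correlation_matrix <- function(table, rows, cols,
                               log_vars = union(rows, cols), offset = 1) {
  stopifnot(all(c(rows, cols) %in% names(table)))
  dat <- table[, union(rows, cols), drop = FALSE]
  for (v in intersect(log_vars, names(dat))) dat[[v]] <- log_minutes(dat[[v]], offset)
  r <- n <- p <- matrix(NA_real_, length(rows), length(cols),
                        dimnames = list(rows, cols))
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    x <- dat[[rows[i]]]; y <- dat[[cols[j]]]
    ok <- stats::complete.cases(x, y)
    n[i, j] <- sum(ok)
    if (n[i, j] >= 3) {
      rij <- stats::cor(x[ok], y[ok])
      r[i, j] <- rij
      if (is.finite(rij) && abs(rij) < 1) {
        tt <- rij * sqrt(n[i, j] - 2) / sqrt(1 - rij^2)
        p[i, j] <- 2 * stats::pt(-abs(tt), df = n[i, j] - 2)
      } else if (is.finite(rij)) p[i, j] <- 0
    }
  }
  structure(list(r = r, n = n, p = p), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Pairwise-complete Pearson correlations (n ",
      min(x$n, na.rm = TRUE), "-", max(x$n, na.rm = TRUE), ")\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Paired-sample t-test on raw minutes
#'
#' Classical paired t-test of `a - b` over subjects complete for both
#' variables, on the raw (untransformed) minute scale so the mean
#' difference reads directly in min/day.
#'
#' @param table data frame with one row per subject.
#' @param a,b variable names; the difference is `a - b`.
#' @return One-row data frame: `mean_diff`, `sd_diff`, `t_stat`, `df`, `p`,
#'   `n`. With zero-variance differences `t_stat` and `p` are `NA`.
#' @export
paired_comparison <- function(table, a, b) {
  d <- table[[a]] - table[[b]]
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0) {
    return(data.frame(mean_diff = mean(d), sd_diff = 0, t_stat = NA_real_,
                      df = n - 1L, p = NA_real_, n = n))
  }
  tt <- stats::t.test(d)
  data.frame(mean_diff = mean(d), sd_diff = stats::sd(d),
             t_stat = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
             p = tt$p.value, n = n)
}

#' Paired bias split by objective activity level
#'
#' Splits the cohort at a threshold on the objective (accelerometer) MVPA —
#' by default the 60 min/day guideline — and runs [paired_comparison()]
#' within each stratum, quantifying how reporting bias depends on true
#' activity. An empty (or single-subject) stratum yields an `NA` row.
#'
#' @param table data frame with one row per subject.
#' @param a,b variable names for the difference `a - b`.
#' @param objective name of the objective MVPA variable used for splitting.
#' @param threshold split point in min/day (default 60).
#' @return Data frame with rows `active` (`objective >= threshold`) and
#'   `inactive`, columns as in [paired_comparison()] plus `stratum`.
#' @export
stratified_bias <- function(table, a, b, objective, threshold = 60) {
  stopifnot(objective %in% names(table))
  run <- function(sub, label) {
    res <- if (sum(stats::complete.cases(sub[[a]], sub[[b]])) >= 2)
      paired_comparison(sub, a, b)
    else data.frame(mean_diff = NA_real_, sd_diff = NA_real_,
                    t_stat = NA_real_, df = NA_integer_, p = NA_real_,
                    n = sum(stats::complete.cases(sub[[a]], sub[[b]])))
    cbind(stratum = label, res)
  }
  act <- !is.na(table[[objective]]) & table[[objective]] >= threshold
  ina <- !is.na(table[[objective]]) & table[[objective]] < threshold
  rbind(run(table[act, , drop = FALSE], "active"),
        run(table[ina, , drop = FALSE], "inactive"))
}

#' Bland-Altman agreement analysis
#'
#' For each subject computes the difference `a - b` and the pair mean
#' `(a + b) / 2`; reports the bias (mean difference), the SD of differences,
#' the 95% limits of agreement `bias -/+ 1.96 SD`, and the proportional-bias
#' correlation of the difference with the pair mean (with its two-sided p).
#' The per-subject coordinates are returned for plotting.
#'
#' @param table data frame with one row per subject.
#' @param a,b variable names; the difference is `a - b`, so call with the
#'   reference method second to read the bias as an over-/underestimate of
#'   it.
#' @return List of class `"bland_altman"`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `prop_bias_r`, `prop_bias_p`, `n`, and `data` (a data
#'   frame of `mean` and `diff`).
#' @export
bland_altman <- function(table, a, b) {
  ok <- stats::complete.cases(table[[a]], table[[b]])
  x <- table[[a]][ok]; y <- table[[b]][ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  d <- x - y; m <- (x + y) / 2
  s <- stats::sd(d)
  if (s > 0 && stats::sd(m) > 0) {
    ct <- stats::cor.test(d, m)
    pr <- unname(ct$estimate); pp <- ct$p.value
  } else {
    pr <- NA_real_; pp <- NA_real_
  }
  structure(list(bias = mean(d), sd_diff = s,
                 loa_low = mean(d) - 1.96 * s, loa_high = mean(d) + 1.96 * s,
                 prop_bias_r = pr, prop_bias_p = pp, n = n,
                 data = data.frame(mean = m, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f, LoA [%.2f, %.2f], proportional bias r = %.2f (p = %.3g)\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$prop_bias_r, x$prop_bias_p))
  invisible(x)
}

#' Multiple regression predicting objective MVPA
#'
#' Ordinary least squares of a (log-transformed) outcome on log-transformed
#' questionnaire predictors, complete cases only. A rank-deficient design is
#' rejected with the collinear columns named.
#'
#' @param table data frame with one row per subject.
#' @param y outcome variable name.
#' @param predictors character vector of predictor names.
#' @param log_vars variables to transform by [log_minutes()] before fitting
#'   (default: `y` and all predictors).
#' @param offset log offset.
#' @return List of class `"mvpa_regression"`: `coefficients` (data frame
#'   with `b`, `se`, `t`, `p` per term), `r_squared`, `n`, `fit` (the `lm`
#'   object).
#' @export
fit_mvpa_regression <- function(table, y, predictors,
                                log_vars = c(y, predictors), offset = 1) {
  stopifnot(all(c(y, predictors) %in% names(table)))
  dat <- table[, c(y, predictors), drop = FALSE]
  for (v in intersect(log_vars, names(dat))) dat[[v]] <- log_minutes(dat[[v]], offset)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fit <- stats::lm(stats::reformulate(predictors, response = y), data = dat)
  if (fit$rank < length(predictors) + 1) {
    alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(alias, collapse = ", "))
  }
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("b", "se", "t", "p")
  structure(list(coefficients = co, r_squared = sm$r.squared,
                 n = nrow(dat), fit = fit),
            class = "mvpa_regression")
}

#' @export
print.mvpa_regression <- function(x, ...) {
  cat(sprintf("OLS, N = %d, R^2 = %.3f\n", x$n, x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Descriptive statistics table (mean, SD, quartiles)
#'
#' @param table data frame with one row per subject.
#' @param vars variables to describe.
#' @return Data frame with one row per variable: `variable`, `n`, `mean`,
#'   `sd`, `q25`, `q50`, `q75`.
#' @export
describe_cohort <- function(table, vars = names(table)) {
  vars <- vars[vapply(table[vars], is.numeric, logical(1))]
  do.call(rbind, lapply(vars, function(v) {
    x <- table[[v]][!is.na(table[[v]])]
    q <- stats::quantile(x, c(.25, .5, .75), names = FALSE)
    data.frame(variable = v, n = length(x), mean = mean(x), sd = stats::sd(x),
               q25 = q[1], q50 = q[2], q75 = q[3])
  }))
}
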