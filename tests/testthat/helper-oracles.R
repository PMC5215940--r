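# Independent oracles: deliberately naive, loop-based implementations used
# to cross-check the package's vectorised / stats-backed code paths.

# minute-resolution epoch series from a counts vector
make_series <- function(counts, steps = NULL, epoch = 60,
                        start = as.POSIXct("2026-01-05 08:00:00", tz = "UTC"),
                        id = "T01") {
  epoch_series(id, start + (seq_along(counts) - 1) * epoch, counts,
               steps, epoch_length = epoch)
}

# exhaustive run-length scan for zero runs >= thresh minutes
oracle_nonwear <- function(counts, thresh = 20) {
  runs <- list()
  i <- 1
  n <- length(counts)
  while (i <= n) {
    if (counts[i] == 0) {
      j <- i
      while (j < n && counts[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= thresh) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# explicit-sum Pearson correlation
oracle_cor <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / n
  den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
  num / den
}

# explicit-sum paired t
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(mean = m, t = m / (s / sqrt(n)), df = n - 1,
       p = 2 * pt(-abs(m / (s / sqrt(n))), n - 1))
}

# OLS by normal equations, with R^2 from explicit sums
oracle_ols <- function(y, X) {
  X1 <- cbind(1, X)
  b <- solve(t(X1) %*% X1, t(X1) %*% y)
  fitted <- X1 %*% b
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  n <- length(y); k <- ncol(X1)
  sigma2 <- ss_res / (n - k)
  se <- sqrt(diag(sigma2 * solve(t(X1) %*% X1)))
  list(b = as.vector(b), se = se, r2 = 1 - ss_res / ss_tot)
}
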