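# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (closed forms, exhaustive enumeration, two-pass
# sums) so they share no code with the implementation they check.

# Closed-form simple linear regression: slope/intercept and their standard
# errors from the textbook formulas.
ols_line_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(s2 / sxx),
       se_intercept = sqrt(s2 * (1 / n + mean(x)^2 / sxx)))
}

# Normal-equations OLS with standard errors.
ols_oracle <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  xtx_inv <- solve(t(Xi) %*% Xi)
  beta <- drop(xtx_inv %*% t(Xi) %*% y)
  res <- y - drop(Xi %*% beta)
  s2 <- sum(res^2) / (nrow(Xi) - ncol(Xi))
  list(intercept = beta[1], coefficients = beta[-1],
       se = sqrt(diag(xtx_inv) * s2))
}

# Two-pass Pearson correlation.
pearson_oracle <- function(a, b) {
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Exhaustive best subset of a given size by a supplied fitness function.
exhaustive_best <- function(d, size, fitness) {
  subsets <- utils::combn(d, size, simplify = FALSE)
  fits <- vapply(subsets, fitness, numeric(1))
  list(fitness = max(fits), subset = subsets[[which.max(fits)]])
}

# Greedy keep-first correlation pruning by explicit pair enumeration.
filter_correlated_oracle <- function(x, r_threshold) {
  keep <- integer(0)
  for (j in seq_len(ncol(x))) {
    ok <- TRUE
    for (k in keep)
      if (abs(pearson_oracle(x[, j], x[, k])) >= r_threshold) ok <- FALSE
    if (ok) keep <- c(keep, j)
  }
  keep
}
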