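# Independent restricted log-likelihood, written from the textbook formula
# with base solve()/determinant() only; used to cross-check the AI-REML
# engine by brute-force grid search.
oracle_reml_logl <- function(theta, y, X, Vlist) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (k in seq_along(Vlist)) V <- V + theta[k] * Vlist[[k]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  ld_v <- determinant(V, logarithm = TRUE)$modulus
  ld_x <- determinant(XtViX, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (ld_v + ld_x + t(y) %*% P %*% y))
}

# Dense grid search of the univariate restricted likelihood over
# (sigma2_a, sigma2_e); returns the argmax grid point and the step sizes.
grid_search_univariate <- function(y, X, G, n_grid = 50) {
  v <- stats::var(y)
  sa <- seq(v / n_grid, 2 * v, length.out = n_grid)
  se <- seq(v / n_grid, 2 * v, length.out = n_grid)
  Vlist <- list(G, diag(length(y)))
  best <- c(NA, NA, -Inf)
  for (i in seq_along(sa)) {
    for (j in seq_along(se)) {
      ll <- oracle_reml_logl(c(sa[i], se[j]), y, X, Vlist)
      if (ll > best[3]) best <- c(sa[i], se[j], ll)
    }
  }
  list(sigma2_a = best[1], sigma2_e = best[2], logl = best[3],
       step_a = sa[2] - sa[1], step_e = se[2] - se[1])
}

# One-way ANOVA variance components on balanced repeated records:
# between-individual variance (sigma2_b) and within (sigma2_w).
anova_repeat_oracle <- function(values, ids) {
  m <- unname(table(ids)[1])
  means <- tapply(values, ids, mean)
  grand <- mean(values)
  q <- length(means)
  msb <- m * sum((means - grand)^2) / (q - 1)
  msw <- sum((values - means[as.character(ids)])^2) / (q * (m - 1))
  list(sigma2_b = (msb - msw) / m, sigma2_w = msw)
}
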