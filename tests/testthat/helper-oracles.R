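# Small data generators and deliberately naive oracle implementations used to
# cross-check the package's linear-algebra paths. Oracles favour explicit
# loops and textbook formulas over speed and share no code with R/.

toy6 <- function() {
  iv_data(y = c(1, 2, 3, 4, 5, 6),
          X = c(1, 1, 2, 2, 3, 3),
          Z = c(0, 1, 0, 1, 1, 2))
}

# confounded genotype DGP at arbitrary (small) size
make_toy <- function(n, J, seed, pi_z = 0.3, maf = 0.3, beta = 0,
                     het = FALSE) {
  set.seed(seed)
  Z <- matrix(rbinom(n * J, 2, maf), n, J)
  w <- rnorm(n)
  x <- pi_z * rowSums(Z) + w + rnorm(n)
  scale_u <- if (het) sqrt(0.2 + rowSums(Z) / (2 * J)) else 1
  y <- beta * x + w + scale_u * rnorm(n)
  iv_data(y, x, Z)
}

center_cols <- function(M) sweep(as.matrix(M), 2, colMeans(as.matrix(M)))

# explicit two-regression 2SLS: lm of x on z, then y on fitted x
oracle_2sls_two_stage <- function(data) {
  first <- lm(data$X ~ data$Z)
  xhat <- fitted(first)
  unname(coef(lm(data$y ~ xhat))[2L])
}

# g(beta) and Omega(beta) assembled element by element
oracle_moments <- function(beta, data) {
  y <- data$y - mean(data$y)
  X <- center_cols(data$X)
  Z <- center_cols(data$Z)
  n <- data$n; J <- data$J
  g <- numeric(J)
  Om <- matrix(0, J, J)
  for (i in seq_len(n)) {
    ui <- y[i] - sum(X[i, ] * beta)
    for (a in seq_len(J)) {
      g[a] <- g[a] + Z[i, a] * ui / n
      for (b in seq_len(J))
        Om[a, b] <- Om[a, b] + Z[i, a] * Z[i, b] * ui^2 / n
    }
  }
  list(g = g, Om = Om)
}

oracle_cue_objective <- function(beta, data) {
  m <- oracle_moments(beta, data)
  data$n * drop(t(m$g) %*% solve(m$Om) %*% m$g)
}

# grid + local refinement minimization of the CUE objective
oracle_cue_grid <- function(data, lo = -5, hi = 5, step = 1e-4) {
  y <- data$y - mean(data$y)
  x <- drop(center_cols(data$X))
  Z <- center_cols(data$Z)
  n <- data$n
  gy <- drop(crossprod(Z, y)) / n
  gx <- drop(crossprod(Z, x)) / n
  Oyy <- crossprod(Z * y); Oxx <- crossprod(Z * x)
  Oxy <- crossprod(Z * y, Z * x); Oxy <- (Oxy + t(Oxy)) / 2
  qf <- function(b) {
    g <- gy - b * gx
    Om <- (Oyy - 2 * b * Oxy + b^2 * Oxx) / n
    n * drop(t(g) %*% solve(Om) %*% g)
  }
  grid <- seq(lo, hi, by = step)
  vals <- vapply(grid, qf, numeric(1))
  grid[which.min(vals)]
}

# LIML as direct scalar minimization of the variance ratio u'Pu/u'u
oracle_liml_ratio <- function(data, lo = -10, hi = 10) {
  y <- data$y - mean(data$y)
  x <- drop(center_cols(data$X))
  Z <- center_cols(data$Z)
  P <- Z %*% solve(crossprod(Z)) %*% t(Z)
  ratio <- function(b) {
    u <- y - b * x
    drop(t(u) %*% P %*% u) / sum(u^2)
  }
  optimize(ratio, c(lo, hi), tol = 1e-12)$minimum
}

# textbook sandwich variances computed with dense projection matrices
oracle_ols_se <- function(data, robust = FALSE) {
  y <- data$y - mean(data$y)
  X <- center_cols(data$X)
  n <- data$n
  XtXi <- solve(crossprod(X))
  u <- drop(y - X %*% XtXi %*% crossprod(X, y))
  if (robust) {
    meat <- matrix(0, data$l, data$l)
    for (i in seq_len(n))
      meat <- meat + tcrossprod(X[i, ]) * u[i]^2
    unname(sqrt(diag(XtXi %*% meat %*% XtXi)))
  } else {
    unname(sqrt(diag(sum(u^2) / n * XtXi)))
  }
}

oracle_2sls_se <- function(data, robust = FALSE) {
  y <- data$y - mean(data$y)
  X <- center_cols(data$X)
  Z <- center_cols(data$Z)
  n <- data$n
  P <- Z %*% solve(crossprod(Z)) %*% t(Z)
  XPXi <- solve(t(X) %*% P %*% X)
  b <- XPXi %*% t(X) %*% P %*% y
  u <- drop(y - X %*% b)
  Xh <- P %*% X
  if (robust) {
    meat <- matrix(0, data$l, data$l)
    for (i in seq_len(n))
      meat <- meat + tcrossprod(Xh[i, ]) * u[i]^2
    unname(sqrt(diag(XPXi %*% meat %*% XPXi)))
  } else {
    unname(sqrt(diag(sum(u^2) / n * XPXi)))
  }
}

# efficient-GMM variance assembled with loops
oracle_gmm_se <- function(result, data) {
  m <- oracle_moments(result$beta_hat, data)
  Z <- center_cols(data$Z)
  X <- center_cols(data$X)
  G <- crossprod(Z, X) / data$n
  unname(sqrt(diag(solve(t(G) %*% solve(m$Om) %*% G)) / data$n))
}

mc_se_median <- function(iqr, reps) 3 * 1.253 * (iqr / 1.349) / sqrt(reps)
mc_se_prop <- function(p, reps) 3 * sqrt(p * (1 - p) / reps)
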