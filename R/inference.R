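#' @name iv_inference
#' @title Standard errors and Wald inference for IV estimates
#'
#' @description
#' With many weak instruments the usual asymptotic standard errors of LIML and
#' the CUE are too small and Wald tests over-reject. [bekker_se] and [nw_se]
#' implement variance estimators that remain valid under many-instrument
#' asymptotics (the number of instruments growing with the sample size) for
#' LIML and CUE respectively; [conventional_se] gives the standard
#' fixed-instrument asymptotic variances for every estimator.
#'
#' @return An object of class `iv_inference` with elements `se` (per
#'   coefficient), `vcov`, `se_kind`, `wald_stat` and `p_value` (joint test of
#'   all coefficients equal zero against chi-squared with `l` degrees of
#'   freedom), and 95% confidence limits `ci_low`, `ci_high`.
NULL

new_inference <- function(V, kind, result, alpha = 0.05) {
  V <- as.matrix(V)
  se <- sqrt(diag(V))
  if (any(!is.finite(se)) || any(se <= 0))
    iv_error("non-positive variance estimate", "weakivmr_degenerate")
  b <- result$beta_hat
  ws <- drop(crossprod(b, solve(V, b)))
  z <- stats::qnorm(1 - alpha / 2)
  structure(
    list(se = stats::setNames(se, names(b)), vcov = V, se_kind = kind,
         estimator = result$estimator,
         wald_stat = ws,
         p_value = stats::pchisq(ws, df = result$l, lower.tail = FALSE),
         ci_low = b - z * se, ci_high = b + z * se),
    class = "iv_inference")
}

#' @export
print.iv_inference <- function(x, ...) {
  cat(sprintf("<iv_inference> %s / %s\n", x$estimator, x$se_kind))
  print(data.frame(se = x$se, ci_low = x$ci_low, ci_high = x$ci_high))
  cat(sprintf("Wald (all = 0): %.4g, p = %.4g\n", x$wald_stat, x$p_value))
  invisible(x)
}

#' Conventional asymptotic standard errors
#'
#' Homoskedastic (or heteroskedasticity-robust) fixed-instrument asymptotic
#' variances: \eqn{\hat\sigma^2 (X'X)^{-1}} for OLS,
#' \eqn{\hat\sigma^2 (X'P_Z X)^{-1}} for 2SLS, the k-class analogue
#' \eqn{\hat\sigma^2 (X'P_Z X - \hat\lambda X'X)^{-1}} for LIML, and the
#' efficient-GMM variance \eqn{\frac{1}{n}(\hat G'\hat\Omega^{-1}\hat G)^{-1}}
#' for two-step GMM and CUE (which is heteroskedasticity-consistent by
#' construction; `robust` is ignored for those). Residual variances use the
#' large-sample divisor `n`.
#'
#' @param result An `iv_estimate`.
#' @param data The [iv_data] the estimate was fitted on.
#' @param robust Heteroskedasticity-robust sandwich? Default `FALSE`.
#' @param alpha Confidence level complement for the reported interval.
#' @return An `iv_inference`; see [iv_inference].
#' @export
conventional_se <- function(result, data, robust = FALSE, alpha = 0.05) {
  core <- iv_core(data)
  n <- data$n
  u <- iv_residuals(result, data)
  s2 <- sum(u^2) / n
  V <- switch(result$estimator,
    OLS = {
      if (robust) {
        Xi <- solve(core$XtX)
        meat <- crossprod(core$Xc * u)
        Xi %*% meat %*% Xi
      } else s2 * solve(core$XtX)
    },
    TSLS = {
      if (robust) {
        Xh <- qr.fitted(core$qz, core$Xc)
        Hi <- solve(core$XPX)
        Hi %*% crossprod(Xh * u) %*% Hi
      } else s2 * solve(core$XPX)
    },
    LIML = {
      lam <- liml_lambda(result)
      H <- core$XPX - lam * core$XtX
      if (robust) {
        Xk <- qr.fitted(core$qz, core$Xc) - lam * core$Xc
        Hi <- solve(H)
        Hi %*% crossprod(Xk * u) %*% Hi
      } else s2 * solve(H)
    },
    GMM2 = ,
    CUE = {
      Om <- crossprod(core$Zc * u) / n
      G <- crossprod(core$Zc, core$Xc) / n
      A <- crossprod(G, solve(Om, G))
      solve((A + t(A)) / 2) / n
    },
    iv_error(paste0("no conventional variance for estimator ", result$estimator),
             "weakivmr_data_error"))
  new_inference(V, if (robust) "robust" else "conventional", result, alpha)
}

#' Bekker many-instrument standard errors for LIML
#'
#' Variance estimator valid under many-instrument asymptotics (J growing with
#' n), in the form given by Hansen, Hausman and Newey (2008) for Bekker's
#' (1994) limiting distribution:
#' \deqn{\hat V = \hat H^{-1}\hat\Sigma\hat H^{-1}, \quad
#'   \hat H = X'P_Z X - \hat\alpha X'X, \quad \hat\alpha = \tilde u'P_Z\tilde
#'   u/\tilde u'\tilde u,}
#' \deqn{\hat\Sigma = \hat\sigma^2\left[(1-\hat\alpha)^2 \tilde X'P_Z\tilde X
#'   + \hat\alpha^2 \tilde X'(I-P_Z)\tilde X\right], \quad
#'   \tilde X = X - \tilde u (\tilde u'X)/(\tilde u'\tilde u).}
#' It reduces towards the conventional LIML variance as \eqn{J/n \to 0} with
#' strong instruments.
#'
#' @param result An `iv_estimate` from [fit_liml].
#' @inheritParams conventional_se
#' @return An `iv_inference`; see [iv_inference].
#' @export
bekker_se <- function(result, data, alpha = 0.05) {
  if (result$estimator != "LIML")
    iv_error("bekker_se is defined for LIML estimates", "weakivmr_data_error")
  if (data$J >= data$n)
    iv_error("Bekker correction requires J < n", "weakivmr_invalid_regime")
  core <- iv_core(data)
  n <- data$n
  u <- iv_residuals(result, data)
  uu <- sum(u^2)
  Pu <- qr.fitted(core$qz, u)
  a <- sum(u * Pu) / uu
  s2 <- uu / n
  Xt <- core$Xc - tcrossprod(u, drop(crossprod(u, core$Xc))) / uu
  PXt <- qr.fitted(core$qz, Xt)
  XtPXt <- crossprod(PXt, Xt)
  XtMXt <- crossprod(Xt) - XtPXt
  Sig <- s2 * ((1 - a)^2 * XtPXt + a^2 * XtMXt)
  H <- core$XPX - a * core$XtX
  Hi <- solve((H + t(H)) / 2)
  new_inference(Hi %*% ((Sig + t(Sig)) / 2) %*% Hi, "bekker", result, alpha)
}

#' Newey-Windmeijer many-weak-moment standard errors for the CUE
#'
#' Variance estimator valid under many weak moment conditions (Newey and
#' Windmeijer, 2009): a sandwich whose bread is the Hessian of (half) the CUE
#' objective, \eqn{\hat H = \frac{1}{2}\partial^2 Q(\hat\beta)/\partial\beta
#' \partial\beta'} (computed by central differences), and whose meat is
#' \eqn{n\hat D'\hat\Omega^{-1}\hat D} with the CUE first-order-condition
#' derivative \eqn{\hat D_j = \partial\hat g/\partial\beta_j - \hat C_j
#' \hat\Omega^{-1}\hat g}, \eqn{\hat C_j = \frac{1}{n}\sum_i (\partial
#' g_i/\partial\beta_j) g_i'}. A flat objective (weak identification) gives a
#' small Hessian and hence larger, honest standard errors; with strong
#' instruments the estimator coincides with the usual efficient-GMM variance.
#' If the Hessian is not positive definite the conventional efficient-GMM
#' variance is returned with a warning.
#'
#' @param result An `iv_estimate` from [fit_cue].
#' @inheritParams conventional_se
#' @return An `iv_inference`; see [iv_inference].
#' @export
nw_se <- function(result, data, alpha = 0.05) {
  if (result$estimator != "CUE")
    iv_error("nw_se is defined for CUE estimates", "weakivmr_data_error")
  core <- iv_core(data)
  n <- data$n
  l <- data$l
  b <- result$beta_hat
  u <- iv_residuals(result, data)
  g <- drop(crossprod(core$Zc, u)) / n
  Om <- crossprod(core$Zc * u) / n
  Og <- solve(Om, g)
  D <- matrix(0, data$J, l)
  for (j in seq_len(l)) {
    Cj <- -crossprod(core$Zc * (core$Xc[, j] * u), core$Zc) / n
    D[, j] <- -drop(crossprod(core$Zc, core$Xc[, j])) / n - drop(Cj %*% Og)
  }
  meat <- n * crossprod(D, solve(Om, D))
  meat <- (meat + t(meat)) / 2

  fn <- function(bb) as.numeric(cue_objective(bb, data))
  H <- matrix(0, l, l)
  h <- 1e-4 * pmax(1, abs(b))
  f0 <- fn(b)
  for (j in seq_len(l)) {
    ej <- replace(numeric(l), j, h[j])
    H[j, j] <- (fn(b + ej) - 2 * f0 + fn(b - ej)) / h[j]^2
    if (l > 1L) for (k in seq_len(j - 1L)) {
      ek <- replace(numeric(l), k, h[k])
      H[j, k] <- H[k, j] <-
        (fn(b + ej + ek) - fn(b + ej - ek) - fn(b - ej + ek) + fn(b - ej - ek)) /
        (4 * h[j] * h[k])
    }
  }
  H <- H / 2
  ok <- all(eigen((H + t(H)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values > 0)
  if (!ok) {
    warning("CUE objective Hessian not positive definite; falling back to the efficient-GMM variance")
    G <- crossprod(core$Zc, core$Xc) / n
    A <- crossprod(G, solve(Om, G))
    return(new_inference(solve((A + t(A)) / 2) / n, "newey_windmeijer",
                         result, alpha))
  }
  Hi <- solve(H)
  new_inference(Hi %*% meat %*% Hi, "newey_windmeijer", result, alpha)
}

#' Wald test of a point null
#'
#' Scalar coefficients are tested with \eqn{((\hat\beta-\beta_0)/se)^2}
#' against \eqn{\chi^2_1}; for several exposures the joint quadratic form
#' against \eqn{\chi^2_l} is used. No small-sample t correction is applied.
#'
#' @param result An `iv_estimate`.
#' @param inference An `iv_inference` for that estimate.
#' @param beta0 Null value(s), recycled to length `l`. Default 0.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
wald_test <- function(result, inference, beta0 = 0) {
  d <- result$beta_hat - rep_len(beta0, result$l)
  stat <- drop(crossprod(d, solve(inference$vcov, d)))
  list(statistic = stat, df = result$l,
       p_value = stats::pchisq(stat, df = result$l, lower.tail = FALSE))
}

#' First-stage weak-instrument diagnostics
#'
#' Joint F-statistic and partial R-squared from the first-stage regression of
#' the (single) exposure on all instruments plus intercept, and the sample
#' concentration estimate `J * (F - 1)`; the expected F implied by that
#' concentration (`concentration/J + 1`) is reported alongside.
#'
#' @param data An [iv_data] with `l = 1`.
#' @return An object of class `iv_diagnostics`: a list with `f_statistic`,
#'   `partial_r2`, `concentration`, `expected_f`, `n`, `J`.
#' @export
first_stage_diagnostics <- function(data) {
  if (data$l != 1L)
    iv_error("first-stage diagnostics require a single exposure",
             "weakivmr_data_error")
  core <- iv_core(data)
  n <- data$n
  J <- data$J
  ess <- core$XPX[1L, 1L]
  tss <- core$XtX[1L, 1L]
  rss <- tss - ess
  f <- (ess / J) / (rss / (n - J - 1L))
  mu2_hat <- J * (f - 1)
  structure(list(f_statistic = f, partial_r2 = ess / tss,
                 concentration = mu2_hat,
                 expected_f = mu2_hat / J + 1,
                 n = n, J = J),
            class = "iv_diagnostics")
}

#' @export
print.iv_diagnostics <- function(x, ...) {
  cat(sprintf("<iv_diagnostics> F = %.3f, partial R2 = %.4f, concentration = %.2f (n = %d, J = %d)\n",
              x$f_statistic, x$partial_r2, x$concentration, x$n, x$J))
  invisible(x)
}

#' Concentration parameter of an equal-effect genotype design
#'
#' For J independent variants with identical first-stage coefficient `pi` and
#' Hardy-Weinberg dosage variance \eqn{\sigma_z^2 = 2\,maf(1-maf)}, the
#' concentration parameter is
#' \deqn{\mu^2 = n J \pi^2 \sigma_z^2 / \sigma_v^2.}
#'
#' @param n Sample size.
#' @param J Number of variants.
#' @param pi Common first-stage coefficient.
#' @param maf Minor allele frequency, in (0, 1).
#' @param sigma_v2 First-stage error variance (> 0).
#' @return The concentration parameter (non-negative scalar).
#' @export
concentration_parameter <- function(n, J, pi, maf, sigma_v2) {
  stopifnot(maf > 0, maf < 1, sigma_v2 > 0, n > 0, J >= 1)
  n * J * pi^2 * (2 * maf * (1 - maf)) / sigma_v2
}

#' Expected first-stage F (Stock approximation)
#'
#' The expectation of the first-stage F-statistic minus one approximately
#' equals the concentration parameter divided by the number of instruments:
#' `E[F] ~ mu2/J + 1`.
#'
#' @param mu2 Concentration parameter.
#' @param J Number of instruments (>= 1).
#' @return The approximate expected F.
#' @export
expected_f <- function(mu2, J) {
  stopifnot(J >= 1, mu2 >= 0)
  mu2 / J + 1
}

#' Approximate many-weak-instrument bias of 2SLS
#'
#' Approximates the bias of 2SLS towards OLS for more than three instruments:
#' \deqn{E[\hat\beta_{2SLS} - \beta] \approx \frac{\sigma_{uv}}{\sigma_v^2}
#'   (J - 2)\, E\!\left[\frac{1}{\chi^2_J(\mu^2)}\right],}
#' the inverse moment of a noncentral chi-square with J degrees of freedom and
#' noncentrality \eqn{\mu^2} (evaluated by its Poisson-mixture series). For
#' large \eqn{\mu^2} this behaves like \eqn{(\sigma_{uv}/\sigma_v^2)(J-2)/
#' \mu^2}: proportional to the number of instruments and the error covariance,
#' inversely proportional to the concentration parameter.
#'
#' @param J Number of instruments. The approximation is derived for `J > 3`;
#'   smaller J is computed anyway with a warning.
#' @param mu2 Concentration parameter (> 0).
#' @param sigma_uv Covariance of structural and first-stage errors.
#' @param sigma_v2 First-stage error variance.
#' @return The approximate bias.
#' @export
bias_2sls_approx <- function(J, mu2, sigma_uv, sigma_v2) {
  stopifnot(sigma_v2 > 0, J >= 1)
  if (mu2 <= 0)
    iv_error("bias approximation undefined at zero concentration",
             "weakivmr_degenerate")
  if (J <= 3)
    warning("2SLS bias approximation is derived for J > 3")
  (sigma_uv / sigma_v2) * (J - 2) * chisq_nc_inv_moment(J, mu2)
}

# E[1/X], X ~ noncentral chi-square(df, ncp): Poisson mixture over central
# components, E_k[1/(df - 2 + 2k)], k ~ Poisson(ncp/2).
chisq_nc_inv_moment <- function(df, ncp) {
  lam <- ncp / 2
  kmax <- max(200L, ceiling(lam + 12 * sqrt(lam)))
  k <- 0:kmax
  sum(stats::dpois(k, lam) / (df - 2 + 2 * k))
}

#' Approximate many-weak-instrument bias of LIML
#'
#' \deqn{E[\hat\beta_{LIML} - \beta] \approx -\frac{\sigma_{uv}}
#'   {\sigma_v^2\,\mu^2},}
#' independent of the number of instruments and opposite in sign to the 2SLS
#' bias: adding instruments hurts only if they fail to increase the
#' concentration parameter.
#'
#' @inheritParams bias_2sls_approx
#' @return The approximate bias.
#' @export
bias_liml_approx <- function(mu2, sigma_uv, sigma_v2) {
  stopifnot(sigma_v2 > 0)
  if (mu2 <= 0)
    iv_error("bias approximation undefined at zero concentration",
             "weakivmr_degenerate")
  -sigma_uv / (sigma_v2 * mu2)
}

#' Sargan overidentification test
#'
#' `n` times the R-squared of the IV residuals regressed on all instruments,
#' against chi-squared with `J - l` degrees of freedom. Assumes conditional
#' homoskedasticity; see [hansen_j_test] for the robust version.
#'
#' @param result An `iv_estimate`.
#' @param data The [iv_data] the estimate was fitted on.
#' @return A list with `statistic`, `df = J - l`, `p_value`.
#' @export
sargan_test <- function(result, data) {
  if (data$J <= data$l)
    iv_error("overidentification test requires J > l",
             "weakivmr_not_overidentified")
  core <- iv_core(data)
  u <- iv_residuals(result, data)
  stat <- data$n * sum(u * qr.fitted(core$qz, u)) / sum(u^2)
  df <- data$J - data$l
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Hansen J overidentification test
#'
#' The efficient-GMM/CUE objective evaluated at the estimate, against
#' chi-squared with `J - l` degrees of freedom; robust to conditional
#' heteroskedasticity.
#'
#' @inheritParams sargan_test
#' @return A list with `statistic`, `df = J - l`, `p_value`.
#' @export
hansen_j_test <- function(result, data) {
  if (data$J <= data$l)
    iv_error("overidentification test requires J > l",
             "weakivmr_not_overidentified")
  stat <- as.numeric(cue_objective(result$beta_hat, data))
  df <- data$J - data$l
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Hausman test of IV versus OLS
#'
#' Tests whether the instrumental-variable estimate differs from OLS using the
#' classic variance-difference form
#' \eqn{(\hat\beta_{IV}-\hat\beta_{OLS})'(V_{IV}-V_{OLS})^{-1}
#' (\hat\beta_{IV}-\hat\beta_{OLS})} with homoskedastic variances, against
#' chi-squared with `l` degrees of freedom. A negative variance difference is
#' clamped: the statistic is reported as 0 with a warning.
#'
#' @param iv_result An `iv_estimate` from an IV estimator.
#' @param ols_result An `iv_estimate` from [fit_ols] on the same data.
#' @param data The shared [iv_data].
#' @return A list with `statistic`, `df = l`, `p_value`.
#' @export
hausman_test <- function(iv_result, ols_result, data) {
  if (ols_result$estimator != "OLS")
    iv_error("ols_result must come from fit_ols", "weakivmr_data_error")
  if (iv_result$n != data$n || ols_result$n != data$n ||
      iv_result$l != data$l || ols_result$l != data$l)
    iv_error("both fits must come from the supplied data", "weakivmr_data_error")
  V_iv <- conventional_se(iv_result, data)$vcov
  V_ols <- conventional_se(ols_result, data)$vcov
  d <- iv_result$beta_hat - ols_result$beta_hat
  Vd <- V_iv - V_ols
  ev <- eigen((Vd + t(Vd)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("variance difference not positive definite; Hausman statistic reported as 0")
    stat <- 0
  } else {
    stat <- drop(crossprod(d, solve(Vd, d)))
  }
  list(statistic = stat, df = data$l,
       p_value = stats::pchisq(stat, data$l, lower.tail = FALSE))
}
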