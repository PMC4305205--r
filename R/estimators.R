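#' @name iv_estimators
#' @title The GMM family of instrumental-variable estimators
#'
#' @description
#' All estimators here minimize a GMM criterion
#' \deqn{Q(\beta) = n \, \hat g(\beta)' W^{-1} \hat g(\beta), \qquad
#'       \hat g(\beta) = \frac{1}{n}\sum_i z_i (y_i - x_i'\beta),}
#' and differ only in the weight matrix \eqn{W}: two-stage least squares uses
#' \eqn{Z'Z/n}, two-step GMM uses the residual-based efficient weight from a
#' preliminary estimate, the continuously updating estimator (CUE) lets the
#' weight depend on \eqn{\beta} itself, and LIML is the CUE under conditional
#' homoskedasticity. OLS is the GMM estimator with the exposures as their own
#' instruments.
#'
#' @param data An [iv_data] object.
#' @return An object of class `iv_estimate` with elements `beta_hat`
#'   (named length-`l` vector), `estimator`, `objective_value` (minimized
#'   criterion, where defined), `liml_kappa` (LIML only: the k-class
#'   eigenvalue), `converged`, `omega_degenerate` (CUE/GMM2: whether a
#'   pseudo-inverse of the weight matrix was needed) and the dimensions
#'   `n`, `J`, `l`.
NULL

new_estimate <- function(beta, estimator, data, objective = NA_real_,
                         liml_kappa = NA_real_, converged = TRUE,
                         omega_degenerate = FALSE) {
  beta <- drop(beta)
  names(beta) <- colnames(data$X)
  structure(
    list(beta_hat = beta, estimator = estimator,
         objective_value = objective, liml_kappa = liml_kappa,
         converged = converged, omega_degenerate = omega_degenerate,
         n = data$n, J = data$J, l = data$l,
         include_intercept = data$include_intercept),
    class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat(sprintf("<iv_estimate> %s (n = %d, J = %d)\n", x$estimator, x$n, x$J))
  print(signif(x$beta_hat, 6))
  if (!is.na(x$objective_value))
    cat(sprintf("objective: %.6g\n", x$objective_value))
  if (!is.na(x$liml_kappa))
    cat(sprintf("kappa: %.6f\n", x$liml_kappa))
  if (!x$converged) cat("warning: optimizer did not converge\n")
  invisible(x)
}

solve_pd <- function(A, b, context) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    iv_error(paste0("singular cross-product matrix in ", context,
                    " (degenerate design)"), "weakivmr_degenerate")
  backsolve(ch, forwardsolve(t(ch), b))
}

#' Ordinary least squares
#'
#' The GMM estimator with the exposures used as their own instruments. Under
#' confounding it is inconsistent for the causal effect; it is reported as the
#' benchmark the weak-instrument bias of 2SLS pulls towards.
#'
#' @inheritParams iv_estimators
#' @return An `iv_estimate`; see [iv_estimators].
#' @export
fit_ols <- function(data) {
  core <- iv_core(data)
  beta <- solve_pd(core$XtX, core$Xty, "fit_ols")
  new_estimate(beta, "OLS", data, objective = 0)
}

#' Two-stage least squares
#'
#' Computes \eqn{\hat\beta = (X'P_Z X)^{-1} X'P_Z y} with \eqn{P_Z} the
#' projection onto the instrument space (intercept included in both stages
#' when requested), i.e. the GMM estimator with weight matrix \eqn{Z'Z/n}.
#'
#' @inheritParams iv_estimators
#' @return An `iv_estimate`; see [iv_estimators].
#' @export
fit_2sls <- function(data) {
  core <- iv_core(data)
  beta <- solve_pd(core$XPX, core$XPy, "fit_2sls (first stage rank deficient)")
  # objective n g'(Z'Z/n)^{-1} g = u' P u
  uPu <- core$yPy - 2 * sum(core$XPy * beta) +
    drop(crossprod(beta, core$XPX %*% beta))
  new_estimate(beta, "TSLS", data, objective = max(uPu, 0))
}

#' Two-step efficient GMM
#'
#' One-step update of a preliminary consistent estimate (2SLS by default)
#' using the efficient weight matrix
#' \eqn{\hat W(\tilde\beta) = \frac{1}{n}\sum_i z_i z_i' \tilde u_i^2}
#' built from the preliminary residuals.
#'
#' @inheritParams iv_estimators
#' @param initial An `iv_estimate` providing the preliminary estimate;
#'   defaults to [fit_2sls].
#' @param centered Center the moment outer products around the sample moment
#'   vector? Default `FALSE` (uncentered, matching the two-step weight used
#'   throughout the package).
#' @return An `iv_estimate`; see [iv_estimators].
#' @export
fit_gmm2 <- function(data, initial = NULL, centered = FALSE) {
  core <- iv_core(data)
  if (is.null(initial)) initial <- fit_2sls(data)
  if (!all(is.finite(initial$beta_hat)))
    iv_error("initial estimate must be finite", "weakivmr_data_error")
  n <- data$n
  u0 <- drop(core$yc - core$Xc %*% initial$beta_hat)
  Om <- crossprod(core$Zc * u0) / n
  g0 <- crossprod(core$Zc, u0) / n
  if (centered) Om <- Om - tcrossprod(g0)
  G <- crossprod(core$Zc, core$Xc) / n
  gy <- crossprod(core$Zc, core$yc) / n
  ch <- tryCatch(chol(Om), error = function(e) NULL)
  degenerate <- is.null(ch)
  if (degenerate) {
    warning(sprintf(
      "two-step weight matrix is ill conditioned (condition number %.3g); using pseudo-inverse",
      kappa(Om)))
    Omi <- MASS::ginv(Om, tol = 1e-10)
    sol <- Omi %*% cbind(G, gy)
  } else {
    sol <- backsolve(ch, forwardsolve(t(ch), cbind(G, gy)))
  }
  A <- crossprod(G, sol[, seq_len(data$l), drop = FALSE])
  b <- crossprod(G, sol[, data$l + 1L])
  beta <- solve_pd((A + t(A)) / 2, b, "fit_gmm2")
  u <- drop(core$yc - core$Xc %*% beta)
  g <- crossprod(core$Zc, u) / n
  obj <- if (degenerate) {
    n * drop(crossprod(g, Omi %*% g))
  } else {
    n * sum(backsolve(ch, g, transpose = TRUE)^2)
  }
  new_estimate(beta, "GMM2", data, objective = max(obj, 0),
               omega_degenerate = degenerate)
}

#' Continuously updating GMM objective
#'
#' Evaluates \eqn{Q(\beta) = n\,\hat g(\beta)'\hat\Omega(\beta)^{-1}\hat
#' g(\beta)} with \eqn{\hat g(\beta) = \frac{1}{n}\sum_i z_i(y_i - x_i'\beta)}
#' and \eqn{\hat\Omega(\beta) = \frac{1}{n}\sum_i z_i z_i' (y_i - x_i'\beta)^2}
#' (uncentered by default). With `homoskedastic = TRUE` the weight matrix is
#' replaced by \eqn{\hat\sigma^2(\beta)\,Z'Z/n}, which turns the objective into
#' the Anderson-Rubin ratio \eqn{n\,u'P_Z u / u'u} minimized by LIML.
#'
#' @param beta Coefficient vector of length `l`.
#' @inheritParams iv_estimators
#' @param homoskedastic Use the homoskedastic weight matrix? Default `FALSE`.
#' @param centered Subtract \eqn{\hat g \hat g'} from the weight matrix?
#'   Default `FALSE`.
#' @return The objective value (non-negative scalar). If the weight matrix was
#'   numerically singular and a pseudo-inverse (relative eigenvalue cutoff
#'   `1e-10`) was applied, the result carries attribute `degenerate = TRUE`.
#' @export
cue_objective <- function(beta, data, homoskedastic = FALSE, centered = FALSE) {
  core <- iv_core(data)
  n <- data$n
  u <- drop(core$yc - core$Xc %*% beta)
  g <- crossprod(core$Zc, u) / n
  if (homoskedastic) {
    s2 <- sum(u^2) / n
    Om <- s2 * crossprod(core$Zc) / n
  } else {
    Om <- crossprod(core$Zc * u) / n
  }
  if (centered) Om <- Om - tcrossprod(g)
  ch <- tryCatch(chol(Om), error = function(e) NULL)
  if (is.null(ch)) {
    val <- n * drop(crossprod(g, MASS::ginv(Om, tol = 1e-10) %*% g))
    return(structure(max(val, 0), degenerate = TRUE))
  }
  max(n * sum(backsolve(ch, g, transpose = TRUE)^2), 0)
}

# Fast scalar-exposure CUE machinery: for l = 1 the weight matrix is quadratic
# in beta, Om(b) = (Oyy - 2 b Oxy + b^2 Oxx)/n, so each objective evaluation
# after the three cross products costs only a J x J Cholesky.
cue_quadratic <- function(core, n) {
  Zy <- core$Zc * core$yc
  Zx <- core$Zc * drop(core$Xc)
  Oxy <- crossprod(Zy, Zx)
  list(Oyy = crossprod(Zy), Oxy = (Oxy + t(Oxy)) / 2, Oxx = crossprod(Zx),
       gy = drop(crossprod(core$Zc, core$yc)) / n,
       gx = drop(crossprod(core$Zc, core$Xc)) / n, n = n)
}

# analytic gradient of cue_q_eval: with s = Om(b)^{-1} g(b),
# Q'(b) = -2 n gx' s + 2 s'(Oxy - b Oxx) s
cue_q_grad <- function(b, qd) {
  Om <- (qd$Oyy - (2 * b) * qd$Oxy + b^2 * qd$Oxx) / qd$n
  g <- qd$gy - b * qd$gx
  s <- tryCatch(solve(Om, g), error = function(e) NULL)
  if (is.null(s)) return(NA_real_)
  -2 * qd$n * sum(qd$gx * s) + 2 * drop(crossprod(s, (qd$Oxy - b * qd$Oxx) %*% s))
}

# Newton refinement of a bracketed minimum, so the reported optimum is
# reproducible to near machine precision (optimize alone stalls around the
# sqrt(eps) flat region of the objective)
cue_polish <- function(b, qd, iters = 12L) {
  for (it in seq_len(iters)) {
    g1 <- cue_q_grad(b, qd)
    h <- 1e-6 * max(1, abs(b))
    g2 <- (cue_q_grad(b + h, qd) - cue_q_grad(b - h, qd)) / (2 * h)
    if (!is.finite(g1) || !is.finite(g2) || g2 <= 0) break
    step <- g1 / g2
    if (!is.finite(step) || abs(step) > 1) break
    b <- b - step
    if (abs(step) < 1e-13 * max(1, abs(b))) break
  }
  b
}

cue_q_eval <- function(b, qd) {
  Om <- (qd$Oyy - (2 * b) * qd$Oxy + b^2 * qd$Oxx) / qd$n
  g <- qd$gy - b * qd$gx
  ch <- tryCatch(chol(Om), error = function(e) NULL)
  if (is.null(ch)) {
    val <- qd$n * drop(crossprod(g, MASS::ginv(Om, tol = 1e-10) %*% g))
    return(structure(max(val, 0), degenerate = TRUE))
  }
  max(qd$n * sum(backsolve(ch, g, transpose = TRUE)^2), 0)
}

#' Continuously updating estimator (CUE)
#'
#' Minimizes [cue_objective] from several starting values and returns the best
#' minimum found. The default starts are \{-2, -1, 0, 1, 2\} times the
#' two-step GMM estimate, guarding against local optima of the (possibly
#' multimodal) objective. For a single exposure each start uses derivative-free
#' bounded minimization on a bracket of half-width 10 around the start; with
#' several exposures a quasi-Newton minimizer is used.
#'
#' @inheritParams iv_estimators
#' @param starts Optional list (or vector, for `l = 1`) of starting values.
#' @param centered Use the centered weight matrix? Default `FALSE`.
#' @return An `iv_estimate`; see [iv_estimators]. Ties between starts with
#'   equal objective values are broken towards the smallest `|beta|`.
#' @export
fit_cue <- function(data, starts = NULL, centered = FALSE) {
  core <- iv_core(data)
  n <- data$n
  if (is.null(starts)) {
    b0 <- fit_gmm2(data)$beta_hat
    starts <- lapply(c(-2, -1, 0, 1, 2), function(k) k * b0)
  }
  if (is.numeric(starts) && data$l == 1L) starts <- as.list(starts)

  degenerate <- FALSE
  if (data$l == 1L && !centered) {
    qd <- cue_quadratic(core, n)
    cand <- lapply(starts, function(s0) {
      s0 <- drop(s0)
      opt <- stats::optimize(function(b) cue_q_eval(b, qd),
                             interval = c(s0 - 10, s0 + 10), tol = 1e-10)
      opt
    })
    objs <- vapply(cand, `[[`, numeric(1), "objective")
    mins <- vapply(cand, `[[`, numeric(1), "minimum")
    best <- order(objs, abs(mins))[1L]   # tie-break: smallest |beta|
    b <- cue_polish(mins[best], qd)
    obj <- cue_q_eval(b, qd)
    degenerate <- isTRUE(attr(obj, "degenerate"))
    return(new_estimate(b, "CUE", data, objective = as.numeric(obj),
                        converged = TRUE, omega_degenerate = degenerate))
  }

  fn <- function(b) as.numeric(cue_objective(b, data, centered = centered))
  cand <- lapply(starts, function(s0) {
    stats::optim(drop(s0), fn, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
  })
  objs <- vapply(cand, `[[`, numeric(1), "value")
  norms <- vapply(cand, function(o) sqrt(sum(o$par^2)), numeric(1))
  best <- order(objs, norms)[1L]
  conv <- cand[[best]]$convergence == 0L
  if (!any(vapply(cand, function(o) o$convergence == 0L, logical(1))))
    warning("no CUE start converged; returning best value found")
  obj <- cue_objective(cand[[best]]$par, data, centered = centered)
  new_estimate(cand[[best]]$par, "CUE", data, objective = as.numeric(obj),
               converged = conv,
               omega_degenerate = isTRUE(attr(obj, "degenerate")))
}

#' Limited information maximum likelihood (LIML)
#'
#' Minimizes the homoskedastic CUE objective, the Anderson-Rubin ratio
#' \eqn{n\,u'P_Z u/u'u}, which is solved exactly by the smallest eigenvalue
#' \eqn{\lambda} of the generalized eigenproblem on the moment matrices of
#' `[y X]`. The coefficient solves \eqn{(X'P_Z X - \lambda X'X)\beta =
#' X'P_Z y - \lambda X'y}, i.e. LIML is the k-class estimator at
#' \eqn{\kappa = 1/(1-\lambda)}, stored as `liml_kappa`.
#'
#' @inheritParams iv_estimators
#' @return An `iv_estimate`; see [iv_estimators].
#' @export
fit_liml <- function(data) {
  core <- iv_core(data)
  B <- core$WtW
  A <- core$WPW
  Rb <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(Rb))
    iv_error("moment matrix of [y X] is singular", "weakivmr_degenerate")
  # symmetric similarity transform R^{-T} A R^{-1}
  S <- backsolve(Rb, t(backsolve(Rb, A, transpose = TRUE)), transpose = TRUE)
  S <- (S + t(S)) / 2
  lam <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (lam < -1e-8 || lam > 1 + 1e-8)
    iv_error(sprintf("LIML eigenvalue %.3g outside [0, 1]", lam),
             "weakivmr_degenerate")
  lam <- min(max(lam, 0), 1 - 1e-12)
  H <- core$XPX - lam * core$XtX
  beta <- solve_pd((H + t(H)) / 2, core$XPy - lam * core$Xty, "fit_liml")
  new_estimate(beta, "LIML", data, objective = data$n * lam,
               liml_kappa = 1 / (1 - lam))
}

# internal: the LIML ratio eigenvalue (u'Pu/u'u at the optimum)
liml_lambda <- function(result) {
  1 - 1 / result$liml_kappa
}

#' Sequential add-one-instrument analysis
#'
#' Re-fits the model with the first `j` instruments of a given ordering for
#' `j = 1, ..., J`, mirroring the applied practice of adding variants one at a
#' time in decreasing order of first-stage effect. With many weak instruments
#' the 2SLS trajectory drifts towards OLS as weak instruments accumulate while
#' the CUE stays near the causal effect.
#'
#' @inheritParams iv_estimators
#' @param order Integer permutation of `1:J` giving the order in which
#'   instruments enter. Defaults to `1:J`.
#' @param estimators Character subset of `c("tsls", "cue")`.
#' @return A data frame with one row per step and estimator: `j`, `estimator`,
#'   `estimate`, `se` (conventional), `f_statistic` (first-stage joint F for
#'   the first `j` instruments), `converged` and `error` (message for steps
#'   whose fit failed; such failures do not abort the sweep).
#' @export
sequential_fit <- function(data, order = seq_len(data$J),
                           estimators = c("tsls", "cue")) {
  order <- as.integer(order)
  if (length(order) > data$J || anyDuplicated(order) ||
      any(order < 1L | order > data$J))
    iv_error("order must be a permutation of instrument indices",
             "weakivmr_data_error")
  estimators <- match.arg(estimators, c("tsls", "cue"), several.ok = TRUE)
  rows <- list()
  for (j in seq_along(order)) {
    dj <- iv_data(data$y, data$X, data$Z[, order[seq_len(j)], drop = FALSE],
                  include_intercept = data$include_intercept)
    fs <- if (data$l == 1L) first_stage_diagnostics(dj)$f_statistic else NA_real_
    for (est in estimators) {
      row <- tryCatch({
        fit <- if (est == "tsls") fit_2sls(dj) else fit_cue(dj)
        inf <- conventional_se(fit, dj)
        data.frame(j = j, estimator = fit$estimator,
                   estimate = unname(fit$beta_hat[1L]), se = inf$se[1L],
                   f_statistic = fs, converged = fit$converged,
                   error = NA_character_)
      }, error = function(e) {
        data.frame(j = j, estimator = toupper(est), estimate = NA_real_,
                   se = NA_real_, f_statistic = fs, converged = FALSE,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
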