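#' Assemble an instrumental-variable data set
#'
#' Bundles an outcome vector, an exposure matrix and an instrument matrix into
#' a validated container used by all estimators in the package. With
#' `include_intercept = TRUE` (the default) an intercept is handled by
#' centering `y`, `X` and `Z`; all moment computations then operate on the
#' centered variables, which is numerically equivalent to carrying an explicit
#' constant through both stages.
#'
#' @param y Numeric outcome vector of length `n`.
#' @param X Numeric exposure matrix (`n` x `l`), or a vector for a single
#'   exposure.
#' @param Z Numeric instrument matrix (`n` x `J`): genotype dosages coded
#'   0/1/2, allele scores, or any continuous instruments. A vector is treated
#'   as a single instrument.
#' @param include_intercept Include an intercept in every first and second
#'   stage (implemented by demeaning)? Default `TRUE`.
#'
#' @return An object of class `iv_data` with elements `y`, `X`, `Z`,
#'   `include_intercept`, and dimensions `n`, `l`, `J`.
#'
#' @details Validity requires `n > J >= l >= 1`, no missing values, no
#'   instrument column constant after centering, and full column rank of the
#'   (centered) instrument matrix.
#'
#' @examples
#' set.seed(1)
#' Z <- matrix(rbinom(300, 2, 0.3), 100, 3)
#' x <- 0.3 * rowSums(Z) + rnorm(100)
#' y <- 0.5 * x + rnorm(100)
#' d <- iv_data(y, x, Z)
#' d
#' @export
iv_data <- function(y, X, Z, include_intercept = TRUE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  storage.mode(X) <- "double"
  storage.mode(Z) <- "double"
  n <- length(y)
  if (nrow(X) != n || nrow(Z) != n)
    iv_error("y, X and Z must have the same number of rows", "weakivmr_data_error")
  if (anyNA(y) || anyNA(X) || anyNA(Z))
    iv_error("missing values are not allowed; filter complete cases first",
             "weakivmr_data_error")
  l <- ncol(X)
  J <- ncol(Z)
  if (l < 1L || J < l)
    iv_error("need J >= l >= 1 (at least as many instruments as exposures)",
             "weakivmr_data_error")
  if (n <= J)
    iv_error("need more observations than instruments (n > J)",
             "weakivmr_data_error")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(l))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(J))

  obj <- structure(
    list(y = y, X = X, Z = Z, include_intercept = isTRUE(include_intercept),
         n = n, l = l, J = J),
    class = "iv_data")
  obj$core <- iv_core(obj)
  obj
}

# Centered data, instrument QR and the cross products every estimator needs.
# Stored on the iv_data object so one decomposition is shared by all fits.
iv_core <- function(data) {
  if (!is.null(data$core)) return(data$core)
  center <- function(M) {
    if (data$include_intercept) sweep(M, 2L, colMeans(M)) else M
  }
  yc <- if (data$include_intercept) data$y - mean(data$y) else data$y
  Xc <- center(data$X)
  Zc <- center(data$Z)

  sdz <- sqrt(colSums(Zc^2))
  if (any(sdz < 1e-12 * sqrt(data$n)))
    iv_error("instrument column constant after centering", "weakivmr_degenerate")

  qz <- qr(Zc)
  if (qz$rank < data$J)
    iv_error("instrument matrix is rank deficient after intercept handling",
             "weakivmr_degenerate")

  W <- cbind(yc, Xc)                       # [y X], used by LIML and 2SLS alike
  Wh <- qr.fitted(qz, W)                   # P_Z W
  WPW <- crossprod(Wh, W)
  WPW <- (WPW + t(WPW)) / 2
  WtW <- crossprod(W)

  list(yc = yc, Xc = Xc, Zc = Zc, qz = qz,
       WPW = WPW, WtW = WtW,
       XPX = WPW[-1L, -1L, drop = FALSE],
       XPy = WPW[-1L, 1L],
       yPy = WPW[1L, 1L],
       XtX = WtW[-1L, -1L, drop = FALSE],
       Xty = WtW[-1L, 1L],
       yty = WtW[1L, 1L])
}

#' @export
print.iv_data <- function(x, ...) {
  cat(sprintf("<iv_data> n = %d, exposures = %d, instruments = %d, intercept = %s\n",
              x$n, x$l, x$J, x$include_intercept))
  invisible(x)
}

iv_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "weakivmr_error", "error")))
}

# residuals of an estimate on (possibly centered) data
iv_residuals <- function(result, data) {
  core <- iv_core(data)
  drop(core$yc - core$Xc %*% result$beta_hat)
}
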