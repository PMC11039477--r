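#' Multivariate multiple linear profile model
#'
#' Defines the in-control profile \eqn{Y_k = X B + E_k}, where each sampled
#' profile consists of \eqn{n} observations of \eqn{p} correlated responses
#' regressed on \eqn{q} explanatory variables, the error rows being i.i.d.
#' multivariate normal with covariance \code{Sigma}.  Parameters are assumed
#' known (Phase II monitoring with an established Phase-I model).
#'
#' @param B coefficient matrix, \code{(q+1) x p}; row 1 holds the intercepts.
#' @param Sigma error covariance matrix, \code{p x p}, symmetric positive
#'   definite.
#' @param designs named list of design matrices, one per allowed sample size.
#'   Each element must be an \code{n x (q+1)} matrix of full column rank whose
#'   first column is all ones; names are the sample sizes (coerced from the
#'   matrices' row counts if missing).
#' @param name optional scenario label used by print methods.
#'
#' @return An object of class \code{"profile_model"}: a list with elements
#'   \code{q}, \code{p}, \code{B}, \code{Sigma}, \code{designs}, \code{name}.
#' @examples
#' m <- profile_model(
#'   B = cbind(c(3, 2, 1), c(2, 1, 1)),
#'   Sigma = matrix(c(1, .5, .5, 1), 2),
#'   designs = list(matrix(c(1, 1, 1, 1, 2, 4, 6, 8, 1, 2, 3, 2), 4, 3))
#' )
#' m
#' @export
profile_model <- function(B, Sigma, designs = list(), name = NULL) {
  B <- as.matrix(B)
  Sigma <- as.matrix(Sigma)
  p <- ncol(B)
  q <- nrow(B) - 1L
  if (q < 1L) stop("B must have at least two rows (intercept + one slope)")
  if (nrow(Sigma) != p || ncol(Sigma) != p)
    stop("Sigma must be ", p, " x ", p, " to match the ", p, " responses of B")
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
    stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  designs <- lapply(designs, as.matrix)
  for (X in designs) {
    if (ncol(X) != q + 1L)
      stop("every design matrix must have q+1 = ", q + 1L, " columns")
    if (nrow(X) < q + 1L)
      stop("design matrices need n >= q+1 rows")
    if (any(X[, 1L] != 1))
      stop("the first column of every design matrix must be all ones")
    if (qr(X)$rank < q + 1L)
      stop("design matrices must have full column rank")
  }
  if (length(designs) && is.null(names(designs)))
    names(designs) <- vapply(designs, nrow, 0L)
  structure(
    list(q = q, p = p, B = B, Sigma = Sigma, designs = designs,
         name = name %||% "profile"),
    class = "profile_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.profile_model <- function(x, ...) {
  cat("Multivariate linear profile model \"", x$name, "\"\n", sep = "")
  cat("  responses p =", x$p, ", explanatory variables q =", x$q, "\n")
  cat("  sample sizes with stored designs:",
      if (length(x$designs)) paste(names(x$designs), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Specify a process shift
#'
#' A shift is an additive change to the coefficient matrix together with a
#' variance multiplier \eqn{\tau} applied elementwise to the error covariance
#' (\eqn{\Sigma \to \tau\Sigma}); \code{delta_B = 0} and \code{tau = 1} is the
#' in-control state.
#'
#' @param delta_B additive coefficient shift, \code{(q+1) x p} (a scalar 0 is
#'   recycled to the all-zero matrix when the model dimensions are known).
#' @param tau variance multiplier, strictly positive.
#' @param scale_by_sigma if \code{TRUE}, each column j of \code{delta_B} is
#'   interpreted in units of the response error standard deviation
#'   \eqn{\sigma_j} and rescaled when the shift is applied.  The simulation
#'   scenarios in this package have unit error variances, for which the two
#'   conventions coincide.
#' @return An object of class \code{"shift_spec"}.
#' @export
shift_spec <- function(delta_B = 0, tau = 1, scale_by_sigma = FALSE) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(delta_B = delta_B, tau = tau, scale_by_sigma = scale_by_sigma),
            class = "shift_spec")
}

## Resolve a shift against a model: full (q+1) x p delta matrix in raw units.
shift_delta <- function(shift, model) {
  d <- shift$delta_B
  if (is.null(d) || (length(d) == 1L && all(d == 0)))
    d <- matrix(0, model$q + 1L, model$p)
  d <- as.matrix(d)
  if (!all(dim(d) == c(model$q + 1L, model$p)))
    stop("delta_B must be ", model$q + 1L, " x ", model$p)
  if (isTRUE(shift$scale_by_sigma))
    d <- sweep(d, 2L, sqrt(diag(model$Sigma)), `*`)
  d
}

design_for <- function(model, n) {
  X <- model$designs[[as.character(n)]]
  if (is.null(X))
    stop("no design matrix stored for sample size ", n,
         " (available: ", paste(names(model$designs), collapse = ", "), ")")
  X
}

#' Simulate one profile sample
#'
#' Draws \eqn{Y = X(B + \Delta B) + E} with the rows of \eqn{E} independent
#' \eqn{N_p(0, \tau\Sigma)}.
#'
#' @param model a [profile_model()].
#' @param n sample-size key selecting the stored design matrix.
#' @param shift a [shift_spec()]; default in-control.
#' @param X optional explicit design matrix overriding the stored one.
#' @return An object of class \code{"profile_sample"}: list with the response
#'   matrix \code{Y} (\code{n x p}), the design \code{X}, \code{n} and
#'   \code{design_key}.
#' @export
simulate_sample <- function(model, n, shift = shift_spec(), X = NULL) {
  X <- if (is.null(X)) design_for(model, n) else as.matrix(X)
  n <- nrow(X)
  p <- model$p
  d <- shift_delta(shift, model)
  E <- matrix(stats::rnorm(n * p), n, p) %*% chol(model$Sigma) * sqrt(shift$tau)
  Y <- X %*% (model$B + d) + E
  structure(list(Y = Y, X = X, n = n, design_key = as.character(n)),
            class = "profile_sample")
}

#' Least-squares coefficient estimate for one sample
#'
#' Computes \eqn{\hat B_k = (X^T X)^{-1} X^T Y_k} and its response-major
#' vectorization \eqn{\hat\beta_k = (\hat\beta_{01},\dots,\hat\beta_{q1},
#' \dots,\hat\beta_{0p},\dots,\hat\beta_{qp})^T}.
#'
#' @param sample a \code{"profile_sample"} (or a list with \code{Y} and
#'   \code{X}).
#' @return Class \code{"beta_hat"}: list with \code{Bhat} (\code{(q+1) x p}),
#'   \code{beta_vec} (length \code{p(q+1)}), and the sample's \code{n} and
#'   \code{X} (carried along for the chart updates).
#' @export
estimate_coefficients <- function(sample) {
  X <- sample$X
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  Bhat <- stats::lm.fit(X, sample$Y)$coefficients
  Bhat <- as.matrix(Bhat)
  dimnames(Bhat) <- NULL
  structure(list(Bhat = Bhat, beta_vec = as.vector(Bhat),
                 n = nrow(X), X = X),
            class = "beta_hat")
}

#' Response-major vectorization of a coefficient matrix
#'
#' @param B a \code{(q+1) x p} coefficient matrix.
#' @return Numeric vector of length \code{p(q+1)} stacking the columns
#'   (responses) of \code{B}.
#' @seealso [unvec_coef()] for the inverse re-layout.
#' @export
vec_coef <- function(B) as.vector(as.matrix(B))

#' @rdname vec_coef
#' @param beta_vec a vector of length \code{p(q+1)}.
#' @param q,p profile dimensions.
#' @export
unvec_coef <- function(beta_vec, q, p) matrix(beta_vec, q + 1L, p)

#' Covariance of the vectorized coefficient estimator
#'
#' Under the in-control model the response-major \eqn{\hat\beta_k} has block
#' covariance with block \eqn{(g,h)} equal to \eqn{\sigma_{gh}(X^TX)^{-1}},
#' i.e. \eqn{\Sigma \otimes (X^TX)^{-1}}.
#'
#' @param model a [profile_model()].
#' @param n sample-size key.
#' @param X optional explicit design matrix.
#' @return A symmetric positive-definite \code{p(q+1) x p(q+1)} matrix.
#' @export
beta_covariance <- function(model, n, X = NULL) {
  X <- if (is.null(X)) design_for(model, n) else as.matrix(X)
  kronecker(model$Sigma, solve(crossprod(X)))
}

#' Residual summary of one sample against the in-control model
#'
#' Residuals are taken against the known in-control coefficients,
#' \eqn{e_{ik} = y_{ik} - x_i B}.  Returns the mean residual vector
#' \eqn{\bar e_k}, the pooled standardized residual sum
#' \eqn{f_k = \sum_i e_{ik}\Sigma^{-1}e_{ik}^T} and the variability statistic
#' \eqn{W_k}, which coincides with \eqn{f_k} when residuals are computed
#' against the true \eqn{B} (in-control, \eqn{W_k \sim \chi^2_{np}}).
#'
#' @inheritParams estimate_coefficients
#' @param model a [profile_model()].
#' @return Class \code{"residual_summary"}: list with \code{ebar} (length p),
#'   scalars \code{f} and \code{W}, and the sample's \code{n}.
#' @export
residual_summary <- function(sample, model) {
  E <- sample$Y - sample$X %*% model$B
  Sinv <- solve(model$Sigma)
  f <- sum((E %*% Sinv) * E)
  structure(list(ebar = colMeans(E), f = f, W = f, n = nrow(E)),
            class = "residual_summary")
}
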