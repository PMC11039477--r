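#' Chart configuration
#'
#' Tuning constants shared by the four memory-type charts.
#'
#' @param lam EWMA smoothing parameter \eqn{\lambda \in (0, 1]}; 0.2 is the
#'   conventional choice.
#' @param k1 CUSUM reference value (allowance) for the mean statistic of
#'   SS-CUSUMe.
#' @param k2 CUSUM reference value for the variability statistic of SS-CUSUMe.
#' @param tau_design design variance multiplier embedded in the Max-MCUSUM
#'   allowance \eqn{v = \log(\tau)\,\tau/(\tau-1)} (natural log); must exceed
#'   1.
#' @param beta_b out-of-control reference coefficient vector (length
#'   \code{p(q+1)}, response-major) for the Max-MCUSUM direction.  If
#'   \code{NULL}, it defaults at use time to the in-control vector plus one
#'   unit on every intercept.
#' @param clamp_eps probability clamp for the chi-square-to-normal quantile
#'   transform, keeping \eqn{\Phi^{-1}} finite at cumulative probabilities 0
#'   and 1.
#' @return An object of class \code{"chart_config"}.
#' @export
chart_config <- function(lam = 0.2, k1 = 1, k2 = 1.5, tau_design = 1.1,
                         beta_b = NULL, clamp_eps = 1e-12) {
  stopifnot(lam > 0, lam <= 1, k1 > 0, k2 > 0, tau_design > 1,
            clamp_eps > 0, clamp_eps < 0.5)
  structure(list(lam = lam, k1 = k1, k2 = k2, tau_design = tau_design,
                 beta_b = beta_b, clamp_eps = clamp_eps),
            class = "chart_config")
}

#' Chi-square to standard-normal probability integral transform
#'
#' Computes \eqn{\Phi^{-1}[H_{df}(x)]} with the cumulative probability clamped
#' to \code{[clamp_eps, 1 - clamp_eps]} so the result is finite for every
#' input.  If \eqn{x} is chi-square with \code{df} degrees of freedom the
#' output is standard normal.
#'
#' @param x nonnegative quantile(s).
#' @param df chi-square degrees of freedom.
#' @param clamp_eps clamp width, in (0, 0.5).
#' @return Numeric vector the length of \code{x}, always finite.
#' @export
normal_chisq_transform <- function(x, df, clamp_eps = 1e-12) {
  stats::qnorm(pmin(pmax(stats::pchisq(x, df), clamp_eps), 1 - clamp_eps))
}

chart_types <- c("max_mewma", "max_mcusum", "ss_ewmae", "ss_cusume")

#' Fresh chart state
#'
#' Every memory statistic starts at zero: the EWMA vectors/scalars of
#' Max-MEWMA (\eqn{z_0 = 0}, \eqn{g_0 = 0}) and SS-EWMAe
#' (\eqn{z_0 = 0, P_0 = 0, V_0 = 0}), and the CUSUM accumulators of
#' Max-MCUSUM (\eqn{U_0 = L_0 = 0}) and SS-CUSUMe
#' (\eqn{D_0^\pm = B_0^\pm = 0}; its internal residual EWMA also starts at
#' zero).
#'
#' @param chart one of \code{"max_mewma"}, \code{"max_mcusum"},
#'   \code{"ss_ewmae"}, \code{"ss_cusume"}.
#' @param model a [profile_model()] fixing the dimensions.
#' @return An object of class \code{"chart_state"}.
#' @export
chart_state <- function(chart = chart_types, model) {
  chart <- match.arg(chart)
  d <- model$p * (model$q + 1L)
  st <- switch(chart,
    max_mewma  = list(z = numeric(d), g = 0),
    max_mcusum = list(U = 0, L = 0),
    ss_ewmae   = list(z = numeric(model$p), P = 0, V = 0),
    ss_cusume  = list(z = numeric(model$p),
                      Dminus = 0, Dplus = 0, Bminus = 0, Bplus = 0)
  )
  structure(c(list(chart = chart, k = 0L), st), class = "chart_state")
}

resolve_beta_b <- function(cfg, model) {
  if (!is.null(cfg$beta_b)) return(cfg$beta_b)
  bb <- model$B
  bb[1L, ] <- bb[1L, ] + 1   # unit shift on every intercept
  as.vector(bb)
}

#' One Max-MEWMA update
#'
#' Applies the recursions
#' \eqn{z_k = \lambda(\hat\beta_k-\beta) + (1-\lambda)z_{k-1}},
#' \eqn{C_k = \Phi^{-1}[H_{(q+1)p}\{\frac{2-\lambda}{\lambda}
#' z_k^T\Sigma_{\hat\beta}^{-1}z_k\}]},
#' \eqn{g_k = (1-\lambda)g_{k-1} + \lambda\Phi^{-1}[H_{np}\{W_k\}]},
#' \eqn{S_k = \sqrt{(2-\lambda)/\lambda}\,g_k} and returns the plotting
#' statistic \eqn{ME_k = \max\{|C_k|, |S_k|\}}.
#'
#' @param state a \code{"chart_state"} of type \code{"max_mewma"}.
#' @param betahat an [estimate_coefficients()] result for the current sample.
#' @param rs a [residual_summary()] for the same sample (supplies \eqn{W_k}).
#' @param model a [profile_model()].
#' @param cfg a [chart_config()].
#' @return List with the advanced \code{state}, the plotting statistic
#'   \code{stat}, and components \code{mean_stat} (\eqn{C_k}) and
#'   \code{var_stat} (\eqn{S_k}).
#' @export
update_max_mewma <- function(state, betahat, rs, model, cfg = chart_config()) {
  stopifnot(state$chart == "max_mewma")
  lam <- cfg$lam
  dev <- betahat$beta_vec - vec_coef(model$B)
  Sbinv <- solve(beta_covariance(model, betahat$n, X = betahat$X))
  if (length(state$z) != length(dev))
    stop("state dimension does not match the coefficient vector")
  z <- lam * dev + (1 - lam) * state$z
  C <- normal_chisq_transform(
    (2 - lam) / lam * drop(z %*% Sbinv %*% z),
    df = length(z), clamp_eps = cfg$clamp_eps)
  g <- (1 - lam) * state$g +
    lam * normal_chisq_transform(rs$W, df = rs$n * model$p,
                                 clamp_eps = cfg$clamp_eps)
  S <- sqrt((2 - lam) / lam) * g
  state$z <- z; state$g <- g; state$k <- state$k + 1L
  list(state = state, stat = max(abs(C), abs(S)), mean_stat = C, var_stat = S)
}

#' One Max-MCUSUM update
#'
#' Mean track: \eqn{U_k = \max\{0, U_{k-1} + Z_k - 0.5D\}} with
#' \eqn{Z_k = a(\hat\beta_k-\beta_g)^T}, \eqn{a} the
#' \eqn{\Sigma_{\hat\beta}^{-1}}-normalized direction towards the
#' out-of-control reference \eqn{\beta_b} and \eqn{D} its length.
#' Variability track (as printed):
#' \eqn{L_k = \max\{0, L_{k-1} +
#' (\hat\beta_k-\beta_g)\Sigma_{\hat\beta}^{-1}(\hat\beta_k-\beta_g)^T - v\}}
#' with \eqn{v = \log(\tau)\,\tau/(\tau-1)} at the design \eqn{\tau}.
#' Plotting statistic \eqn{MC_k = \max\{U_k, L_k\}}.
#'
#' @inheritParams update_max_mewma
#' @return List with \code{state}, \code{stat}, \code{mean_stat}
#'   (\eqn{U_k}) and \code{var_stat} (\eqn{L_k}).
#' @export
update_max_mcusum <- function(state, betahat, model, cfg = chart_config()) {
  stopifnot(state$chart == "max_mcusum")
  beta_g <- vec_coef(model$B)
  beta_b <- resolve_beta_b(cfg, model)
  diff <- beta_b - beta_g
  if (all(diff == 0)) stop("beta_b must differ from the in-control beta")
  Sbinv <- solve(beta_covariance(model, betahat$n, X = betahat$X))
  D <- sqrt(drop(diff %*% Sbinv %*% diff))
  a <- drop(diff %*% Sbinv) / D
  dev <- betahat$beta_vec - beta_g
  Zk <- sum(a * dev)
  tau <- cfg$tau_design
  v <- log(tau) * tau / (tau - 1)
  U <- max(0, state$U + Zk - 0.5 * D)
  L <- max(0, state$L + drop(dev %*% Sbinv %*% dev) - v)
  state$U <- U; state$L <- L; state$k <- state$k + 1L
  list(state = state, stat = max(U, L), mean_stat = U, var_stat = L)
}

## T and F statistics shared by the SS-type charts; z is the *already
## advanced* EWMA of the mean residual vector.
ss_TF <- function(z, f, n, model, cfg) {
  lam <- cfg$lam
  zcov_inv <- solve(model$Sigma / n) * (2 - lam) / lam
  Tk <- normal_chisq_transform(drop(z %*% zcov_inv %*% z),
                               df = model$p, clamp_eps = cfg$clamp_eps)
  Fk <- normal_chisq_transform(f, df = n * model$p, clamp_eps = cfg$clamp_eps)
  c(Tk, Fk)
}

#' One SS-EWMAe update
#'
#' Residual EWMA \eqn{z_k = \lambda\bar e_k + (1-\lambda)z_{k-1}};
#' \eqn{T_k = \Phi^{-1}[H_p\{z_k^T[\frac{\lambda}{2-\lambda}\Sigma/n]^{-1}
#' z_k\}]} (the Mahalanobis distance of the EWMA'd mean residual under its
#' asymptotic in-control covariance); \eqn{P_k = \lambda T_k +
#' (1-\lambda)P_{k-1}}; \eqn{F_k = \Phi^{-1}[H_{np}\{f_k\}]};
#' \eqn{V_k = \lambda F_k + (1-\lambda)V_{k-1}}; plotting statistic
#' \eqn{EWe_k = P_k^2 + V_k^2}.
#'
#' @param state a \code{"chart_state"} of type \code{"ss_ewmae"}.
#' @param rs a [residual_summary()] for the current sample.
#' @inheritParams update_max_mewma
#' @return List with \code{state}, \code{stat}, \code{mean_stat}
#'   (\eqn{P_k}), \code{var_stat} (\eqn{V_k}) and the transformed inputs
#'   \code{T} and \code{F}.
#' @export
update_ss_ewmae <- function(state, rs, model, cfg = chart_config()) {
  stopifnot(state$chart == "ss_ewmae")
  lam <- cfg$lam
  z <- lam * rs$ebar + (1 - lam) * state$z
  TF <- ss_TF(z, rs$f, rs$n, model, cfg)
  P <- lam * TF[1L] + (1 - lam) * state$P
  V <- lam * TF[2L] + (1 - lam) * state$V
  state$z <- z; state$P <- P; state$V <- V; state$k <- state$k + 1L
  list(state = state, stat = P^2 + V^2, mean_stat = P, var_stat = V,
       T = TF[1L], F = TF[2L])
}

#' One SS-CUSUMe update from the transformed statistics
#'
#' Given the SS-EWMAe transformed statistics \eqn{T_k} and \eqn{F_k},
#' accumulates \eqn{D_k^\mp = \max\{0, \mp T_k - k_1 + D_{k-1}^\mp\}} and
#' \eqn{B_k^\mp = \max\{0, \mp F_k - k_2 + B_{k-1}^\mp\}}, forms
#' \eqn{M_k = \max\{D_k^-, D_k^+\}}, \eqn{N_k = \max\{B_k^-, B_k^+\}} and the
#' plotting statistic \eqn{CUe_k = M_k^2 + N_k^2}.
#'
#' Use [chart_update()] to drive this chart directly from samples (it
#' maintains the residual EWMA feeding \eqn{T_k}).
#'
#' @param state a \code{"chart_state"} of type \code{"ss_cusume"}.
#' @param T,F transformed mean and variability statistics for the current
#'   sample.
#' @param cfg a [chart_config()] supplying the reference values \code{k1},
#'   \code{k2}.
#' @return List with \code{state}, \code{stat}, \code{mean_stat}
#'   (\eqn{M_k}) and \code{var_stat} (\eqn{N_k}).
#' @export
update_ss_cusume <- function(state, T, F, cfg = chart_config()) {
  stopifnot(state$chart == "ss_cusume")
  state$Dminus <- max(0, -T - cfg$k1 + state$Dminus)
  state$Dplus  <- max(0,  T - cfg$k1 + state$Dplus)
  state$Bminus <- max(0, -F - cfg$k2 + state$Bminus)
  state$Bplus  <- max(0,  F - cfg$k2 + state$Bplus)
  M <- max(state$Dminus, state$Dplus)
  N <- max(state$Bminus, state$Bplus)
  state$k <- state$k + 1L
  list(state = state, stat = M^2 + N^2, mean_stat = M, var_stat = N)
}

#' Advance any chart state by one sample
#'
#' Convenience dispatcher: computes the coefficient estimate and residual
#' summary of \code{sample} and applies the update rule of the state's chart
#' type.  For SS-CUSUMe it also advances the internal residual EWMA that
#' feeds \eqn{T_k}.
#'
#' @param state a [chart_state()].
#' @param sample a \code{"profile_sample"}.
#' @inheritParams update_max_mewma
#' @return As the chart-specific update functions: list with \code{state},
#'   \code{stat}, \code{mean_stat}, \code{var_stat}.
#' @export
chart_update <- function(state, sample, model, cfg = chart_config()) {
  switch(state$chart,
    max_mewma = update_max_mewma(state, estimate_coefficients(sample),
                                 residual_summary(sample, model), model, cfg),
    max_mcusum = update_max_mcusum(state, estimate_coefficients(sample),
                                   model, cfg),
    ss_ewmae = update_ss_ewmae(state, residual_summary(sample, model),
                               model, cfg),
    ss_cusume = {
      rs <- residual_summary(sample, model)
      z <- cfg$lam * rs$ebar + (1 - cfg$lam) * state$z
      TF <- ss_TF(z, rs$f, rs$n, model, cfg)
      out <- update_ss_cusume(state, TF[1L], TF[2L], cfg)
      out$state$z <- z
      out
    }
  )
}
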