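#' Monte-Carlo calibration settings
#'
#' @param reps replications per evaluation (at least 100).
#' @param rl_cap truncation cap on simulated run lengths; defaults to
#'   \code{50 / alpha} at the point of use.  Truncated runs are counted at
#'   the cap and their number is reported.
#' @param tol relative tolerance on the achieved in-control ARL.
#' @param max_iter maximum number of ARL evaluations in the limit search.
#' @param seed base seed; every evaluation during a search reuses the same
#'   derived seed (common random numbers), so identical settings give
#'   identical limits.
#' @return An object of class \code{"calibration_settings"}.
#' @export
calibration_settings <- function(reps = 10000, rl_cap = NULL, tol = 0.02,
                                 max_iter = 40, seed = 1L) {
  stopifnot(reps >= 100, tol > 0, tol < 0.2)
  structure(list(reps = as.integer(reps), rl_cap = rl_cap, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "calibration_settings")
}

cap_for <- function(settings, alpha)
  as.integer(settings$rl_cap %||% ceiling(50 / alpha))

#' Initial control limit from first-update order statistics
#'
#' Generates \code{reps} in-control plotting statistics, each the first
#' update of a fresh chart state, sorts them increasingly and returns the
#' \eqn{\lceil reps\,(1-\alpha)\rceil}-th value — the starting point for the
#' ARL root search of [calibrate_ucl()].
#'
#' @param chart chart type (see [chart_state()]).
#' @param model a [profile_model()].
#' @param alpha Type-I error rate in (0, 1).
#' @param n sample-size key.
#' @param cfg a [chart_config()].
#' @param reps number of in-control statistics.
#' @param stats optional precomputed statistic values (used in tests); when
#'   supplied no simulation is performed.
#' @return The selected order statistic (a scalar).
#' @export
initial_ucl <- function(chart, model, alpha, n, cfg = chart_config(),
                        reps = 10000, stats = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(stats))
    stats <- first_update_stats(chart, model, n, cfg, reps)
  sort(stats)[ceiling(length(stats) * (1 - alpha))]
}

## In-control ARL at a given UCL, common random numbers via reseeding.
arl_at <- function(ucl, chart, model, n, cfg, reps, cap, seed) {
  set.seed(seed)
  r <- sim_rl_fp(chart, model, n, shift_spec(), ucl, cfg, reps, cap)
  structure(mean(r$rl), truncated = r$truncated)
}

#' Calibrate an upper control limit to a target in-control ARL
#'
#' Monotone bracketing/bisection search for the UCL at which the simulated
#' zero-state in-control ARL equals \eqn{1/\alpha}, started from
#' [initial_ucl()].  The in-control ARL is nondecreasing in the UCL; every
#' evaluation reuses the same random-number seed so the empirical ARL curve
#' seen by the search is (near) monotone as well.
#'
#' @inheritParams initial_ucl
#' @param settings a [calibration_settings()].
#' @return The calibrated UCL, with attributes \code{arl} (achieved
#'   in-control ARL), \code{sdrl}, \code{se} (Monte-Carlo standard error),
#'   \code{truncated}, \code{iterations} and \code{bracket}.
#' @export
calibrate_ucl <- function(chart, model, alpha, n, cfg = chart_config(),
                          settings = calibration_settings()) {
  target <- 1 / alpha
  cap <- cap_for(settings, alpha)
  reps <- settings$reps
  eval_seed <- settings$seed
  set.seed(eval_seed)
  u <- initial_ucl(chart, model, alpha, n, cfg, reps = reps)
  f <- function(u) arl_at(u, chart, model, n, cfg, reps, cap, eval_seed)
  iter <- 0L
  ev <- function(u) { iter <<- iter + 1L; f(u) }
  a <- b <- u
  fa <- fb <- ev(u)
  while (fb < target && iter < settings$max_iter) {
    a <- b; fa <- fb
    b <- b * 1.5
    fb <- ev(b)
  }
  while (fa > target && iter < settings$max_iter) {
    b <- a; fb <- fa
    a <- a / 1.5
    fa <- ev(a)
  }
  if (!(fa <= target && target <= fb))
    stop("failed to bracket the target ARL within max_iter; last bracket [",
         signif(a, 6), ", ", signif(b, 6), "] with ARL [",
         signif(fa, 4), ", ", signif(fb, 4), "]")
  best <- if (abs(fb - target) < abs(fa - target)) c(b, fb) else c(a, fa)
  repeat {
    if (abs(best[2L] - target) / target <= settings$tol ||
        iter >= settings$max_iter) break
    mid <- (a + b) / 2
    fm <- ev(mid)
    if (abs(fm - target) < abs(best[2L] - target)) best <- c(mid, fm)
    if (fm < target) { a <- mid; fa <- fm } else { b <- mid; fb <- fm }
  }
  set.seed(eval_seed + 1L)
  chk <- sim_rl_fp(chart, model, n, shift_spec(), best[1L], cfg, reps, cap)
  if (chk$truncated > 0.01 * reps)
    message("calibrate_ucl: ", chk$truncated, " of ", reps,
            " runs truncated at the cap")
  structure(best[1L], arl = mean(chk$rl), sdrl = stats::sd(chk$rl),
            se = stats::sd(chk$rl) / sqrt(reps), truncated = chk$truncated,
            iterations = iter, bracket = c(a, b))
}

#' Calibrate an upper warning limit to a target safe-zone probability
#'
#' Following the variable-sampling-interval view of the warning limit, the
#' chart is run in-control as an FP chart at its calibrated UCL (interval
#' switching does not alter the statistic stream when \code{n} is fixed);
#' the UWL is the \eqn{P_0} order-statistic quantile of the pooled
#' non-signal plotting statistics, so the in-control fraction of non-signal
#' samples in the safe zone matches \eqn{P_0}.  The in-control ARL and the
#' VSI time to signal (intervals \eqn{t_1}/\eqn{t_2} selected by the zone of
#' the preceding sample, first interval \eqn{t_1}) are re-verified and
#' reported as attributes.
#'
#' @inheritParams calibrate_ucl
#' @param UCL the control limit already calibrated for this
#'   \eqn{(\alpha, n)}.
#' @param design a [solve_vp_design()] result supplying \eqn{P_0},
#'   \eqn{t_1}, \eqn{t_2}.
#' @return The UWL (scalar \code{< UCL}) with attributes \code{p0_achieved},
#'   \code{arl}, \code{ats}, \code{ats_se}.
#' @export
calibrate_uwl <- function(chart, model, alpha, n, UCL, design,
                          cfg = chart_config(),
                          settings = calibration_settings()) {
  if (design$P0 <= 0 || design$P0 >= 1) stop("infeasible P0")
  cap <- cap_for(settings, alpha)
  set.seed(settings$seed + 2L)
  run <- sim_rl_fp(chart, model, n, shift_spec(), UCL, cfg,
                   settings$reps, cap, collect_stats = TRUE)
  pool <- sort(run$stats)
  UWL <- pool[ceiling(design$P0 * length(pool))]
  if (!(UWL < UCL)) UWL <- UCL * (1 - 1e-9)
  safe <- run$stats <= UWL
  ## VSI time to signal: first interval t1, then t1 after safe samples and
  ## t2 after warning samples.
  per_rep_safe <- tabulate(run$rep_id[safe], nbins = settings$reps)
  per_rep_tot <- tabulate(run$rep_id, nbins = settings$reps)
  ts <- design$t1 + design$t1 * per_rep_safe +
        design$t2 * (per_rep_tot - per_rep_safe)
  structure(UWL,
            p0_achieved = mean(safe),
            arl = mean(run$rl),
            ats = mean(ts), ats_se = stats::sd(ts) / sqrt(settings$reps))
}

#' Calibrate all four limits of a VP design
#'
#' Runs [calibrate_ucl()] for \eqn{(\alpha_1, n_1)} and
#' \eqn{(\alpha_2, n_2)} and [calibrate_uwl()] for each pair, returning the
#' design with \code{UCL1, UCL2, UWL1, UWL2} filled in.
#'
#' @inheritParams calibrate_ucl
#' @param design a [solve_vp_design()] result.
#' @return The design with limits set; attribute \code{calibration} holds
#'   the per-limit achieved ARLs and safe-zone fractions.
#' @export
calibrate_vp <- function(chart, model, design, cfg = chart_config(),
                         settings = calibration_settings()) {
  s1 <- settings; s2 <- settings; s2$seed <- settings$seed + 1000L
  UCL1 <- calibrate_ucl(chart, model, design$alpha1, design$n1, cfg, s1)
  UCL2 <- calibrate_ucl(chart, model, design$alpha2, design$n2, cfg, s2)
  UWL1 <- calibrate_uwl(chart, model, design$alpha1, design$n1, UCL1,
                        design, cfg, s1)
  UWL2 <- calibrate_uwl(chart, model, design$alpha2, design$n2, UCL2,
                        design, cfg, s2)
  out <- set_vp_limits(design, as.numeric(UCL1), as.numeric(UCL2),
                       as.numeric(UWL1), as.numeric(UWL2))
  attr(out, "calibration") <- list(
    arl1 = attr(UCL1, "arl"), arl2 = attr(UCL2, "arl"),
    p0_1 = attr(UWL1, "p0_achieved"), p0_2 = attr(UWL2, "p0_achieved"))
  out
}
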