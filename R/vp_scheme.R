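#' Solve the variable-parameters design constraints
#'
#' A VP scheme alternates between a relaxed setting \eqn{(n_1, t_1)} used
#' after safe-zone samples and a tightened setting \eqn{(n_2, t_2)} used
#' after warning-zone samples, tied to target expectations through
#' \deqn{E(n) = n_1 P_0 + n_2(1-P_0),\quad E(t) = t_1 P_0 + t_2(1-P_0),\quad
#' E(\alpha) = \alpha_1 P_0 + \alpha_2(1-P_0),}
#' where \eqn{P_0} is the in-control probability of the safe zone.  Given
#' \eqn{n_1 < n_2}, \eqn{E(n)}, \eqn{t_2}, \eqn{E(t)}, \eqn{\alpha_1} and
#' \eqn{E(\alpha)}, the derived parameters are
#' \eqn{P_0 = (E(n)-n_2)/(n_1-n_2)},
#' \eqn{t_1 = [E(t)(n_1-n_2) - t_2(n_1-E(n))]/(E(n)-n_2)} and
#' \eqn{\alpha_2 = [E(\alpha)(n_1-n_2) - \alpha_1(E(n)-n_2)]/(n_1-E(n))}.
#'
#' @param n1,n2 the two sample sizes, \code{n1 < n2}.
#' @param En target expected sample size, strictly between \code{n1} and
#'   \code{n2}.
#' @param t2 short sampling interval.
#' @param Et target expected sampling interval.
#' @param alpha1 small Type-I error rate (used with \code{n1}).
#' @param Ealpha target expected Type-I error rate.
#' @return An object of class \code{"vp_design"} holding the six free and
#'   three derived parameters; control/warning limits are unset until
#'   [set_vp_limits()] or [calibrate_vp()] fills them in.
#' @examples
#' solve_vp_design(4, 8, En = 6, t2 = 0.1, Et = 1,
#'                 alpha1 = 0.004, Ealpha = 0.005)
#' @export
solve_vp_design <- function(n1, n2, En, t2, Et, alpha1, Ealpha) {
  if (n1 >= n2) stop("need n1 < n2")
  if (En <= n1 || En >= n2) stop("E(n) must lie strictly between n1 and n2")
  if (Et <= t2) stop("need E(t) > t2, otherwise the derived t1 cannot exceed t2")
  P0 <- (En - n2) / (n1 - n2)
  t1 <- (Et * (n1 - n2) - t2 * (n1 - En)) / (En - n2)
  alpha2 <- (Ealpha * (n1 - n2) - alpha1 * (En - n2)) / (n1 - En)
  if (Et >= t2 && t1 <= t2)
    stop("derived t1 <= t2; increase E(t) or decrease t2")
  if (alpha2 <= alpha1 || alpha2 >= 1)
    stop("derived alpha2 = ", alpha2, " is infeasible (need alpha1 < alpha2 < 1)")
  structure(list(n1 = n1, n2 = n2, En = En, t1 = t1, t2 = t2, Et = Et,
                 alpha1 = alpha1, alpha2 = alpha2, Ealpha = Ealpha, P0 = P0,
                 UCL1 = NA_real_, UCL2 = NA_real_,
                 UWL1 = NA_real_, UWL2 = NA_real_),
            class = "vp_design")
}

#' Attach calibrated limits to a VP design
#'
#' @param design a [solve_vp_design()] result.
#' @param UCL1,UCL2 upper control limits for regions 1 and 2
#'   (\code{UCL2 < UCL1}).
#' @param UWL1,UWL2 upper warning limits (\code{UWL1 < UCL1},
#'   \code{UWL2 < UCL2}).
#' @return The design with limits set.
#' @export
set_vp_limits <- function(design, UCL1, UCL2, UWL1, UWL2) {
  if (!(UCL2 < UCL1)) stop("limits must satisfy UCL2 < UCL1")
  if (!(UWL1 < UCL1 && UWL2 < UCL2))
    stop("warning limits must satisfy UWL1 < UCL1 and UWL2 < UCL2")
  design$UCL1 <- UCL1; design$UCL2 <- UCL2
  design$UWL1 <- UWL1; design$UWL2 <- UWL2
  design
}

#' @export
print.vp_design <- function(x, ...) {
  cat("VP design: n =", x$n1, "/", x$n2,
      " t =", signif(x$t1, 4), "/", x$t2,
      " alpha =", x$alpha1, "/", signif(x$alpha2, 6),
      " P0 =", signif(x$P0, 6), "\n")
  cat("  targets E(n) =", x$En, " E(t) =", x$Et, " E(alpha) =", x$Ealpha, "\n")
  if (!is.na(x$UCL1))
    cat("  limits UCL =", signif(x$UCL1, 5), "/", signif(x$UCL2, 5),
        " UWL =", signif(x$UWL1, 5), "/", signif(x$UWL2, 5), "\n")
  else cat("  limits: not yet calibrated\n")
  invisible(x)
}

#' Classify a plotting statistic into a zone
#'
#' Safe zone \eqn{[0, UWL]}, warning zone \eqn{(UWL, UCL]}, signal
#' \eqn{(UCL, \infty)}; boundaries are inclusive exactly as written.
#'
#' @param stat nonnegative plotting statistic(s).
#' @param UWL,UCL warning and control limits, \code{0 <= UWL < UCL}.
#' @return Character vector in \code{c("safe", "warning", "signal")}.
#' @export
classify_zone <- function(stat, UWL, UCL) {
  if (!(UWL < UCL)) stop("need UWL < UCL")
  ifelse(stat > UCL, "signal", ifelse(stat > UWL, "warning", "safe"))
}

#' Parameters prescribed for the next sample
#'
#' Safe zone selects the relaxed region-1 setting \eqn{(n_1, t_1, UCL_1,
#' UWL_1)}; warning zone selects the tightened region-2 setting
#' \eqn{(n_2, t_2, UCL_2, UWL_2)}.  A signal has no next sample.
#'
#' @param zone \code{"safe"} or \code{"warning"}.
#' @param design a [vp_design] with limits set.
#' @return List with \code{n}, \code{t}, \code{UCL}, \code{UWL},
#'   \code{region}.
#' @export
next_parameters <- function(zone, design) {
  switch(zone,
    safe = list(n = design$n1, t = design$t1, UCL = design$UCL1,
                UWL = design$UWL1, region = 1L),
    warning = list(n = design$n2, t = design$t2, UCL = design$UCL2,
                   UWL = design$UWL2, region = 2L),
    signal = stop("the process signalled; there is no next sample"),
    stop("unknown zone: ", zone)
  )
}

#' Dual-track monitoring state for a VP scheme
#'
#' Memory statistics accumulated while sampling under region-1 parameters
#' must not feed updates performed under region-2 parameters (and vice
#' versa), so the scheme keeps two independent chart states.  Only the track
#' matching the current region is updated at each sample; the other is
#' frozen and resumes from its last value when its region is re-entered.
#' Monitoring starts relaxed (region 1) with both tracks at zero;
#' \code{start_region = "random"} instead draws the initial region with
#' safe-zone probability \eqn{P_0}.
#'
#' @param chart chart type, as in [chart_state()].
#' @param model a [profile_model()].
#' @param design a [vp_design] with limits set.
#' @param start_region \code{"region1"} (default) or \code{"random"}.
#' @return An object of class \code{"dual_track_state"}.
#' @export
dual_track_state <- function(chart, model, design,
                             start_region = c("region1", "random")) {
  start_region <- match.arg(start_region)
  region <- if (start_region == "region1") 1L
            else if (stats::runif(1) < design$P0) 1L else 2L
  structure(list(track1 = chart_state(chart, model),
                 track2 = chart_state(chart, model),
                 chart = chart, current_region = region,
                 elapsed_time = 0, samples_taken = 0L),
            class = "dual_track_state")
}

#' One VP monitoring step
#'
#' Takes the sample prescribed for the current region, advances only the
#' active track, accounts the sampling interval that preceded the sample,
#' and classifies the resulting statistic against the active region's
#' limits.  The inactive track is untouched.
#'
#' @param state a [dual_track_state()].
#' @param sample a \code{"profile_sample"} whose size matches the current
#'   region's prescribed sample size.
#' @param design a [vp_design] with limits set.
#' @param model a [profile_model()].
#' @param cfg a [chart_config()].
#' @return List with the advanced \code{state}, the plotting statistic
#'   \code{stat}, the \code{zone} of this sample, and the \code{region} it
#'   was taken under.
#' @export
step_dual <- function(state, sample, design, model, cfg = chart_config()) {
  r <- state$current_region
  n_need <- if (r == 1L) design$n1 else design$n2
  if (sample$n != n_need)
    stop("sample size ", sample$n, " does not match region ", r,
         " (expected n = ", n_need, ")")
  t_r <- if (r == 1L) design$t1 else design$t2
  UCL <- if (r == 1L) design$UCL1 else design$UCL2
  UWL <- if (r == 1L) design$UWL1 else design$UWL2
  track <- if (r == 1L) state$track1 else state$track2
  upd <- chart_update(track, sample, model, cfg)
  if (r == 1L) state$track1 <- upd$state else state$track2 <- upd$state
  state$elapsed_time <- state$elapsed_time + t_r
  state$samples_taken <- state$samples_taken + 1L
  zone <- classify_zone(upd$stat, UWL, UCL)
  if (zone != "signal")
    state$current_region <- next_parameters(zone, design)$region
  list(state = state, stat = upd$stat, zone = zone, region = r,
       mean_stat = upd$mean_stat, var_stat = upd$var_stat)
}
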