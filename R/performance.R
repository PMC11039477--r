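#' Summarize simulated run lengths and times to signal
#'
#' @param rl vector of run lengths (samples to signal).
#' @param ts vector of times to signal, same length.
#' @param truncated number of runs truncated at the cap (already counted at
#'   the cap in \code{rl}/\code{ts}).
#' @return An object of class \code{"perf_summary"} with \code{ARL},
#'   \code{SDRL}, \code{ATS}, \code{SDTS}, \code{reps}, Monte-Carlo standard
#'   errors \code{mc_se_arl}, \code{mc_se_ats}, and \code{truncated}.
#' @export
summarize_runs <- function(rl, ts = rl, truncated = 0L) {
  if (!length(rl)) stop("no run lengths to summarize")
  if (any(rl <= 0) || any(ts <= 0)) stop("run lengths and times must be positive")
  reps <- length(rl)
  structure(list(ARL = mean(rl), SDRL = stats::sd(rl),
                 ATS = mean(ts), SDTS = stats::sd(ts),
                 reps = reps,
                 mc_se_arl = stats::sd(rl) / sqrt(reps),
                 mc_se_ats = stats::sd(ts) / sqrt(reps),
                 truncated = truncated),
            class = "perf_summary")
}

#' @export
print.perf_summary <- function(x, ...) {
  cat(sprintf("ATS %.4g (SDTS %.4g)   ARL %.4g (SDRL %.4g)\n",
              x$ATS, x$SDTS, x$ARL, x$SDRL))
  cat(sprintf("  %d replications; MC SE: ATS %.3g, ARL %.3g; truncated %d\n",
              x$reps, x$mc_se_ats, x$mc_se_arl, x$truncated))
  invisible(x)
}

#' Zero-state run-length performance of an FP chart
#'
#' Simulates replicated monitoring runs: the chart state is reset, the shift
#' is present from the first sample, and samples of size \code{n} are drawn
#' every \code{t} time units until the plotting statistic exceeds
#' \code{UCL} (or the run is truncated at the cap).  For an FP scheme
#' \eqn{ATS = t \times ARL} and \eqn{SDTS = t \times SDRL} exactly.
#'
#' @param chart chart type (see [chart_state()]).
#' @param model a [profile_model()].
#' @param shift a [shift_spec()].
#' @param UCL calibrated upper control limit.
#' @param n sample-size key.
#' @param t fixed sampling interval.
#' @param cfg a [chart_config()].
#' @param settings a [calibration_settings()] (supplies \code{reps},
#'   \code{rl_cap}, \code{seed}).
#' @param alpha nominal Type-I error used only to default the run cap to
#'   \code{50/alpha}.
#' @return A [summarize_runs()] object.
#' @export
run_length_fp <- function(chart, model, shift, UCL, n, t = 1,
                          cfg = chart_config(),
                          settings = calibration_settings(),
                          alpha = 0.005) {
  cap <- cap_for(settings, alpha)
  set.seed(settings$seed)
  r <- sim_rl_fp(chart, model, n, shift, UCL, cfg, settings$reps, cap)
  if (r$truncated > 0.01 * settings$reps)
    warning(r$truncated, " of ", settings$reps, " runs truncated at the cap")
  summarize_runs(r$rl, t * r$rl, truncated = r$truncated)
}

#' Zero-state run-length performance of a VP chart
#'
#' Each replication resets both memory tracks to zero, then repeatedly:
#' elapses the interval prescribed by the previous sample's zone, draws a
#' sample of the prescribed size under the shift, updates the active track,
#' and classifies the statistic, until a signal or the cap.  RL counts
#' samples, TS accumulates intervals; they differ because the intervals
#' vary.
#'
#' By default the initial region of each replication is drawn with the
#' in-control safe-zone probability \eqn{P_0} (so the first sample's
#' parameters reflect the scheme's stationary region occupancy at the
#' moment the shift arrives); \code{start_region = "region1"} instead
#' starts every run relaxed, which is also how [monitor_stream()] begins a
#' fresh monitoring session.  See the methods vignette for why performance
#' profiles use the randomized start.
#'
#' @inheritParams run_length_fp
#' @param design a fully calibrated [vp_design].
#' @param start_region \code{"random"} (default) or \code{"region1"}.
#' @return A [summarize_runs()] object; attribute \code{occupancy} reports
#'   the realized mean sample size, mean interval and safe-zone fraction.
#' @export
run_length_vp <- function(chart, model, shift, design,
                          cfg = chart_config(),
                          settings = calibration_settings(),
                          alpha = NULL,
                          start_region = c("random", "region1")) {
  if (anyNA(c(design$UCL1, design$UCL2, design$UWL1, design$UWL2)))
    stop("design limits are not calibrated; run calibrate_vp() first")
  start_region <- match.arg(start_region)
  cap <- cap_for(settings, alpha %||% design$Ealpha)
  set.seed(settings$seed)
  r <- sim_rl_vp(chart, model, design, shift, cfg, settings$reps, cap,
                 start_region = start_region)
  if (r$truncated > 0.01 * settings$reps)
    warning(r$truncated, " of ", settings$reps, " runs truncated at the cap")
  out <- summarize_runs(r$rl, r$ts, truncated = r$truncated)
  attr(out, "occupancy") <- r$occupancy
  out
}
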