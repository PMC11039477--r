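## Phase-II sample streams: synthetic generation, CSV round-trip, and the
## monitoring runner that turns a stream into a decision table.

draw_covariates <- function(spec, n) {
  cols <- lapply(spec, function(v) {
    x <- switch(v$dist,
      normal = stats::rnorm(n, v$mean, v$sd),
      bernoulli = stats::rbinom(n, 1L, v$prob),
      gamma = stats::rgamma(n, shape = v$shape, scale = v$scale),
      stop("unknown covariate distribution: ", v$dist))
    if (!is.null(v$min)) x <- pmax(x, v$min)
    if (!is.null(v$max)) x <- pmin(x, v$max)
    x
  })
  do.call(cbind, cols)
}

#' Generate a synthetic Phase-II sample stream
#'
#' Draws one profile sample per entry of \code{ns} from the scenario's
#' model, optionally under per-sample shifts, and returns (and optionally
#' writes) a long-format stream: one row per observation with columns
#' \code{sample_id}, \code{x1..xq}, \code{y1..yp}.  Covariates come from the
#' scenario's stored design matrix for the requested sample size or, when
#' the scenario declares covariate distributions (as the stroke fixture
#' does), are drawn afresh for every sample.  For scenarios whose responses
#' live on the base-10 log scale, convenience back-transformed columns
#' \code{y1_orig..} are appended.
#'
#' @param scenario a [load_scenario()] result.
#' @param ns integer vector of sample sizes, one per sample.
#' @param shifts \code{NULL} (in-control), one [shift_spec()] applied to all
#'   samples, or a list of shift specs of length \code{length(ns)}.
#' @param file optional CSV path to write.
#' @param seed optional seed; identical seeds give identical streams.
#' @return The stream as a data frame (invisibly when \code{file} is given).
#' @export
generate_phase2_stream <- function(scenario, ns, shifts = NULL, file = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- scenario$model
  if (inherits(shifts, "shift_spec")) shifts <- rep(list(shifts), length(ns))
  if (!is.null(shifts) && length(shifts) != length(ns))
    stop("shifts must be NULL, one shift_spec, or one per sample")
  rows <- vector("list", length(ns))
  for (k in seq_along(ns)) {
    n <- ns[k]
    sh <- if (is.null(shifts)) shift_spec() else shifts[[k]]
    X <- if (!is.null(scenario$covariates))
      cbind(1, draw_covariates(scenario$covariates, n))
    else design_for(model, n)
    smp <- simulate_sample(model, n, sh, X = X)
    df <- data.frame(sample_id = k, X[, -1L, drop = FALSE],
                     smp$Y, check.names = FALSE)
    names(df) <- c("sample_id", paste0("x", seq_len(model$q)),
                   paste0("y", seq_len(model$p)))
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  if (identical(scenario$response_scale, "log10"))
    for (j in seq_len(model$p))
      out[[paste0("y", j, "_orig")]] <- 10^out[[paste0("y", j)]]
  rownames(out) <- NULL
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a Phase-II sample stream from CSV
#'
#' @param file CSV with columns \code{sample_id}, \code{x1..xq},
#'   \code{y1..yp}, observations grouped by \code{sample_id}.
#' @return A data frame.
#' @export
read_sample_stream <- function(file) utils::read.csv(file)

split_stream <- function(stream, q, p) {
  xcols <- paste0("x", seq_len(q))
  ycols <- paste0("y", seq_len(p))
  miss <- setdiff(c("sample_id", xcols, ycols), names(stream))
  if (length(miss))
    stop("stream is missing columns: ", paste(miss, collapse = ", "))
  ids <- unique(stream$sample_id)
  lapply(ids, function(id) {
    g <- stream[stream$sample_id == id, , drop = FALSE]
    structure(list(Y = as.matrix(g[, ycols, drop = FALSE]),
                   X = cbind(1, as.matrix(g[, xcols, drop = FALSE])),
                   n = nrow(g), design_key = as.character(nrow(g))),
              class = "profile_sample")
  })
}

#' Run Phase-II monitoring over a sample stream
#'
#' Applies an FP or VP scheme sample by sample, producing one decision
#' record per sample: sample number, sample size and its running sum,
#' sampling interval and cumulative time, per-response sample means, the
#' mean and variability components, the plotting statistic, the limits in
#' force, and the in-/out-of-control status (out-of-control iff the
#' statistic exceeds the active UCL; a statistic exactly at the UCL is
#' in-control, in the warning zone).
#'
#' For a VP scheme the runner prescribes the sample size of each step from
#' the previous sample's zone; a stream sample of the wrong size is an
#' error.
#'
#' @param stream a stream data frame (see [read_sample_stream()]) or a CSV
#'   path.
#' @param scenario a [load_scenario()] result (supplies model and chart
#'   config).
#' @param chart chart type (see [chart_state()]).
#' @param scheme either a fully calibrated [vp_design], or a list
#'   \code{list(n =, t =, UCL =, UWL = NULL)} describing an FP scheme (an
#'   FP chart has no warning limit; one may still be supplied for display).
#' @param on_signal \code{"stop"} (default) ends monitoring at the first
#'   signal; \code{"continue"} records it, resets all memory statistics and
#'   carries on.
#' @return A data frame of class \code{"vp_monitor"} with one row per
#'   monitored sample.
#' @export
monitor_stream <- function(stream, scenario, chart, scheme,
                           on_signal = c("stop", "continue")) {
  on_signal <- match.arg(on_signal)
  if (is.character(stream)) stream <- read_sample_stream(stream)
  model <- scenario$model
  cfg <- scenario$cfg
  samples <- split_stream(stream, model$q, model$p)
  vp <- inherits(scheme, "vp_design")
  if (vp && anyNA(c(scheme$UCL1, scheme$UCL2, scheme$UWL1, scheme$UWL2)))
    stop("VP scheme limits are missing; run calibrate_vp() first")
  if (!vp && is.null(scheme$UCL)) stop("FP scheme needs a UCL")
  state <- if (vp) dual_track_state(chart, model, scheme)
           else chart_state(chart, model)
  recs <- vector("list", length(samples))
  cum_n <- 0L; cum_t <- 0
  for (k in seq_along(samples)) {
    smp <- samples[[k]]
    if (vp) {
      res <- step_dual(state, smp, scheme, model, cfg)
      state <- res$state
      region <- res$region
      t_k <- if (region == 1L) scheme$t1 else scheme$t2
      UCL <- if (region == 1L) scheme$UCL1 else scheme$UCL2
      UWL <- if (region == 1L) scheme$UWL1 else scheme$UWL2
      stat <- res$stat; mean_stat <- res$mean_stat; var_stat <- res$var_stat
      signal <- res$zone == "signal"
    } else {
      if (smp$n != scheme$n)
        stop("sample ", k, " has n = ", smp$n,
             " but the FP scheme prescribes n = ", scheme$n)
      res <- chart_update(state, smp, model, cfg)
      state <- res$state
      region <- NA_integer_
      t_k <- scheme$t
      UCL <- scheme$UCL; UWL <- scheme$UWL %||% NA_real_
      stat <- res$stat; mean_stat <- res$mean_stat; var_stat <- res$var_stat
      signal <- stat > UCL
    }
    cum_n <- cum_n + smp$n; cum_t <- cum_t + t_k
    ybar <- colMeans(smp$Y)
    rec <- data.frame(k = k, n_k = smp$n, cum_n = cum_n, t_k = t_k,
                      cum_t = cum_t)
    for (j in seq_len(model$p)) rec[[paste0("ybar", j)]] <- ybar[j]
    rec$mean_stat <- mean_stat
    rec$var_stat <- var_stat
    rec$stat <- stat
    rec$UWL_k <- UWL
    rec$UCL_k <- UCL
    rec$region <- region
    rec$status <- if (signal) "out-of-control" else "in-control"
    recs[[k]] <- rec
    if (signal) {
      if (on_signal == "stop") { recs <- recs[seq_len(k)]; break }
      state <- if (vp) dual_track_state(chart, model, scheme)
               else chart_state(chart, model)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("vp_monitor", "data.frame")
  attr(out, "chart") <- chart
  attr(out, "scheme") <- if (vp) "vp" else "fp"
  out
}

#' @export
print.vp_monitor <- function(x, digits = 4, ...) {
  cat("Phase-II monitoring (", attr(x, "chart"), ", ",
      toupper(attr(x, "scheme")), " scheme): ", nrow(x), " samples, ",
      sum(x$status == "out-of-control"), " signal(s)\n", sep = "")
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

#' Plot a monitoring record table as a control chart
#'
#' Plots the final statistic against the sample number with the control
#' (and, for VP schemes, warning) limits in force at each sample drawn as
#' step lines; signalling samples are highlighted.
#'
#' @param x a [monitor_stream()] result.
#' @param ... further arguments passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.vp_monitor <- function(x, ...) {
  ylim <- range(0, x$stat, x$UCL_k, x$UWL_k, na.rm = TRUE)
  graphics::plot(x$k, x$stat, type = "b", pch = 19, ylim = ylim,
                 xlab = "sample k", ylab = "plotting statistic",
                 main = paste0(attr(x, "chart"), " (",
                               toupper(attr(x, "scheme")), ")"), ...)
  graphics::lines(x$k, x$UCL_k, type = "s", lty = 1, col = "red3")
  if (!all(is.na(x$UWL_k)))
    graphics::lines(x$k, x$UWL_k, type = "s", lty = 2, col = "orange3")
  bad <- x$status == "out-of-control"
  if (any(bad))
    graphics::points(x$k[bad], x$stat[bad], pch = 19, col = "red3",
                     cex = 1.3)
  invisible(x)
}
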