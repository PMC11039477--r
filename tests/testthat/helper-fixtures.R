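## Shared fixtures and memoized Monte-Carlo calibrations (computed once per
## test run; several test files reuse them).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

p2_scenario <- function() memo("p2", load_scenario("p2_sim"))

p2_design <- function() {
  sc <- p2_scenario()
  do.call(solve_vp_design, sc$design)
}

## FP Max-MEWMA control limit for the reference scenario (alpha 0.005, n 4).
p2_mewma_ucl <- function() memo("mewma_ucl", {
  sc <- p2_scenario()
  calibrate_ucl("max_mewma", sc$model, 0.005, 4, sc$cfg,
                calibration_settings(reps = 8000, tol = 0.005, seed = 101L))
})

## FP control limits for the other charts (smoke-scale replications).
p2_fp_ucl <- function(chart) memo(paste0("ucl_", chart), {
  sc <- p2_scenario()
  calibrate_ucl(chart, sc$model, 0.005, 4, sc$cfg,
                calibration_settings(reps = 4000, tol = 0.005, seed = 101L))
})

## Fully calibrated VP Max-MEWMA design.
p2_vp_calibrated <- function() memo("vp_design", {
  sc <- p2_scenario()
  calibrate_vp("max_mewma", sc$model, p2_design(), sc$cfg,
               calibration_settings(reps = 5000, tol = 0.005, seed = 202L))
})

## A degenerate VP design that should behave exactly like an FP chart.
degenerate_design <- function(n = 4, t = 1, UCL = 2.5) {
  structure(list(n1 = n, n2 = n, En = n, t1 = t, t2 = t, Et = t,
                 alpha1 = 0.01, alpha2 = 0.01, Ealpha = 0.01, P0 = 0.5,
                 UCL1 = UCL, UCL2 = UCL,
                 UWL1 = UCL * (1 - 1e-12), UWL2 = UCL * (1 - 1e-12)),
            class = "vp_design")
}

## Run one chart manually over a list of samples, collecting statistics.
replay_chart <- function(chart, samples, model, cfg) {
  st <- chart_state(chart, model)
  vapply(samples, function(s) {
    u <- chart_update(st, s, model, cfg)
    st <<- u$state
    u$stat
  }, 0)
}
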