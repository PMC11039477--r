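test_that("packaged scenarios carry the published parameters", {
  p2 <- load_scenario("p2_sim")
  expect_equal(p2$model$B, cbind(c(3, 2, 1), c(2, 1, 1)))
  expect_equal(p2$model$Sigma, matrix(c(1, .5, .5, 1), 2))
  expect_equal(p2$model$designs[["4"]][, 2], c(2, 4, 6, 8))
  expect_equal(nrow(p2$model$designs[["8"]]), 8)

  stroke <- load_scenario("stroke")
  expect_equal(stroke$model$Sigma[1, 2], 0.0207)
  expect_equal(stroke$model$B[1, ], c(2.0457, 1.6797))
  expect_equal(stroke$model$B[4, ], c(-0.0045, -0.0032))
  expect_identical(stroke$response_scale, "log10")
  expect_length(stroke$model$designs, 0)

  p6 <- load_scenario("p6_sim")
  expect_equal(dim(p6$model$B), c(7L, 6L))
  expect_equal(p6$model$B[3, 2], 21.01)
  expect_length(p6$model$designs, 0)   # design matrices must be user-supplied
  expect_match(p6$notes, "SYNTHETIC")

  expect_error(load_scenario("nope"), "available fixtures")
})

test_that("scenario files round-trip through YAML", {
  p2 <- load_scenario("p2_sim")
  f <- tempfile(fileext = ".yaml")
  write_scenario(p2, f)
  back <- read_scenario(f)
  expect_equal(back$model$B, p2$model$B)
  expect_equal(back$model$Sigma, p2$model$Sigma)
  expect_equal(back$model$designs[["8"]], p2$model$designs[["8"]])
  expect_equal(back$cfg$lam, p2$cfg$lam)
  unlink(f)
})

test_that("stream generation is reproducible and respects the schedule", {
  p2 <- load_scenario("p2_sim")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  generate_phase2_stream(p2, ns = c(4, 8, 4), file = f1, seed = 99)
  generate_phase2_stream(p2, ns = c(4, 8, 4), file = f2, seed = 99)
  expect_identical(readLines(f1), readLines(f2))
  stream <- read_sample_stream(f1)
  expect_equal(as.vector(table(stream$sample_id)), c(4, 8, 4))
  expect_named(stream, c("sample_id", "x1", "x2", "y1", "y2"))
  ## fixed-design covariates come from the stored X
  expect_equal(stream$x1[stream$sample_id == 1], c(2, 4, 6, 8))
  unlink(c(f1, f2))

  ## stroke covariates are drawn from the documented distributions
  stroke <- load_scenario("stroke")
  st <- generate_phase2_stream(stroke, ns = rep(4, 50), seed = 1)
  expect_true(all(st$x1 >= 18 & st$x1 <= 100))
  expect_true(all(st$x2 %in% c(0, 1)))
  expect_true(all(st$x3 >= 0 & st$x3 <= 42))
  expect_equal(st$y1_orig, 10^st$y1)
})

test_that("the FP monitor reproduces the decision-table contract", {
  sc <- load_scenario("p2_sim")
  stream <- generate_phase2_stream(sc, ns = rep(4, 40),
                                   shifts = shift_spec(0, 2.5), seed = 7)
  rec <- monitor_stream(stream, sc, "max_mewma",
                        scheme = list(n = 4, t = 1, UCL = 2.8))
  ## out-of-control iff the statistic exceeds the active control limit
  expect_identical(rec$status == "out-of-control", rec$stat > rec$UCL_k)
  ## table conservation: cumulative columns are running sums
  expect_equal(rec$cum_n, cumsum(rec$n_k))
  expect_equal(rec$cum_t, cumsum(rec$t_k))
  ## the FP runner never varies n or t
  expect_true(all(rec$n_k == 4) && all(rec$t_k == 1))
  ## stop-at-first-signal leaves exactly one signalling row, at the end
  expect_identical(which(rec$status == "out-of-control"), nrow(rec))
  ## replaying the recorded stream reproduces the table exactly
  rec2 <- monitor_stream(stream, sc, "max_mewma",
                         scheme = list(n = 4, t = 1, UCL = 2.8))
  expect_identical(rec, rec2)
  ## a statistic exactly at the UCL is still in-control (warning zone)
  rec3 <- monitor_stream(stream[stream$sample_id == 1, ], sc, "max_mewma",
                         scheme = list(n = 4, t = 1, UCL = rec$stat[1]))
  expect_identical(rec3$status, "in-control")
})

test_that("the VP monitor follows the zone state machine", {
  sc <- load_scenario("p2_sim")
  d <- set_vp_limits(do.call(solve_vp_design, sc$design),
                     UCL1 = 3.02, UCL2 = 2.88, UWL1 = 1.015, UWL2 = 1.027)
  ## build a stream that always matches the prescribed sizes by generating
  ## sample by sample with the runner's own state machine
  set.seed(41)
  state <- dual_track_state("max_mewma", sc$model, d)
  rows <- list(); k <- 0
  while (k < 30) {
    k <- k + 1
    n_k <- if (state$current_region == 1L) d$n1 else d$n2
    s <- simulate_sample(sc$model, n_k, shift_spec(0, 1.6))
    X <- s$X
    df <- data.frame(sample_id = k, x1 = X[, 2], x2 = X[, 3],
                     y1 = s$Y[, 1], y2 = s$Y[, 2])
    rows[[k]] <- df
    res <- step_dual(state, s, d, sc$model, sc$cfg)
    state <- res$state
    if (res$zone == "signal") break
  }
  stream <- do.call(rbind, rows)
  rec <- monitor_stream(stream, sc, "max_mewma", scheme = d)
  expect_equal(nrow(rec), k)
  ## sample sizes/intervals switch only according to the previous zone
  prev_safe <- head(rec$stat <= rec$UWL_k, -1)
  expect_equal(rec$n_k[-1], ifelse(prev_safe, d$n1, d$n2))
  expect_equal(rec$t_k[-1], ifelse(prev_safe, d$t1, d$t2))
  expect_equal(rec$n_k[1], d$n1)       # fresh sessions start relaxed
  ## a sample whose size matches neither region's prescription is an error
  first <- stream[stream$sample_id == 1, ]
  bad <- first[1:3, ]; bad$sample_id <- 2
  expect_error(monitor_stream(rbind(first, bad), sc, "max_mewma",
                              scheme = d), "does not match")
})

test_that("in-control false alarms occur at roughly the design rate", {
  sc <- load_scenario("p2_sim")
  ucl <- as.numeric(p2_fp_ucl("max_mewma"))
  stream <- generate_phase2_stream(sc, ns = rep(4, 1500), seed = 55)
  rec <- monitor_stream(stream, sc, "max_mewma",
                        scheme = list(n = 4, t = 1, UCL = ucl),
                        on_signal = "continue")
  n_sig <- sum(rec$status == "out-of-control")
  ## 1500 samples at ARL 200: expect ~7.5 alarm episodes; wide Poisson band
  expect_gte(n_sig, 1)
  expect_lte(n_sig, 20)
})

test_that("a shift injected mid-stream is never anticipated", {
  sc <- load_scenario("p2_sim")
  shifts <- c(rep(list(shift_spec()), 50),
              rep(list(shift_spec(rbind(c(2, 2), 0, 0))), 30))
  ks <- vapply(1:5, function(i) {
    stream <- generate_phase2_stream(sc, ns = rep(4, 80), shifts = shifts,
                                     seed = 100 + i)
    rec <- monitor_stream(stream, sc, "max_mewma",
                          scheme = list(n = 4, t = 1, UCL = 3.2))
    if (any(rec$status == "out-of-control")) max(rec$k) else NA_real_
  }, 0)
  expect_true(all(is.na(ks) | ks > 50))
  expect_true(any(!is.na(ks)))         # the large shift is in fact caught
})
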