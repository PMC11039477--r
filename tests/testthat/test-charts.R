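cfg <- chart_config()

make_betahat <- function(model, beta_vec, n = 4) {
  structure(list(Bhat = unvec_coef(beta_vec, model$q, model$p),
                 beta_vec = beta_vec, n = n,
                 X = model$designs[[as.character(n)]]),
            class = "beta_hat")
}
make_rs <- function(ebar, f, n = 4) {
  structure(list(ebar = ebar, f = f, W = f, n = n),
            class = "residual_summary")
}

test_that("the chi-square-to-normal transform is a proper PIT", {
  expect_equal(normal_chisq_transform(qchisq(0.5, 8), 8), 0, tolerance = 1e-12)
  expect_equal(normal_chisq_transform(0, 8), qnorm(1e-12))
  expect_true(is.finite(normal_chisq_transform(1e6, 8)))
  set.seed(2)
  z <- normal_chisq_transform(rchisq(1e4, 8), 8)
  ks <- stats::ks.test(z, stats::pnorm)
  expect_gt(ks$p.value, 0.01)
})

test_that("Max-MEWMA updates follow the printed recursions", {
  m <- p2_scenario()$model
  beta0 <- vec_coef(m$B)

  ## beta-hat at target, W at its median: C is the clamped floor, S = 0
  st <- chart_state("max_mewma", m)
  u <- update_max_mewma(st, make_betahat(m, beta0),
                        make_rs(c(0, 0), qchisq(0.5, 8)), m, cfg)
  expect_equal(u$mean_stat, qnorm(1e-12))
  expect_equal(u$var_stat, 0)
  expect_equal(u$stat, abs(qnorm(1e-12)))

  ## C is monotone in the Mahalanobis size of the deviation
  set.seed(4)
  for (i in 1:10) {
    dev <- rnorm(6, sd = 0.3)
    rs <- make_rs(c(0, 0), 8)
    u1 <- update_max_mewma(chart_state("max_mewma", m),
                           make_betahat(m, beta0 + dev), rs, m, cfg)
    u2 <- update_max_mewma(chart_state("max_mewma", m),
                           make_betahat(m, beta0 + 2 * dev), rs, m, cfg)
    expect_gt(u2$mean_stat, u1$mean_stat)
  }

  ## plotting statistic is the max of the absolute components
  set.seed(9)
  st <- chart_state("max_mewma", m)
  for (i in 1:20) {
    u <- update_max_mewma(st, make_betahat(m, beta0 + rnorm(6, sd = .2)),
                          make_rs(c(0, 0), rchisq(1, 8)), m, cfg)
    st <- u$state
    expect_identical(u$stat, max(abs(u$mean_stat), abs(u$var_stat)))
    expect_gte(u$stat, 0)
  }
})

test_that("Max-MCUSUM accumulators and allowance match the definitions", {
  m <- p2_scenario()$model
  beta0 <- vec_coef(m$B)
  ## allowance v = log(tau) tau/(tau-1) at the design tau = 1.1
  expect_equal(log(1.1) * 1.1 / 0.1, 1.0484, tolerance = 1e-4)

  ## beta-hat at target with fresh state stays at zero
  u <- update_max_mcusum(chart_state("max_mcusum", m),
                         make_betahat(m, beta0), m, cfg)
  expect_equal(u$stat, 0)
  expect_equal(c(u$state$U, u$state$L), c(0, 0))

  ## beta_b must differ from the in-control vector
  cfg_bad <- chart_config(beta_b = beta0)
  expect_error(update_max_mcusum(chart_state("max_mcusum", m),
                                 make_betahat(m, beta0), m, cfg_bad),
               "beta_b")

  ## accumulators stay nonnegative and MC = max(U, L)
  set.seed(14)
  st <- chart_state("max_mcusum", m)
  for (i in 1:20) {
    u <- update_max_mcusum(st, make_betahat(m, beta0 + rnorm(6, sd = .5)),
                           m, cfg)
    st <- u$state
    expect_true(st$U >= 0 && st$L >= 0)
    expect_identical(u$stat, max(st$U, st$L))
  }
})

test_that("SS-EWMAe updates follow the printed recursions", {
  m <- p2_scenario()$model
  ## F = 1 with V_0 = 0 and lambda = 0.2 gives V_1 = 0.2
  f_for_F1 <- qchisq(pnorm(1), 8)
  u <- update_ss_ewmae(chart_state("ss_ewmae", m),
                       make_rs(c(0, 0), f_for_F1), m, cfg)
  expect_equal(u$var_stat, 0.2, tolerance = 1e-12)
  expect_equal(u$F, 1, tolerance = 1e-12)
  ## fresh state, zero mean residual: T at the clamp floor, P = lambda * floor
  expect_equal(u$mean_stat, 0.2 * qnorm(1e-12))
  ## statistic is P^2 + V^2
  expect_equal(u$stat, u$mean_stat^2 + u$var_stat^2)
})

test_that("SS-CUSUMe accumulates the transformed statistics", {
  m <- p2_scenario()$model
  st <- chart_state("ss_cusume", m)
  ## |T| <= k1 and |F| <= k2 keep everything at zero
  u <- update_ss_cusume(st, T = 0.5, F = -1, cfg)
  expect_equal(u$stat, 0)
  ## T = 2, k1 = 1 -> D+ = 1, M = 1; F = 0 -> N = 0; CUe = 1
  u <- update_ss_cusume(chart_state("ss_cusume", m), T = 2, F = 0, cfg)
  expect_equal(u$mean_stat, 1)
  expect_equal(u$var_stat, 0)
  expect_equal(u$stat, 1)
})

test_that("worked-example combining identities reproduce the printed values", {
  ## Max operator rows: final statistic is the larger absolute component
  expect_equal(max(abs(-2.370), abs(-0.544)), 2.370)    # mean side dominates
  expect_equal(max(1.8698, 0), 1.8698)
  ## SS rows: squared components (the published table prints the rounded
  ## components, so the sum of squares agrees to ~1e-4)
  expect_equal((-0.3005)^2 + (-0.1815)^2, 0.1233, tolerance = 1e-3)
  ## a first-sample SS-CUSUMe update engineered to the printed components
  m <- p2_scenario()$model
  u <- update_ss_cusume(chart_state("ss_cusume", m),
                        T = -(0.5029 + 1), F = 0, cfg)
  expect_equal(u$mean_stat, 0.5029, tolerance = 1e-12)
  expect_equal(u$var_stat, 0)
  expect_equal(u$stat, 0.2529, tolerance = 5e-5)
})

test_that("all plotting statistics are nonnegative and replays are exact", {
  m <- p2_scenario()$model
  cfgs <- p2_scenario()$cfg
  set.seed(21)
  samples <- lapply(1:30, function(i)
    simulate_sample(m, 4, shift_spec(matrix(rnorm(6, sd = .2), 3, 2),
                                     tau = sample(c(1, 1.5, 2), 1))))
  for (ch in c("max_mewma", "max_mcusum", "ss_ewmae", "ss_cusume")) {
    s1 <- replay_chart(ch, samples, m, cfgs)
    s2 <- replay_chart(ch, samples, m, cfgs)
    expect_true(all(s1 >= 0), label = paste(ch, "nonnegative"))
    expect_identical(s1, s2)
  }
})

test_that("chart statistics are invariant to relabeling the responses", {
  m <- p2_scenario()$model
  msw <- profile_model(m$B[, 2:1], m$Sigma[2:1, 2:1], m$designs)
  cfgs <- p2_scenario()$cfg
  set.seed(31)
  samples <- lapply(1:10, function(i) simulate_sample(m, 4, shift_spec(0, 1.4)))
  swapped <- lapply(samples, function(s) {
    s$Y <- s$Y[, 2:1]
    s
  })
  for (ch in c("max_mewma", "ss_ewmae", "ss_cusume")) {
    expect_equal(replay_chart(ch, samples, m, cfgs),
                 replay_chart(ch, swapped, msw, cfgs), tolerance = 1e-10,
                 label = paste(ch, "response relabeling"))
  }
})

test_that("the in-control F statistic is standard normal", {
  m <- p2_scenario()$model
  ## f_k ~ chi2(np) exactly under known parameters, so the transform of
  ## simulated residual summaries must be standard normal
  set.seed(8)
  Fstat <- vapply(seq_len(4000), function(i) {
    rs <- residual_summary(simulate_sample(m, 4), m)
    normal_chisq_transform(rs$f, 8)
  }, 0)
  ks <- stats::ks.test(Fstat, stats::pnorm)
  expect_gt(ks$p.value, 0.01)
})

test_that("block engine and single-sample updates agree path by path", {
  sc <- p2_scenario()
  m <- sc$model
  for (ch in c("max_mewma", "max_mcusum", "ss_ewmae", "ss_cusume")) {
    for (tau in c(1, 1.5)) {
      pre <- vpcharts:::chart_precomp(ch, m, 4, shift_spec(tau = tau), sc$cfg)
      st <- vpcharts:::kern_init(ch, 1L, pre)
      set.seed(77)
      eng <- vapply(1:15, function(i) {
        ku <- vpcharts:::kern_update(st, 1L,
                                     vpcharts:::draw_inputs(1L, pre), pre)
        st <<- ku$st
        ku$stat
      }, 0)
      set.seed(77)
      man <- replay_chart(ch, lapply(1:15, function(i)
        simulate_sample(m, 4, shift_spec(tau = tau))), m, sc$cfg)
      expect_equal(eng, man, tolerance = 1e-10,
                   label = paste(ch, "engine equals manual path, tau", tau))
    }
  }
})
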