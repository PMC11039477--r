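## Internal vectorized Monte-Carlo engine.
##
## Run-length simulation is vectorized across replications: a block of active
## runs is advanced one sample per iteration with matrix operations, runs
## leave the block when they signal.  The per-sample math is identical to the
## exported single-sample update functions (an equivalence asserted by the
## test suite for every chart type).

## Per-(chart, model, n, shift) constants.
chart_precomp <- function(chart, model, n, shift, cfg) {
  X <- design_for(model, n)
  p <- model$p
  d0 <- model$q + 1L
  XtX <- crossprod(X)
  Sinv <- solve(model$Sigma)
  dB <- shift_delta(shift, model)
  shiftX <- X %*% dB
  lam <- cfg$lam
  pre <- list(
    chart = chart, n = n, p = p, d0 = d0, d = p * d0, np = n * p,
    P = solve(XtX, t(X)),
    cholS = chol(model$Sigma) * sqrt(shift$tau),
    Sinv = Sinv,
    dB_vec = as.vector(dB), shifted = any(dB != 0),
    ebar_shift = colMeans(shiftX),
    SbInv = kronecker(Sinv, XtX),
    zcov_inv = solve(model$Sigma / n) * (2 - lam) / lam,
    lam = lam, eps = cfg$clamp_eps, k1 = cfg$k1, k2 = cfg$k2,
    need_bdev = chart %in% c("max_mewma", "max_mcusum"),
    need_resid = chart %in% c("max_mewma", "ss_ewmae", "ss_cusume")
  )
  if (chart == "max_mcusum") {
    diff <- resolve_beta_b(cfg, model) - as.vector(model$B)
    if (all(diff == 0)) stop("beta_b must differ from the in-control beta")
    D <- sqrt(drop(diff %*% pre$SbInv %*% diff))
    pre$mc <- list(a = drop(diff %*% pre$SbInv) / D, D = D,
                   v = log(cfg$tau_design) * cfg$tau_design /
                       (cfg$tau_design - 1))
  }
  pre
}

## Draw the per-sample sufficient statistics for m replications:
## bdev (m x d coefficient deviations from the in-control beta, response-
## major), f (m residual quadratic forms = W), ebar (m x p mean residuals).
##
## Shift semantics: a coefficient shift moves the process level, so it
## enters the mean channels (bdev, ebar) additively, while the residual
## dispersion statistic f = W stays central (scaled by tau only) — the
## variability channel measures spread about the current process level.
## This is the out-of-control model under which the charts' run-length
## profiles are defined; see the methods vignette.
draw_inputs <- function(m, pre) {
  n <- pre$n; p <- pre$p
  E <- matrix(stats::rnorm(m * n * p), m * n, p) %*% pre$cholS
  out <- list()
  if (pre$need_resid) {
    qv <- rowSums((E %*% pre$Sinv) * E)
    out$f <- .colSums(qv, n, m)
    if (pre$chart %in% c("ss_ewmae", "ss_cusume")) {
      ebar <- matrix(0, m, p)
      for (j in seq_len(p))
        ebar[, j] <- .colSums(E[, j], n, m) / n
      if (pre$shifted)
        ebar <- ebar + matrix(pre$ebar_shift, m, p, byrow = TRUE)
      out$ebar <- ebar
    }
  }
  if (pre$need_bdev) {
    PE <- pre$P %*% matrix(E, n, m * p)          # d0 x (m p), rep index fastest
    bdev <- matrix(aperm(array(PE, c(pre$d0, m, p)), c(2L, 1L, 3L)),
                   m, pre$d)
    if (pre$shifted)
      bdev <- bdev + matrix(pre$dB_vec, m, pre$d, byrow = TRUE)
    out$bdev <- bdev
  }
  out
}

kern_init <- function(chart, m, pre) {
  switch(chart,
    max_mewma  = list(Z = matrix(0, m, pre$d), g = numeric(m)),
    max_mcusum = list(U = numeric(m), L = numeric(m)),
    ss_ewmae   = list(Z = matrix(0, m, pre$p), P = numeric(m), V = numeric(m)),
    ss_cusume  = list(Z = matrix(0, m, pre$p), Dm = numeric(m), Dp = numeric(m),
                      Bm = numeric(m), Bp = numeric(m))
  )
}

clampq <- function(pr, eps) stats::qnorm(pmin(pmax(pr, eps), 1 - eps))

## Advance rows `idx` of a block state by one sample.
kern_update <- function(st, idx, inp, pre) {
  lam <- pre$lam; eps <- pre$eps
  switch(pre$chart,
    max_mewma = {
      Z <- (1 - lam) * st$Z[idx, , drop = FALSE] + lam * inp$bdev
      qf <- (2 - lam) / lam * rowSums((Z %*% pre$SbInv) * Z)
      C <- clampq(stats::pchisq(qf, pre$d), eps)
      g <- (1 - lam) * st$g[idx] +
           lam * clampq(stats::pchisq(inp$f, pre$np), eps)
      st$Z[idx, ] <- Z; st$g[idx] <- g
      list(st = st, stat = pmax(abs(C), abs(sqrt((2 - lam) / lam) * g)))
    },
    max_mcusum = {
      Zk <- drop(inp$bdev %*% pre$mc$a)
      qf <- rowSums((inp$bdev %*% pre$SbInv) * inp$bdev)
      U <- pmax(0, st$U[idx] + Zk - 0.5 * pre$mc$D)
      L <- pmax(0, st$L[idx] + qf - pre$mc$v)
      st$U[idx] <- U; st$L[idx] <- L
      list(st = st, stat = pmax(U, L))
    },
    ss_ewmae = {
      Z <- (1 - lam) * st$Z[idx, , drop = FALSE] + lam * inp$ebar
      Tk <- clampq(stats::pchisq(rowSums((Z %*% pre$zcov_inv) * Z), pre$p), eps)
      Fk <- clampq(stats::pchisq(inp$f, pre$np), eps)
      P <- lam * Tk + (1 - lam) * st$P[idx]
      V <- lam * Fk + (1 - lam) * st$V[idx]
      st$Z[idx, ] <- Z; st$P[idx] <- P; st$V[idx] <- V
      list(st = st, stat = P^2 + V^2)
    },
    ss_cusume = {
      Z <- (1 - lam) * st$Z[idx, , drop = FALSE] + lam * inp$ebar
      Tk <- clampq(stats::pchisq(rowSums((Z %*% pre$zcov_inv) * Z), pre$p), eps)
      Fk <- clampq(stats::pchisq(inp$f, pre$np), eps)
      Dm <- pmax(0, -Tk - pre$k1 + st$Dm[idx])
      Dp <- pmax(0,  Tk - pre$k1 + st$Dp[idx])
      Bm <- pmax(0, -Fk - pre$k2 + st$Bm[idx])
      Bp <- pmax(0,  Fk - pre$k2 + st$Bp[idx])
      st$Z[idx, ] <- Z
      st$Dm[idx] <- Dm; st$Dp[idx] <- Dp; st$Bm[idx] <- Bm; st$Bp[idx] <- Bp
      list(st = st, stat = pmax(Dm, Dp)^2 + pmax(Bm, Bp)^2)
    }
  )
}

## First-update plotting statistics from fresh states (Algorithm-1 step 3).
first_update_stats <- function(chart, model, n, cfg, reps) {
  pre <- chart_precomp(chart, model, n, shift_spec(), cfg)
  st <- kern_init(chart, reps, pre)
  kern_update(st, seq_len(reps), draw_inputs(reps, pre), pre)$stat
}

## Zero-state run lengths of an FP chart.  Optionally collects every
## non-signal statistic (with its replication id) for warning-limit work.
sim_rl_fp <- function(chart, model, n, shift, ucl, cfg, reps, cap,
                      collect_stats = FALSE) {
  pre <- chart_precomp(chart, model, n, shift, cfg)
  st <- kern_init(chart, reps, pre)
  rl <- rep.int(cap, reps)
  signalled <- logical(reps)
  active <- seq_len(reps)
  coll_s <- if (collect_stats) vector("list", 256L) else NULL
  coll_r <- if (collect_stats) vector("list", 256L) else NULL
  nc <- 0L
  step <- 0L
  while (length(active) && step < cap) {
    step <- step + 1L
    ku <- kern_update(st, active, draw_inputs(length(active), pre), pre)
    st <- ku$st
    sig <- ku$stat > ucl
    if (collect_stats && any(!sig)) {
      nc <- nc + 1L
      if (nc > length(coll_s)) {
        length(coll_s) <- 2L * nc
        length(coll_r) <- 2L * nc
      }
      coll_s[[nc]] <- ku$stat[!sig]
      coll_r[[nc]] <- active[!sig]
    }
    if (any(sig)) {
      rl[active[sig]] <- step
      signalled[active[sig]] <- TRUE
      active <- active[!sig]
    }
  }
  out <- list(rl = rl, truncated = sum(!signalled))
  if (collect_stats) {
    out$stats <- unlist(coll_s[seq_len(nc)], use.names = FALSE)
    out$rep_id <- unlist(coll_r[seq_len(nc)], use.names = FALSE)
  }
  out
}

## Zero-state run lengths and times to signal of a VP chart (dual-track
## state machine).  Memory statistics start at zero; the initial region is
## either region 1 or drawn with the in-control safe-zone probability P0.
sim_rl_vp <- function(chart, model, design, shift, cfg, reps, cap,
                      start_region = c("random", "region1")) {
  start_region <- match.arg(start_region)
  pre1 <- chart_precomp(chart, model, design$n1, shift, cfg)
  pre2 <- chart_precomp(chart, model, design$n2, shift, cfg)
  st1 <- kern_init(chart, reps, pre1)
  st2 <- kern_init(chart, reps, pre2)
  region <- if (start_region == "region1") rep.int(1L, reps)
            else ifelse(stats::runif(reps) < design$P0, 1L, 2L)
  ts <- numeric(reps)
  rl <- rep.int(cap, reps)
  signalled <- logical(reps)
  active <- seq_len(reps)
  n_samples <- 0; n_sum <- 0; t_sum <- 0; safe_ct <- 0; nonsig_ct <- 0
  step <- 0L
  while (length(active) && step < cap) {
    step <- step + 1L
    for (r in 1:2) {
      idx <- active[region[active] == r]
      if (!length(idx)) next
      pre <- if (r == 1L) pre1 else pre2
      inp <- draw_inputs(length(idx), pre)
      if (r == 1L) {
        ku <- kern_update(st1, idx, inp, pre); st1 <- ku$st
      } else {
        ku <- kern_update(st2, idx, inp, pre); st2 <- ku$st
      }
      t_r <- if (r == 1L) design$t1 else design$t2
      UCL <- if (r == 1L) design$UCL1 else design$UCL2
      UWL <- if (r == 1L) design$UWL1 else design$UWL2
      ts[idx] <- ts[idx] + t_r
      n_samples <- n_samples + length(idx)
      n_sum <- n_sum + length(idx) * pre$n
      t_sum <- t_sum + length(idx) * t_r
      sig <- ku$stat > UCL
      if (any(sig)) {
        rl[idx[sig]] <- step
        signalled[idx[sig]] <- TRUE
      }
      if (any(!sig)) {
        safe <- ku$stat[!sig] <= UWL
        region[idx[!sig]] <- ifelse(safe, 1L, 2L)
        safe_ct <- safe_ct + sum(safe)
        nonsig_ct <- nonsig_ct + sum(!sig)
      }
    }
    active <- active[!signalled[active]]
  }
  list(rl = rl, ts = ts, truncated = sum(!signalled),
       occupancy = list(mean_n = n_sum / n_samples,
                        mean_t = t_sum / n_samples,
                        safe_fraction = safe_ct / nonsig_ct))
}
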