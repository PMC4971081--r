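test_that("unit input magnitude sums absolute synaptic drives", {
  p <- default_lsnm_params()
  expect_equal(unit_input_magnitude(0, 0, p), 0)
  # inhibitory within-unit input contributes its absolute value
  p2 <- modifyList(p, list(w_EE = 0, w_EI = 0, w_IE = -0.5))
  expect_equal(unit_input_magnitude(0, 0.4, p2), 0.2)
  # nonnegative for random states and mixed-sign afferents
  set.seed(2)
  for (i in 1:25) {
    v <- unit_input_magnitude(runif(1), runif(1), p, rnorm(5))
    expect_gte(v, 0)
  }
  # composition: (w_EE + w_EI) E + |w_IE I| + sum |afferent terms|
  expect_equal(unit_input_magnitude(0.5, 0.2, p, c(0.1, -0.3)),
               (p$w_EE + p$w_EI) * 0.5 + abs(p$w_IE * 0.2) + 0.4)
})

test_that("integrated synaptic activity bins sum members over 50 ms", {
  IN <- matrix(0, 200, 6)
  z <- integrated_synaptic_activity(IN, list(A = 1:3, B = 4:6))
  expect_equal(dim(z), c(20, 2))               # 200 steps / 10 per bin
  expect_true(all(z == 0))
  # constant input c over an ROI of m members: bin value 10 * m * c
  INc <- matrix(0.3, 200, 6)
  zc <- integrated_synaptic_activity(INc, list(A = 1:4))
  expect_true(all(abs(zc - 10 * 4 * 0.3) < 1e-12))
  # a 198-s run at 5 ms gives 3960 bins
  expect_equal(nrow(integrated_synaptic_activity(
    matrix(0, 198 * 200, 1), list(A = 1))), 3960)
  # superset ROI dominates its subset at every bin
  set.seed(3)
  INr <- matrix(runif(200 * 6), 200, 6)
  zr <- integrated_synaptic_activity(INr, list(sub = 1:2, sup = 1:4))
  expect_true(all(zr[, "sup"] >= zr[, "sub"]))
  expect_error(integrated_synaptic_activity(INr, list(A = 1),
                                            window_ms = 42), "multiple")
})

test_that("balloon k-coefficients match their printed formulas", {
  p <- default_balloon_params()
  k <- hybridbrain:::balloon_k(p)
  expect_equal(k$k1, 4.3 * p$theta0 * p$E0 * p$TE)
  expect_equal(k$k2, p$epsilon_ratio * p$r0 * p$E0 * p$TE)
  expect_equal(k$k3, 1 - p$epsilon_ratio)
})

test_that("the balloon rest point is stationary and zero drive gives y = 0", {
  isa <- matrix(0, 400, 2)
  y <- balloon_bold(isa, TR = 2, bin_s = 0.05)
  expect_true(all(abs(y) < 1e-14))
  # constant (baseline-only) drive normalizes away: still resting
  isa_c <- matrix(7.3, 400, 1)
  expect_true(all(abs(balloon_bold(isa_c, TR = 2, bin_s = 0.05)) < 1e-14))
})

test_that("y is invariant to an additive ISA baseline", {
  set.seed(4)
  x <- matrix(rep(c(0, 1, 0, 0), each = 100) + runif(400, 0, 0.1), ncol = 1)
  y1 <- balloon_bold(x, TR = 2)
  y2 <- balloon_bold(x + 123.4, TR = 2)
  expect_equal(as.numeric(y1), as.numeric(y2), tolerance = 1e-12)
})

test_that("an ISA impulse yields a hemodynamic peak 4-6 s later", {
  isa <- matrix(0, 1200, 1)
  isa[101:110] <- 1                            # 0.5-s impulse at t = 5 s
  yfull <- balloon_bold(isa, TR = 0.05, substeps = 4)  # keep bin resolution
  tpk <- (which.max(yfull) * 0.05) - 5.25      # latency from impulse centre
  expect_gt(tpk, 4)
  expect_lt(tpk, 6)
})

test_that("halving the balloon step changes y by far less than 0.1% RMS", {
  isa <- matrix(0, 600, 1)
  isa[101:120] <- 1
  y1 <- balloon_bold(isa, TR = 2)              # default sub-stepping
  y2 <- balloon_bold(isa, TR = 2, substeps = 20)
  rel <- sqrt(mean((y1 - y2)^2)) / max(abs(y1))
  expect_lt(rel, 1e-3)
})

test_that("the balloon integrator matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- default_balloon_params()
  nb <- 400
  x <- rep(0, nb); x[41:60] <- 1
  x <- (x - mean(x)) / diff(range(x))
  rhs <- function(t, st, parms) {
    xb <- x[pmin(nb, floor(t / 0.05) + 1)]
    with(as.list(st), list(c(
      s = p$efficacy * xb - s / p$tau_s - (f - 1) / p$tau_f,
      f = s,
      v = (f - v^(1 / p$alpha)) / p$tau0,
      q = (f * (1 - (1 - p$E0)^(1 / f)) / p$E0 -
             v^(1 / p$alpha) * q / v) / p$tau0)))
  }
  sol <- deSolve::lsoda(c(s = 0, f = 1, v = 1, q = 1), seq(0, 20, by = 0.05),
                        rhs, NULL, rtol = 1e-10, atol = 1e-12)
  k <- hybridbrain:::balloon_k(p)
  y_ref <- p$V0 * (k$k1 * (1 - sol[, "q"]) +
                     k$k2 * (1 - sol[, "q"] / sol[, "v"]) +
                     k$k3 * (1 - sol[, "v"]))
  y_ref <- y_ref[-1][seq(40, 400, by = 40)]    # sample at TR = 2 s
  y <- as.numeric(balloon_bold(matrix(x, ncol = 1), p, TR = 2,
                               substeps = 20, normalize = FALSE))
  expect_equal(y, y_ref, tolerance = 2e-3)
})

test_that("block signal change recovers a constructed boxcar contrast", {
  des <- build_dms_design(seed = 6)
  # constant series: all changes zero
  y0 <- matrix(0.5, 99, 2, dimnames = list(NULL, c("A", "B")))
  bs0 <- block_signal_change(y0, des)
  expect_true(all(abs(bs0$per_condition) < 1e-12))
  expect_equal(unname(bs0$difference), c(0, 0))
  # boxcar elevated during DMS blocks by a known amount
  tr_times <- (seq_len(99) - 1) * 2
  ons <- block_onsets(des)
  blk <- findInterval(tr_times, ons$onset)
  y <- matrix(ifelse(ons$condition[blk] == "DMS", 0.2, 0), ncol = 1,
              dimnames = list(NULL, "A"))
  bs <- block_signal_change(y, des)
  base <- 1 + mean(y)
  expect_equal(unname(bs$per_condition["DMS", 1]),
               100 * (1.2 - base) / base, tolerance = 1e-10)
  expect_equal(unname(bs$difference[1]), 100 * 0.2 / base,
               tolerance = 1e-10)
  expect_error(block_signal_change(y, des, timepoints = 4:12), "shorter")
})
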