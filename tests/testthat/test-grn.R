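test_that("rhs has the exact closed form at the origin and rejects bad input", {
  pr <- grn_parameters()
  f0 <- grn_rhs(c(0, 0, 0), pr, signal_input())
  # at zero concentration every repression term is exactly 1 and the
  # activation term exactly 0
  expect_equal(unname(f0),
               c(pr$mu_p + pr$sigma_p, pr$mu_b + pr$sigma_b, pr$mu_r))
  expect_error(grn_rhs(c(-1, 0, 0), pr), "finite and >= 0")
  expect_error(grn_parameters(mu_b = -1), "strictly positive")
  expect_error(signal_input(cd40_affinity = 1.5), "\\[0, 1\\]")
})

test_that("the autonomous network is bistable with the printed steady states", {
  ss <- grn_steady_states()
  expect_identical(sum(ss$stable), 2L)
  expect_true(all(ss$residual < 1e-9))
  stab <- ss[ss$stable, ]
  lo <- stab[which.min(stab$blimp1), ]
  hi <- stab[which.max(stab$blimp1), ]
  # founder-like state: BCL6 high, BLIMP1 and IRF4 low
  expect_gt(lo$bcl6, lo$blimp1)
  expect_lt(lo$irf4, 1)
  # plasma-cell state: BLIMP1 high, BCL6 low, IRF4 near 2 model units
  expect_gt(hi$blimp1, hi$bcl6)
  expect_gt(hi$blimp1, fate_thresholds()$blimp1_pc_threshold)
  expect_lt(abs(hi$irf4 - 2) / 2, 0.2)
})

test_that("fixed points shift but remain fixed points when rates are scaled", {
  pr <- grn_parameters(lambda_p = 2, lambda_b = 2, lambda_r = 2)
  ss <- grn_steady_states(pr)
  expect_gt(nrow(ss), 0)
  for (i in seq_len(nrow(ss)))
    expect_lt(rhs_norm(as.numeric(ss[i, 1:3]), pr), 1e-9)
})

test_that("founder basin is stable: no spontaneous differentiation in 504 h", {
  tr <- grn_integrate(tf_state(0, 5, 0), duration = 504, dt = 0.05)
  expect_lt(max(tr$blimp1), 8)
  final <- as.numeric(tr[nrow(tr), -1])
  expect_gt(final[2], final[1])      # BCL6 stays dominant
  expect_lt(rhs_norm(final), 1e-6)
})

test_that("trajectories started at the stable states stay within 1 percent", {
  ss <- grn_steady_states()
  stab <- ss[ss$stable, ]
  for (i in seq_len(nrow(stab))) {
    s0 <- as.numeric(stab[i, 1:3])
    tr <- grn_integrate(s0, duration = 504, dt = 0.05)
    dev <- abs(sweep(as.matrix(tr[, -1]), 2, s0)) /
      rep(pmax(s0, 1e-3), each = nrow(tr))
    expect_lt(max(dev), 0.01)
  }
})

test_that("integration contract: identity at zero duration, fixed length, clip", {
  s <- tf_state(1, 2, 3)
  tr0 <- grn_integrate(s, duration = 0)
  expect_identical(nrow(tr0), 1L)
  expect_equal(as.numeric(tr0[1, -1]), as.numeric(s))
  tr <- grn_integrate(s, duration = 10, dt = 0.1)
  expect_identical(nrow(tr), 101L)
  expect_true(all(as.matrix(tr[, -1]) >= 0))
})

test_that("halving the step changes a 504-h endpoint by less than 1e-6", {
  s <- tf_state(0.5, 3, 0.4)
  e1 <- as.numeric(tail(grn_integrate(s, duration = 504, dt = 0.05), 1))[-1]
  e2 <- as.numeric(tail(grn_integrate(s, duration = 504, dt = 0.025), 1))[-1]
  expect_lt(max(abs(e1 - e2)), 1e-6)
})

test_that("fixed-step trajectories match an adaptive reference within 1e-5", {
  skip_if_not_installed("deSolve")
  pr <- grn_parameters()
  ode_rhs <- function(t, y, parms)
    list(as.numeric(grn_rhs(pmax(y, 0), pr, signal_input())))
  check <- function(start, dt) {
    times <- seq(0, 48, by = 1)
    ref <- deSolve::lsoda(start, times, ode_rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
    tr <- grn_integrate(start, pr, duration = 48, dt = dt)
    ours <- as.matrix(tr[tr$time_h %in% times, -1])
    expect_lt(max(abs(ours - ref[, -1])), 1e-5)
  }
  # smooth regimes at the standard step
  check(c(0, 5, 0), dt = 0.05)
  check(c(6, 2, 2), dt = 0.05)
  # a TF-depleted daughter has an initial BCL6 production burst (~80/h);
  # the step must resolve that transient for the tolerance to apply
  check(c(0, 0, 0.5), dt = 0.01)
})

test_that("classification threshold is inclusive at 8 model units", {
  expect_identical(classify_tf_state(c(8, 2, 2)), "BLIMP1-high")
  expect_identical(classify_tf_state(c(7.999, 2, 2)), "BLIMP1-low")
  expect_identical(classify_tf_state(c(0, 5, 0)), "BLIMP1-low")
})

test_that("time_to_threshold handles the three crossing regimes", {
  expect_identical(time_to_threshold(tf_state(8, 2, 2)), 0)
  t_cross <- time_to_threshold(tf_state(0, 0, 0.5), max_hours = 100)
  expect_true(is.finite(t_cross) && t_cross <= 20)
  expect_identical(time_to_threshold(tf_state(0, 5, 0), max_hours = 504), Inf)
})

test_that("time_to_threshold is non-increasing in the initial BLIMP1 level", {
  p0 <- seq(0, 8, by = 1)
  tt <- vapply(p0, function(p)
    time_to_threshold(tf_state(p, 2, 2), max_hours = 200), numeric(1))
  expect_true(all(diff(tt) <= 1e-9))
})

test_that("bisection refines the crossing to within 0.01 h of the oracle", {
  skip_if_not_installed("deSolve")
  pr <- grn_parameters()
  ode_rhs <- function(t, y, parms)
    list(as.numeric(grn_rhs(pmax(y, 0), pr, signal_input())))
  ref <- deSolve::lsoda(c(6, 2, 2), seq(0, 5, by = 1e-3), ode_rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  t_ref <- ref[which(ref[, 2] >= 8)[1], 1]
  expect_lt(abs(time_to_threshold(tf_state(6, 2, 2)) - t_ref), 0.02)
})

test_that("daughter experiments reproduce the polarity-level patterns", {
  hi_lo <- function(dx) unname(dx$classification)
  expect_identical(hi_lo(daughter_experiment(c(1, 1, 1))),
                   c("BLIMP1-high", "BLIMP1-low"))
  expect_identical(hi_lo(daughter_experiment(c(0.9, 0.9, 0.9))),
                   c("BLIMP1-high", "BLIMP1-low"))
  expect_identical(hi_lo(daughter_experiment(c(0.75, 0.75, 0.75))),
                   c("BLIMP1-high", "BLIMP1-high"))
  expect_identical(hi_lo(daughter_experiment(c(0.5, 0.5, 0.5))),
                   c("BLIMP1-high", "BLIMP1-high"))
  expect_error(daughter_experiment(c(0.4, 1, 1)), "\\[0.5, 1\\]")
})

test_that("lower BLIMP1 polarity delays the high daughter by at most 4 h", {
  t_full <- time_to_threshold(tf_state(8, 2, 2))
  t_low <- time_to_threshold(tf_state(0.75 * 8, 2, 2))
  delay <- t_low - t_full
  expect_gt(delay, 0)
  expect_lte(delay, 4)
})
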