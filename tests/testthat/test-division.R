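test_that("policy invariants are validated", {
  expect_error(division_policy(p_ag = 1.2), "\\[0, 1\\]")
  expect_error(division_policy(l_blimp1 = 1.2), "polarity levels")
  expect_error(division_policy(l_ag = 0.3), "polarity levels")
  expect_error(division_policy(p_ag = 0.72, p_tf = 0.5, coupling = "coupled"),
               "p_ag == p_tf")
  expect_silent(division_policy(p_ag = 0.72, p_tf = 0.72,
                                coupling = "coupled"))
})

test_that("P = 0 always draws symmetric modes and identical daughters", {
  pol <- division_policy(coupling = "none")
  set.seed(42)
  for (i in 1:20) {
    out <- draw_division_mode(pol)
    expect_identical(out$ag_mode, "symmetric")
    expect_identical(out$tf_mode, "symmetric")
    d <- split_concentrations(c(3, 1, 0.4), 5, out, pol)
    expect_equal(d$daughter1, d$daughter2)
  }
})

test_that("coupled draws match the exact binomial interval at P = 0.72", {
  pol <- division_policy(p_ag = 0.72, p_tf = 0.72, l_ag = 1, l_blimp1 = 1,
                         l_bcl6 = 1, l_irf4 = 1, coupling = "coupled")
  set.seed(7)
  n <- 10000
  draws <- replicate(n, {
    out <- draw_division_mode(pol)
    expect_identical(out$ag_mode, out$tf_mode)  # one shared draw
    out$ag_mode == "asymmetric"
  })
  k <- sum(draws)
  ci <- qbinom(c(0.005, 0.995), n, 0.72)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("uncoupled P_TF = 1 is asymmetric for TFs in every draw", {
  pol <- division_policy(p_ag = 0.72, p_tf = 1, l_ag = 1, l_blimp1 = 1,
                         l_bcl6 = 1, l_irf4 = 1, coupling = "uncoupled")
  set.seed(1)
  for (i in 1:50)
    expect_identical(draw_division_mode(pol)$tf_mode, "asymmetric")
})

test_that("splits follow the fraction definition exactly", {
  pol <- division_policy(p_ag = 1, p_tf = 1, l_ag = 1, l_blimp1 = 0.75,
                         l_bcl6 = 1, l_irf4 = 1, coupling = "uncoupled")
  out <- list(ag_mode = "asymmetric", tf_mode = "asymmetric", high_side = 1L)
  d <- split_concentrations(c(8, 2, 2), 4, out, pol)
  expect_equal(d$daughter1$tf, c(6, 2, 2))
  expect_equal(d$daughter2$tf, c(2, 0, 0))
  expect_equal(d$daughter1$ag, 4)
  expect_equal(d$daughter2$ag, 0)

  pol1 <- division_policy(p_ag = 1, p_tf = 1, l_ag = 1, l_blimp1 = 1,
                          l_bcl6 = 1, l_irf4 = 1, coupling = "uncoupled")
  d1 <- split_concentrations(c(8, 2, 2), 3, out, pol1)
  expect_equal(d1$daughter1$tf, c(8, 2, 2))
  expect_equal(d1$daughter2$tf, c(0, 0, 0))

  sym <- list(ag_mode = "symmetric", tf_mode = "symmetric", high_side = 2L)
  ds <- split_concentrations(c(8, 2, 2), 4, sym, pol)
  expect_equal(ds$daughter1$ag, 2)
  expect_equal(ds$daughter2$ag, 2)
})

test_that("mass is conserved and high sides co-orient across random draws", {
  set.seed(99)
  for (i in 1:200) {
    pol <- division_policy(p_ag = runif(1), p_tf = runif(1),
                           l_ag = runif(1, 0.5, 1),
                           l_blimp1 = runif(1, 0.5, 1),
                           l_bcl6 = runif(1, 0.5, 1),
                           l_irf4 = runif(1, 0.5, 1), coupling = "uncoupled")
    out <- draw_division_mode(pol)
    tf <- runif(3, 0, 10); ag <- runif(1, 0, 8)
    d <- split_concentrations(tf, ag, out, pol)
    expect_equal(d$daughter1$tf + d$daughter2$tf, tf)
    expect_equal(d$daughter1$ag + d$daughter2$ag, ag)
    if (out$ag_mode == "asymmetric" && out$tf_mode == "asymmetric" &&
        pol$l_ag > 0.5) {
      ag_hi <- which.max(c(d$daughter1$ag, d$daughter2$ag))
      for (k in 1:3) {
        lv <- c(pol$l_blimp1, pol$l_bcl6, pol$l_irf4)[k]
        if (lv > 0.5 && tf[k] > 0) {
          tf_hi <- which.max(c(d$daughter1$tf[k], d$daughter2$tf[k]))
          expect_identical(tf_hi, ag_hi)
        }
      }
    }
  }
})

test_that("identical seed and call sequence reproduce identical outcomes", {
  pol <- division_policy(p_ag = 0.72, p_tf = 1, l_ag = 1, coupling = "uncoupled")
  seq1 <- {
    set.seed(123)
    replicate(20, draw_division_mode(pol), simplify = FALSE)
  }
  seq2 <- {
    set.seed(123)
    replicate(20, draw_division_mode(pol), simplify = FALSE)
  }
  expect_identical(seq1, seq2)
})
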