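# minimal synthetic run records for metric arithmetic
fake_run <- function(cb, cc, pc_times = numeric(0), mbc_times = numeric(0),
                     time_h = seq_along(cb) - 1) {
  n_oc <- length(pc_times) + length(mbc_times)
  oc <- data.frame(
    exit_time_h = c(pc_times, mbc_times),
    type = c(rep(1, length(pc_times)), rep(2, length(mbc_times))),
    ag_status = rep(0, n_oc), blimp1 = rep(9, n_oc))
  structure(list(
    timeseries = data.frame(time_h = time_h, cb = cb, cc_live = cc,
                            dz_lz_ratio = ifelse(cc == 0, Inf, cb / cc)),
    output_cells = oc,
    counters = list(pc = length(pc_times), mbc = length(mbc_times))),
    class = "gc_run")
}

test_that("ratio series reports the exact ratios with infinity markers", {
  r <- fake_run(cb = c(10, 7, 0), cc = c(5, 0, 5))
  s <- dz_lz_series(r)
  expect_equal(s$ratio, c(2, Inf, 0))
  expect_identical(s$infinite, c(FALSE, TRUE, FALSE))
  sm <- dz_lz_series(r, smooth = TRUE)
  expect_true(is.infinite(sm$ratio_smooth[2]))
})

test_that("switch metrics split plasma-cell exits at the day-6 boundary", {
  r <- fake_run(1, 1, pc_times = c(150, 200, 300), mbc_times = 100)
  m <- switch_metrics(r)
  expect_equal(m$frac_pc_after, 1)
  expect_true(m$switch_flag)

  r2 <- fake_run(1, 1, pc_times = c(10, 50, 100, 120, 140, 150, 160, 170,
                                    180, 200))
  m2 <- switch_metrics(r2)
  expect_equal(m2$frac_pc_before, 0.5)
  expect_equal(m2$frac_pc_before + m2$frac_pc_after, 1)
  expect_false(m2$switch_flag)

  # exit exactly at the boundary counts as before (strictly-greater rule)
  m3 <- switch_metrics(fake_run(1, 1, pc_times = 144))
  expect_equal(m3$frac_pc_before, 1)

  m4 <- switch_metrics(fake_run(1, 1))
  expect_false(m4$defined)
  expect_true(is.na(m4$frac_pc_after))
})

test_that("fold change handles ratios, identity and division by zero", {
  a <- fake_run(1, 1, mbc_times = rep(1, 1200))
  b <- fake_run(1, 1, mbc_times = rep(1, 100))
  expect_equal(fold_change(a, b, "MBC")$value, 12)
  expect_equal(fold_change(a, a, "MBC")$value, 1)
  z <- fake_run(1, 1)
  expect_identical(fold_change(a, z, "MBC")$value, Inf)
  both <- fold_change(z, z, "MBC")
  expect_false(both$defined)
  expect_true(is.na(both$value))
  expect_equal(fold_change(a, b, "OC")$value, 12)
})

test_that("window median uses day-4 onward and propagates infinity", {
  r <- fake_run(cb = rep(6, 200), cc = rep(2, 200),
                time_h = seq(0, 199))
  expect_equal(dz_lz_window_median(list(r))$median, 3)
  r2 <- fake_run(cb = rep(6, 200), cc = rep(0, 200), time_h = seq(0, 199))
  expect_identical(dz_lz_window_median(list(r2))$median, Inf)
})
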