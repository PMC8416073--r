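test_that("a run is bit-identical when repeated with the same seed", {
  eng <- fast_engine(duration = 120, n_founders = 20)
  r1 <- gc_run(eng, reference_policy(), seed = 4L)
  r2 <- gc_run(eng, reference_policy(), seed = 4L)
  expect_identical(r1$timeseries, r2$timeseries)
  expect_identical(r1$output_cells, r2$output_cells)
  expect_identical(r1$selections, r2$selections)
  r3 <- gc_run(eng, reference_policy(), seed = 5L)
  expect_false(identical(r1$timeseries, r3$timeseries))
})

test_that("an empty founder cohort yields an empty, eventless reaction", {
  eng <- fast_engine(duration = 48, n_founders = 0)
  r <- gc_run(eng, reference_policy(), seed = 1L)
  expect_true(all(r$timeseries$cb == 0))
  expect_true(all(r$timeseries$cc_live == 0))
  expect_identical(r$counters$pc, 0L)
  expect_identical(r$counters$created, 0L)
  expect_true(all(is.infinite(r$timeseries$dz_lz_ratio)))
})

test_that("cells are conserved: created = alive + divided + dead + egressed", {
  r <- cached_run("ref_fast",
                  gc_run(fast_engine(duration = 240, n_founders = 40),
                         reference_policy(), seed = 2L))
  cnt <- r$counters
  expect_identical(cnt$created,
                   cnt$alive_final + cnt$division_parents + cnt$apoptosed +
                     cnt$pc + cnt$mbc)
  expect_gt(cnt$pc + cnt$mbc, 0)
})

test_that("cumulative observables are monotone and the ratio is exact", {
  r <- cached_run("ref_fast",
                  gc_run(fast_engine(duration = 240, n_founders = 40),
                         reference_policy(), seed = 2L))
  ts <- r$timeseries
  expect_true(all(diff(ts$pc_cum) >= 0))
  expect_true(all(diff(ts$mbc_cum) >= 0))
  expect_true(all(diff(ts$apopt_cum) >= 0))
  has_cc <- ts$cc_live > 0
  expect_equal(ts$dz_lz_ratio[has_cc], ts$cb[has_cc] / ts$cc_live[has_cc])
  expect_true(all(is.infinite(ts$dz_lz_ratio[!has_cc])))
})

test_that("every output cell satisfies its exit invariant", {
  r <- cached_run("ref_fast",
                  gc_run(fast_engine(duration = 240, n_founders = 40),
                         reference_policy(), seed = 2L))
  oc <- r$output_cells
  thr <- fate_thresholds()$blimp1_pc_threshold
  expect_true(all(oc$blimp1[oc$type == 1] >= thr))       # PCs BLIMP1-high
  expect_true(all(oc$ag_status[oc$type == 2] == 1))      # MBCs antigen+
  expect_true(all(oc$blimp1[oc$type == 2] < thr))        # MBCs BLIMP1-low
})

test_that("without selection there are no output cells or recycled divisions", {
  # founder expansion only: stop before the light zone can select anyone
  eng <- fast_engine(duration = 46, n_founders = 10)
  r <- gc_run(eng, reference_policy(), seed = 3L)
  expect_gt(max(r$timeseries$cb), 10)
  expect_identical(r$counters$pc + r$counters$mbc, 0L)
  expect_identical(nrow(r$selections), 0L)
})

test_that("selected-cell affinities trend upward across the reaction", {
  recs <- lapply(1:5, function(s)
    cached_run(paste0("mat", s),
               gc_run(fast_engine(duration = 360, n_founders = 60),
                      reference_policy(), seed = s)))
  slopes <- vapply(recs, function(r) {
    sl <- r$selections
    unname(coef(lm(affinity ~ time_h, data = sl))[2])
  }, numeric(1))
  # median slope over seeds is positive (affinity maturation)
  expect_gt(median(slopes), 0)
})
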