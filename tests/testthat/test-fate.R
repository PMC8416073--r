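eligible <- function(blimp1, ag, ag_full = ag > 0)
  list(blimp1 = blimp1, retained_ag = ag, ag_full = ag_full,
       recycled = TRUE, divisions_left = 0L)

test_that("the three printed fate examples are reproduced", {
  expect_identical(classify_fate(eligible(9, 0)), "PC")
  expect_identical(classify_fate(eligible(3, 2)), "MBC")
  expect_identical(classify_fate(eligible(3, 0)), "return_to_CC")
})

test_that("classification is exhaustive and exclusive for any eligible cell", {
  set.seed(8)
  outcomes <- c("PC", "MBC", "return_to_CC", "await_pc")
  for (i in 1:300) {
    cell <- eligible(runif(1, 0, 12), sample(0:4, 1),
                     ag_full = runif(1) < 0.5)
    res <- classify_fate(cell)
    expect_identical(length(res), 1L)
    expect_true(res %in% outcomes)
  }
})

test_that("no antigen-negative MBC; PC decision ignores antigen", {
  set.seed(9)
  for (i in 1:100) {
    p <- runif(1, 0, 12)
    with_ag <- classify_fate(eligible(p, 3, ag_full = TRUE))
    no_ag <- classify_fate(eligible(p, 0))
    if (with_ag == "MBC") expect_lt(p, 8)
    # a PC stays a PC whichever antigen status it carries
    expect_identical(with_ag == "PC", no_ag == "PC")
  }
  expect_false(classify_fate(eligible(3, 0)) == "MBC")
})

test_that("partial antigen loads await the BLIMP1 threshold", {
  expect_identical(classify_fate(eligible(3, 1.5, ag_full = FALSE)),
                   "await_pc")
  expect_identical(classify_fate(eligible(8, 1.5, ag_full = FALSE)), "PC")
})

test_that("the contract rejects non-eligible cells", {
  expect_error(classify_fate(list(blimp1 = 9, retained_ag = 0,
                                  recycled = FALSE, divisions_left = 0L)),
               "recycled")
  expect_error(classify_fate(list(blimp1 = 9, retained_ag = 0,
                                  recycled = TRUE, divisions_left = 1L)),
               "finished dividing")
})

test_that("plasmablast annotation follows the threshold and stage", {
  expect_true(annotate_pb(list(blimp1 = 8.5, stage = "CB")))
  expect_false(annotate_pb(list(blimp1 = 0, stage = "CB")))
  expect_false(annotate_pb(list(blimp1 = 9, stage = "PC")))
})

test_that("founder cells start in the printed state", {
  set.seed(2)
  f <- make_founder(7L, founder_divisions = 6L)
  expect_equal(as.numeric(f$tf), c(0, 5, 0))
  expect_identical(f$stage, "CB")
  expect_identical(f$zone, "DZ")
  expect_equal(f$retained_ag, 0)
  expect_false(f$recycled)
  expect_false(is_ag_positive(f))
  expect_true(is_ag_positive(list(retained_ag = 3)))
  g <- make_founder(8L)
  expect_false(identical(f$gene, g$gene))  # genes differ between founders
})
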