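test_that("a straight bar yields the textbook skeleton graph", {
  m <- matrix(FALSE, 60, 120); m[30:32, 11:110] <- TRUE
  cm <- collagen_mask(m, 0.25)
  g <- skeletonize_mask(cm)
  st <- skeleton_component_stats(g)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_junctions, 0)
  expect_equal(st$n_endpoints, 2)
  expect_lt(abs(st$length_px - 99) / 99, 0.05)
  rec <- decompose_fibers(g, cm)
  expect_equal(rec$continuity, 1)
  expect_equal(rec$straightness, 1, tolerance = 0.02)
  expect_equal(rec$orientation_deg, 0, tolerance = 0.5)
})

test_that("a Y of three bars has one junction and three endpoints", {
  cm <- collagen_mask(y_mask(), 0.25)
  st <- skeleton_component_stats(skeletonize_mask(cm))
  expect_equal(st$n_junctions, 1)
  expect_equal(st$n_endpoints, 3)
})

test_that("length and orientation are recovered across the angle grid", {
  for (th in seq(0, 165, by = 15)) {
    cm <- collagen_mask(bar_mask(th), 0.25)
    rec <- decompose_fibers(skeletonize_mask(cm), cm)
    len_err <- abs(rec$length_um / (0.25 * 140) - 1)
    ori_err <- min(abs(rec$orientation_deg - th),
                   180 - abs(rec$orientation_deg - th))
    expect_lt(len_err, 0.05)
    expect_lt(ori_err, 2)
  }
})

test_that("width from the distance transform matches the drawn bar", {
  for (wid in c(8, 12)) {
    m <- matrix(FALSE, 60, 160); m[30 + seq_len(wid), 11:150] <- TRUE
    cm <- collagen_mask(m, 0.25)
    rec <- decompose_fibers(skeletonize_mask(cm), cm)
    expect_lt(abs(rec$width_mean_um - wid * 0.25) / (wid * 0.25), 0.15)
    expect_gte(rec$width_max_um, rec$width_mean_um)
  }
})

test_that("two disjoint bars decompose additively and partition the mask", {
  m <- matrix(FALSE, 100, 200)
  m[20:23, 10:150] <- TRUE
  m[70:73, 30:190] <- TRUE
  cm <- collagen_mask(m, 0.25)
  rec <- decompose_fibers(skeletonize_mask(cm), cm)
  expect_equal(nrow(rec), 2)
  expect_equal(sum(rec$area_um2), sum(m) * 0.25^2)
})

test_that("fiber classification sits exactly at the >30 junction boundary", {
  n <- 0:60
  cls <- classify_fiber(n, node_threshold = 30)
  expect_equal(max(n[cls == "fine"]), 30)
  expect_equal(min(n[cls == "assembled"]), 31)
  expect_identical(classify_fiber(0), "fine")
  # monotone in n_junctions
  expect_false(is.unsorted(as.integer(factor(cls, c("fine", "assembled")))))
  # configurable threshold
  expect_identical(classify_fiber(11, node_threshold = 10), "assembled")
})

test_that("junction counts match ground truth on resolvable trees", {
  pairs <- do.call(rbind, lapply(1:15, junction_pairs))
  expect_gte(nrow(pairs), 5)
  expect_true(any(pairs[, "truth"] > 0))
  expect_equal(pairs[, "truth"], pairs[, "est"])
})

test_that("thinning is idempotent on its own output", {
  d <- demo_sample()
  sk <- fibroscope:::thin_mask_c(d$cm$mask)
  expect_identical(fibroscope:::thin_mask_c(sk), sk)
  yk <- fibroscope:::thin_mask_c(y_mask())
  expect_identical(fibroscope:::thin_mask_c(yk), yk)
})

test_that("per-fiber areas partition the mask on real segmentations", {
  d <- demo_sample()
  expect_equal(sum(d$rec$area_um2), sum(d$cm$mask) * d$cm$mpp^2)
})

test_that("fiber summaries handle empty and degenerate strata", {
  empty <- decompose_fibers(
    skeletonize_mask(collagen_mask(matrix(FALSE, 10, 10), 0.25)),
    collagen_mask(matrix(FALSE, 10, 10), 0.25))
  fsum <- fiber_summary(empty, area_mm2 = 1)
  expect_true(all(fsum$counts$n == 0))
  expect_true(all(is.na(fsum$stats$value)))
  # ten identical bars: sd 0, mean equal to the common value
  m <- matrix(FALSE, 220, 100)
  for (k in 0:9) m[20 * k + 3:5, 11:90] <- TRUE
  cm <- collagen_mask(m, 0.25)
  rec <- decompose_fibers(skeletonize_mask(cm), cm)
  expect_equal(nrow(rec), 10)
  fsum <- fiber_summary(rec, area_mm2 = 220 * 100 * 0.25^2 / 1e6)
  lm <- fsum$stats[fsum$stats$stratum == "all" &
                     fsum$stats$measure == "length_um", ]
  expect_equal(lm$value[lm$descriptor == "sd"], 0)
  expect_equal(lm$value[lm$descriptor == "mean"], rec$length_um[1])
})
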