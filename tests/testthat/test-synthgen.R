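test_that("empty and unbranched fiber sets have trivial ground truth", {
  fs0 <- make_fiber_set(fiber_params(n_fibers = 0, canvas = c(64, 64), seed = 1))
  expect_length(fs0$fibers, 0)
  expect_false(any(fs0$truth_mask))

  fs1 <- make_fiber_set(fiber_params(n_fibers = 1, branch_rate = 0,
                                     canvas = c(128, 128), seed = 3))
  expect_length(fs1$fibers, 1)
  expect_identical(fs1$fibers[[1]]$n_junctions, 0L)
})

test_that("parameter validation rejects impossible synthesis requests", {
  expect_error(fiber_params(n_fibers = -1), "n_fibers")
  expect_error(fiber_params(mpp = 0), "mpp")
  expect_error(fiber_params(branch_rate = -2), "branch_rate")
  expect_error(fiber_params(thickness_um = c(0.1, 0), mpp = 0.25), "thickness")
  # canvas too small for the requested mean stroke length
  p <- fiber_params(n_fibers = 1, length_um = c(500, 1), canvas = c(10, 10))
  expect_error(make_fiber_set(p), "too small")
})

test_that("branch events follow the Poisson arc-length expectation", {
  r <- 4
  J <- numeric(200); L <- numeric(200)
  for (s in seq_len(200)) {
    fs <- make_fiber_set(fiber_params(n_fibers = 5, length_um = c(40, 10),
                                      branch_rate = r, canvas = c(400, 400),
                                      seed = s))
    J[s] <- sum(vapply(fs$fibers, `[[`, numeric(1), "n_junctions"))
    L[s] <- sum(vapply(fs$fibers, `[[`, numeric(1), "length_um"))
  }
  expected <- r * mean(L) / 100
  se <- stats::sd(J) / sqrt(length(J))
  expect_lt(abs(mean(J) - expected), 3 * se)
})

test_that("generation is bit-identical under a fixed seed", {
  a <- make_fiber_set(fiber_params(n_fibers = 10, canvas = c(128, 128), seed = 42))
  b <- make_fiber_set(fiber_params(n_fibers = 10, canvas = c(128, 128), seed = 42))
  expect_identical(a, b)
  i1 <- render_trichrome(a, seed = 5)
  i2 <- render_trichrome(b, seed = 5)
  expect_identical(i1$pixels, i2$pixels)
})

test_that("footprint bookkeeping: union never exceeds the summed areas", {
  for (s in 1:5) {
    fs <- make_fiber_set(fiber_params(n_fibers = 8, canvas = c(256, 256),
                                      seed = 600 + s))
    areas <- vapply(fs$fibers, function(f) length(f$footprint_px), numeric(1))
    expect_gte(sum(areas), sum(fs$truth_mask))
  }
  # guaranteed-disjoint strokes (far-apart horizontal bands): equality
  a <- make_fiber_set(fiber_params(n_fibers = 1, length_um = c(10, 0.5),
                                   orientation_kappa = 200, mean_direction_deg = 0,
                                   wiggle_sd = 0, canvas = c(200, 200),
                                   start_rows = c(20, 40), seed = 7))
  b <- make_fiber_set(fiber_params(n_fibers = 1, length_um = c(10, 0.5),
                                   orientation_kappa = 200, mean_direction_deg = 0,
                                   wiggle_sd = 0, canvas = c(200, 200),
                                   start_rows = c(150, 170), seed = 8))
  both <- fibroscope:::combine_fiber_sets(a, b)
  areas <- vapply(both$fibers, function(f) length(f$footprint_px), numeric(1))
  expect_equal(sum(areas), sum(both$truth_mask))
})

test_that("rendering composes stains as programmed", {
  # empty set: no collagen signal beyond the noise floor
  fs0 <- make_fiber_set(fiber_params(n_fibers = 0, canvas = c(128, 128), seed = 1))
  img0 <- render_trichrome(fs0, seed = 2)
  maps0 <- deconvolve_stains(img0)
  expect_lt(max(maps0$collagen), 0.1)
  # single stroke: collagen OD above cytoplasm OD inside the footprint
  fs1 <- make_fiber_set(fiber_params(n_fibers = 1, branch_rate = 0,
                                     canvas = c(128, 128), seed = 3))
  img1 <- render_trichrome(fs1, seed = 2)
  m1 <- deconvolve_stains(img1)
  inm <- fs1$truth_mask
  expect_gte(mean(m1$collagen[inm] > m1$cytoplasm[inm]), 0.99)
  # empty regions white-balance near 255 (collagen-free, low-cytoplasm image)
  fsw <- make_fiber_set(fiber_params(n_fibers = 0, canvas = c(32, 32), seed = 1))
  imw <- render_trichrome(fsw, background = render_params(cytoplasm_od = 0.001,
                                                          noise_sd = 0),
                          seed = 9)
  expect_gt(min(imw$pixels), 250)
})

test_that("study bundles have the paired two-region layout", {
  d <- study_design(n_patients = 6, canvas = c(96, 96), seed = 21)
  b <- make_study(d)
  tab <- study_table(b)
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$region == "peri_papillary"), 6)
  expect_equal(sum(tab$region == "remote"), 6)
  # exactly one sample per patient x region
  expect_equal(nrow(unique(tab[, c("patient_id", "region")])), 12)
  expect_setequal(unique(b$samples[[1]]$rois$labels),
                  c("endocardium", "myocardium"))
})

test_that("the programmed thickness effect shows in the ground truth", {
  d <- study_design(n_patients = 10, canvas = c(96, 96),
                    endocardial_band_um = 0, seed = 31)
  b <- make_study(d)
  th <- function(region) {
    s <- b$samples[study_table(b)$region == region]
    mean(unlist(lapply(s, function(x)
      vapply(x$fibers$fibers, `[[`, numeric(1), "thickness_um"))))
  }
  ratio <- th("peri_papillary") / th("remote")
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("a null design makes the two regions exchangeable", {
  null_eff <- list(n_fibers = 1, thickness = 1, branch_rate = 1,
                   orientation_kappa = 1)
  d <- study_design(n_patients = 8, canvas = c(96, 96), effects = null_eff,
                    endocardial_band_um = 0, seed = 41)
  b <- make_study(d)
  tab <- study_table(b)
  n_fib <- vapply(b$samples, function(s) length(s$fibers$fibers), numeric(1))
  x <- n_fib[tab$region == "peri_papillary"]
  y <- n_fib[tab$region == "remote"]
  expect_gt(mann_whitney_u(x, y)$p, 0.01)
})
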