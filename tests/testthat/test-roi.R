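rect_poly <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

test_that("GeoJSON ROI files validate and round-trip", {
  rs <- roi_set(c("myocardium", "endocardium"),
                list(rect_poly(9.5, 49.5, 4.5, 24.5),
                     rect_poly(59.5, 79.5, 9.5, 39.5)))
  expect_length(rs$labels, 2)
  tmp <- withr::local_tempfile(fileext = ".geojson")
  write_rois(rs, tmp)
  rs2 <- load_rois(tmp)
  expect_equal(rs$labels, rs2$labels)
  for (i in seq_along(rs$polygons)) {
    expect_equal(rs$polygons[[i]], rs2$polygons[[i]],
                 ignore_attr = TRUE)
  }
})

test_that("invalid ROI inputs raise errors naming the feature", {
  r <- rect_poly(0, 10, 0, 10)
  expect_error(roi_set("stroma", list(r)), "unknown label 'stroma'")
  expect_error(roi_set("stroma", list(r)), "endocardium, myocardium")
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(roi_set("myocardium", list(bowtie)), "self-intersecting")
  expect_error(roi_set("myocardium", list(r[1:2, ])), "matrix|vertices")
  tmp <- withr::local_tempfile(fileext = ".geojson")
  writeLines("{not json", tmp)
  expect_error(load_rois(tmp), "malformed")
})

test_that("rasterization fills polygons with exact pixel areas", {
  rs <- roi_set(c("myocardium", "endocardium"),
                list(rect_poly(9.5, 49.5, 4.5, 24.5),    # 40 x 20
                     rect_poly(59.5, 79.5, 9.5, 39.5)))  # 20 x 30
  ras <- rasterize_compartments(rs, c(100, 100))
  expect_equal(sum(ras$labels == 1), 800)
  expect_equal(sum(ras$labels == 2), 600)
  # no polygons: everything unassigned
  none <- rasterize_compartments(roi_set(character(0), list()), c(20, 20))
  expect_true(all(none$labels == 0))
  # nested endocardium inside myocardium takes precedence
  rs2 <- roi_set(c("myocardium", "endocardium"),
                 list(rect_poly(-0.5, 89.5, -0.5, 89.5),
                      rect_poly(19.5, 49.5, 19.5, 49.5)))
  ras2 <- rasterize_compartments(rs2, c(90, 90))
  expect_equal(ras2$labels[30, 30], 2L)
  expect_equal(ras2$labels[5, 5], 1L)
})

test_that("compartment restriction follows the majority rule", {
  d <- demo_sample()
  full <- roi_set("myocardium",
                  list(rect_poly(-0.5, 255.5, -0.5, 255.5)))
  ras_full <- rasterize_compartments(full, dim(d$cm$mask))
  # whole-frame compartment: identity on the mask
  expect_identical(restrict_to_compartment(d$cm, ras_full, "myocardium")$mask,
                   d$cm$mask)
  expect_identical(restrict_to_compartment(d$cm, ras_full, "whole")$mask,
                   d$cm$mask)
  # fiber with 60% of its skeleton in the endocardium goes to endocardium
  rec <- data.frame(fiber_id = 1)
  rec$skeleton_px <- list(c(1:6, 101:104))  # rows 1..6 and 101..104 of col 1
  ras <- list(labels = matrix(0L, 200, 1), codes = c(unassigned = 0L,
                                                     myocardium = 1L,
                                                     endocardium = 2L))
  ras$labels[1:6, 1] <- 2L; ras$labels[101:104, 1] <- 1L
  class(ras) <- "compartment_raster"
  expect_identical(fiber_compartments(rec, ras), "endocardium")
})

test_that("tiling polygons partition the tissue and the fibers", {
  d <- demo_sample()
  h <- nrow(d$cm$mask); w <- ncol(d$cm$mask)
  rs <- roi_set(c("endocardium", "myocardium"),
                list(rect_poly(-0.5, w - 0.5, -0.5, 79.5),
                     rect_poly(-0.5, w - 0.5, 79.5, h - 0.5)))
  ras <- rasterize_compartments(rs, c(h, w))
  expect_true(all(ras$labels > 0))  # polygons tile the frame
  me <- restrict_to_compartment(d$cm, ras, "endocardium")$mask
  mm <- restrict_to_compartment(d$cm, ras, "myocardium")$mask
  expect_false(any(me & mm))
  expect_identical(me | mm, d$cm$mask)  # area conservation with equality
  comp <- fiber_compartments(d$rec, ras)
  expect_true(all(comp %in% c("endocardium", "myocardium")))
  n_e <- nrow(restrict_to_compartment(d$rec, ras, "endocardium"))
  n_m <- nrow(restrict_to_compartment(d$rec, ras, "myocardium"))
  expect_equal(n_e + n_m, nrow(d$rec))  # every fiber in exactly one place
})
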