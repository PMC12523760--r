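test_that("the trait catalog spans the documented grammar", {
  cat3 <- trait_catalog()
  expect_gte(nrow(cat3), 300)
  expect_equal(anyDuplicated(cat3$name), 0)
  # morphometry block: 8 bases x 7 descriptors x 3 strata per compartment
  morpho <- cat3[cat3$family == "morphometry" & cat3$compartment == "whole", ]
  expect_equal(nrow(morpho), 8 * 7 * 3)
  # every name parses back into its grammar parts
  parsed <- parse_trait_name(cat3$name)
  expect_equal(parsed$compartment, cat3$compartment)
  expect_equal(parsed$family, cat3$family)
  expect_equal(parsed$base, cat3$base)
  expect_equal(parsed$descriptor, cat3$descriptor)
  expect_equal(parsed$stratum, cat3$stratum)
  # directions declared for every trait; skewness is the only signed one
  expect_true(all(cat3$direction %in% c(-1, 1)))
  expect_setequal(unique(cat3$descriptor[cat3$signed]), "skewness")
})

test_that("area fraction matches a painted mask exactly", {
  m <- matrix(FALSE, 64, 64)
  m[1:32, 1:32] <- TRUE  # exactly 25% of the frame
  cm <- collagen_mask(m, 0.25)
  rec <- decompose_fibers(skeletonize_mask(cm), cm)
  em <- glcm_entropy_map(matrix(as.numeric(m), 64, 64), window = 64,
                         stride = 32, range = c(0, 1))
  tr <- extract_traits(cm, rec, em)
  expect_equal(unname(tr["whole.content.collagen.area_fraction"]), 0.25)
  expect_equal(unname(tr["whole.content.collagen.area_um2"]),
               32 * 32 * 0.25^2)
})

test_that("zero fibers give zero content and missing morphometry", {
  cm <- collagen_mask(matrix(FALSE, 64, 64), 0.25)
  rec <- decompose_fibers(skeletonize_mask(cm), cm)
  em <- glcm_entropy_map(matrix(0, 64, 64), window = 64, stride = 32,
                         range = c(0, 1))
  tr <- extract_traits(cm, rec, em)
  expect_equal(unname(tr["whole.content.collagen.area_fraction"]), 0)
  expect_equal(unname(tr["whole.content.objects.density_per_mm2"]), 0)
  expect_true(is.na(tr["whole.content.objects.nodularity"]))
  expect_true(all(is.na(tr[grep("morphometry", names(tr))])))
})

test_that("identical fibers collapse the descriptors", {
  m <- matrix(FALSE, 220, 100)
  for (k in 0:9) m[20 * k + 3:5, 11:90] <- TRUE
  cm <- collagen_mask(m, 0.25)
  rec <- decompose_fibers(skeletonize_mask(cm), cm)
  em <- glcm_entropy_map(matrix(as.numeric(m), 220, 100), window = 64,
                         stride = 32, range = c(0, 1))
  tr <- extract_traits(cm, rec, em)
  expect_equal(unname(tr["whole.morphometry.length.sd.all"]), 0)
  true_len <- 80 * 0.25
  expect_lt(abs(tr["whole.morphometry.length.mean.all"] / true_len - 1), 0.05)
})

test_that("extraction emits exactly the catalog names per compartment", {
  d <- demo_sample()
  tr <- extract_traits(d$cm, d$rec, d$em)
  expect_setequal(names(tr),
                  trait_catalog(compartments = "whole")$name)
})

test_that("whole equals the compartment sum when polygons tile the frame", {
  d <- demo_sample()
  h <- nrow(d$cm$mask); w <- ncol(d$cm$mask)
  rs <- roi_set(c("endocardium", "myocardium"),
                list(cbind(c(-0.5, w - 0.5, w - 0.5, -0.5),
                           c(-0.5, -0.5, 79.5, 79.5)),
                     cbind(c(-0.5, w - 0.5, w - 0.5, -0.5),
                           c(79.5, 79.5, h - 0.5, h - 0.5))))
  ras <- rasterize_compartments(rs, c(h, w))
  tr <- extract_traits(d$cm, d$rec, d$em, compartments = ras)
  expect_equal(unname(tr["whole.content.collagen.area_um2"]),
               unname(tr["myocardium.content.collagen.area_um2"] +
                        tr["endocardium.content.collagen.area_um2"]))
})

test_that("traits scale correctly under an mpp change", {
  fs <- make_fiber_set(fiber_params(n_fibers = 20, canvas = c(200, 200),
                                    seed = 4))
  mk <- fs$truth_mask
  at <- function(mpp) {
    cm <- collagen_mask(mk, mpp)
    rec <- decompose_fibers(skeletonize_mask(cm), cm)
    em <- glcm_entropy_map(matrix(as.numeric(mk), 200, 200), window = 64,
                          stride = 32, range = c(0, 1))
    extract_traits(cm, rec, em)
  }
  a <- at(0.25); b <- at(0.5)
  # length-typed traits double
  expect_equal(unname(b["whole.morphometry.length.mean.all"]),
               2 * unname(a["whole.morphometry.length.mean.all"]))
  expect_equal(unname(b["whole.morphometry.width_mean.mean.all"]),
               2 * unname(a["whole.morphometry.width_mean.mean.all"]))
  # area-typed traits quadruple
  expect_equal(unname(b["whole.content.collagen.area_um2"]),
               4 * unname(a["whole.content.collagen.area_um2"]))
  # densities scale with 1/area
  expect_equal(unname(b["whole.architecture.fibers.density_per_mm2.all"]),
               unname(a["whole.architecture.fibers.density_per_mm2.all"]) / 4)
  # dimensionless traits unchanged
  for (nm in c("whole.content.collagen.area_fraction",
               "whole.morphometry.continuity.mean.all",
               "whole.architecture.orientation.order_parameter",
               "whole.architecture.entropy.mean")) {
    expect_equal(unname(b[nm]), unname(a[nm]), tolerance = 1e-8)
  }
})
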