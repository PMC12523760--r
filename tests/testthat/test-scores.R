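test_that("group mean change follows the stated arithmetic", {
  reg <- rep(c("peri_papillary", "remote"), each = 3)
  expect_equal(group_mean_change(c(6, 6, 6, 4, 4, 4), reg), 50)
  expect_equal(group_mean_change(c(4, 4, 4, 4, 4, 4), reg), 0)
  expect_equal(group_mean_change(c(0, 0, 0, 0, 0, 0), reg), 0)
  expect_identical(group_mean_change(c(1, 1, 1, 0, 0, 0), reg), Inf)
  expect_error(group_mean_change(c(3, 3, 3, -2, -2, -2), reg), "negative")
  # signed traits (skewness) bypass the domain check
  expect_equal(group_mean_change(c(3, 3, 3, -2, -2, -2), reg,
                                 nonnegative = FALSE), 250)
})

test_that("the exact Mann-Whitney branch reproduces enumeration", {
  m <- mann_whitney_u(1:3, 4:6)
  expect_equal(m$U, 0)
  expect_equal(m$p, 0.1)  # 2 of choose(6,3) = 20 assignments as extreme
  expect_identical(m$method, "exact")
  m2 <- mann_whitney_u(1:6, 7:12)
  expect_equal(m2$p, 2 / choose(12, 6))
  # exchangeable multisets: p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(2, 1, 3))$p, 1)
  # all identical: U = n1 n2 / 2, p = 1
  md <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(md$U, 10)
  expect_equal(md$p, 1)
})

test_that("exact p matches brute-force enumeration over random cases", {
  set.seed(91)
  for (i in seq_len(1000)) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    m <- mann_whitney_u(x, y)
    expect_equal(m$p, brute_mwu_p(x, y), tolerance = 1e-12)
    # U identity: U_x + U_y = n1 * n2
    expect_equal(m$U + mann_whitney_u(y, x)$U, n1 * n2)
  }
})

test_that("exact and normal branches agree for 6 vs 6", {
  set.seed(92)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6)
    pe <- mann_whitney_u(x, y)$p
    pn <- mann_whitney_u(x, y, exact_max = 0)$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("selection applies both the change and significance gates", {
  catalog <- trait_catalog(compartments = "whole")
  study <- data.frame(sample_id = sprintf("s%d", 1:12),
                      region = rep(c("peri_papillary", "remote"), each = 6))
  base <- "whole.content.collagen.area_fraction"
  mk_traits <- function(x, y) {
    df <- data.frame(sample_id = study$sample_id)
    df[[base]] <- c(x, y)
    df
  }
  # large change but weak significance: not selected
  t1 <- mk_traits(c(6, 1, 7, 2, 8, 3), c(4, 4, 4, 4, 4, 4) * 0.8)
  s1 <- select_traits(t1, study, catalog)
  expect_gt(abs(s1$delta_pct), 20)
  expect_gt(s1$p, 0.05)
  expect_false(s1$selected)
  # significant but below the 20% change floor: not selected
  t2 <- mk_traits(119:124 / 100, 100:105 / 100)
  s2 <- select_traits(t2, study, catalog)
  expect_lt(s2$p, 0.05)
  expect_lt(abs(s2$delta_pct), 20)
  expect_false(s2$selected)
  # both gates pass: selected
  t3 <- mk_traits(2:7, c(1, 1.1, 1.2, 1.3, 1.4, 1.5))
  s3 <- select_traits(t3, study, catalog)
  expect_true(s3$selected)
  # the literal "p > alpha" reading is available as a config
  s1g <- select_traits(t1, study, catalog, p_rule = "greater")
  expect_true(s1g$selected)
})

test_that("normalization is min-max on oriented traits", {
  catalog <- trait_catalog(compartments = "whole")
  df <- data.frame(sample_id = c("a", "b", "c"))
  df[["whole.content.collagen.area_fraction"]] <- c(2, 4, 6)
  df[["whole.content.collagen.area_um2"]] <- c(5, 5, 5)
  norm <- normalize_traits(df, names(df)[-1], catalog)
  expect_equal(norm[["whole.content.collagen.area_fraction"]], c(0, 0.5, 1))
  # constant trait dropped with a record
  expect_null(norm[["whole.content.collagen.area_um2"]])
  expect_equal(attr(norm, "dropped_constant"),
               "whole.content.collagen.area_um2")
  # affine rescaling leaves the normalized column unchanged
  df2 <- df
  df2[["whole.content.collagen.area_fraction"]] <-
    3 * df[["whole.content.collagen.area_fraction"]] + 7
  norm2 <- normalize_traits(df2, "whole.content.collagen.area_fraction", catalog)
  expect_equal(norm2[["whole.content.collagen.area_fraction"]], c(0, 0.5, 1))
  # negative-direction traits are flipped before scaling
  df3 <- data.frame(sample_id = c("a", "b", "c"))
  df3[["whole.architecture.orientation.order_parameter"]] <- c(0.2, 0.5, 0.8)
  norm3 <- normalize_traits(df3, names(df3)[2], catalog)
  expect_equal(norm3[[2]], c(1, 0.5, 0))
})

test_that("composite scores are equi-weighted family means on [0, scale]", {
  catalog <- trait_catalog(compartments = "whole")
  study <- data.frame(sample_id = c("a", "b"),
                      region = c("peri_papillary", "remote"))
  df <- data.frame(sample_id = c("a", "b"))
  df[["whole.content.collagen.area_fraction"]] <- c(1, 0)
  sel <- data.frame(trait = "whole.content.collagen.area_fraction",
                    family = "content", stratum = NA_character_,
                    selected = TRUE)
  norm <- df
  cs <- composite_scores(norm, sel, study, scale = 10)
  expect_equal(cs$scores$phfcs, c(10, 0))
  expect_equal(cs$scores$ccs, c(10, 0))
  expect_true(is.na(cs$scores$mcs[1]))  # empty family flagged, still reported
  expect_setequal(c("phfcs", "ccs", "mcs", "acs"),
                  intersect(cs$group_stats$score,
                            c("phfcs", "ccs", "mcs", "acs")))
})

test_that("composites are monotone and permutation invariant", {
  catalog <- trait_catalog(compartments = "whole")
  set.seed(93)
  study <- data.frame(sample_id = sprintf("s%d", 1:12),
                      region = rep(c("peri_papillary", "remote"), each = 6))
  df <- data.frame(sample_id = study$sample_id)
  nm1 <- "whole.morphometry.length.mean.all"
  nm2 <- "whole.morphometry.width_mean.mean.all"
  df[[nm1]] <- c(rnorm(6, 10), rnorm(6, 5))
  df[[nm2]] <- c(rnorm(6, 4), rnorm(6, 2))
  run <- function(d) {
    sel <- select_traits(d, study, catalog)
    norm <- normalize_traits(d, sel$trait[sel$selected], catalog)
    composite_scores(norm, sel, study)
  }
  cs <- run(df)
  # raising one positively-oriented selected trait for one sample never
  # lowers that sample's family score
  df_up <- df
  df_up[[nm1]][1] <- df_up[[nm1]][1] + 5
  cs_up <- run(df_up)
  expect_gte(cs_up$scores$mcs[1], cs$scores$mcs[1])
  # permuting sample order changes nothing
  perm <- sample(12)
  dfp <- df[perm, ]; studyp <- study[perm, ]
  csp <- {
    sel <- select_traits(dfp, studyp, catalog)
    norm <- normalize_traits(dfp, sel$trait[sel$selected], catalog)
    composite_scores(norm, sel, studyp)
  }
  expect_equal(csp$scores$mcs[match(cs$scores$sample_id, csp$scores$sample_id)],
               cs$scores$mcs)
  expect_equal(csp$group_stats$p, cs$group_stats$p)
})

test_that("significance stars match the figure convention", {
  expect_identical(significance_stars(c(0.042, 0.009, 0.2, NA)),
                   c("*", "**", "", ""))
})
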