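# Shared fixtures: analytic masks with known geometry, a cached synthetic
# sample, and independent oracles (brute-force Mann-Whitney, rank AUC).

# digital bar of given angle (degrees), length and width (pixels), centred
# on an n x n canvas
bar_mask <- function(theta_deg, len = 140, wid = 3, n = 200) {
  mm <- matrix(FALSE, n, n)
  t <- seq(-len / 2, len / 2, by = 0.25)
  r <- round(n / 2 - t * sin(theta_deg * pi / 180))
  c <- round(n / 2 + t * cos(theta_deg * pi / 180))
  hw <- floor((wid - 1) / 2)
  for (k in seq_along(t)) mm[r[k] + (-hw:hw), c[k] + (-hw:hw)] <- TRUE
  mm
}

# three bars meeting at one point ("Y"), 3 px thick
y_mask <- function(n = 100) {
  y <- matrix(FALSE, n, n)
  y[n / 2, 10:(n / 2)] <- TRUE
  for (i in 0:35) {
    y[n / 2 - i, n / 2 + i] <- TRUE
    y[n / 2 + i, n / 2 + i] <- TRUE
  }
  yd <- EBImage::dilate(y * 1, EBImage::makeBrush(3, "box"))
  matrix(yd > 0.5, n, n)
}

# rank AUC of positives vs negatives
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# brute-force two-sided exact Mann-Whitney p by enumerating all
# choose(n1+n2, n1) group assignments (independent of the package's
# counting recursion)
brute_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  rk <- rank(pool)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(rk[ii]) - n1 * (n1 + 1) / 2)
  mean(abs(us - n1 * n2 / 2) >= abs(u_obs - n1 * n2 / 2) - 1e-9)
}

# A fiber tree is geometrically resolvable when its branch points are
# mutually separated and no two limbs approach each other (away from their
# shared branch point) closer than the stroke diameter; only such trees are
# valid oracles for skeleton junction counting. Decided from ground truth
# alone, never from the measurement.
tree_resolvable <- function(f) {
  hw <- f$half_width_px
  bp <- f$branch_points
  if (nrow(bp) >= 2 && min(stats::dist(bp)) < 6 * hw) return(FALSE)
  # a branch event at a limb tip makes a kink, not a junction: the stub is
  # shorter than thinning erosion plus spur pruning can resolve
  for (b in seq_len(nrow(bp))) {
    for (L in f$limbs) {
      tips <- rbind(L[1, ], L[nrow(L), ])
      d <- sqrt((tips[, 1] - bp[b, 1])^2 + (tips[, 2] - bp[b, 2])^2)
      d <- d[d > 1e-9]  # the child limb starts at the branch point itself
      if (length(d) && min(d) < 4 * hw + 4) return(FALSE)
    }
  }
  n <- length(f$limbs)
  if (n < 2) return(TRUE)
  excl2 <- (6 * hw)^2       # ignore points near any branch point
  min_clear <- 2 * hw + 2   # limbs must stay a stroke diameter apart
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      A <- f$limbs[[i]]; B <- f$limbs[[j]]
      keep <- function(P) {
        k <- rep(TRUE, nrow(P))
        for (b in seq_len(nrow(bp))) {
          k <- k & ((P[, 1] - bp[b, 1])^2 + (P[, 2] - bp[b, 2])^2 > excl2)
        }
        k
      }
      A <- A[keep(A), , drop = FALSE]; B <- B[keep(B), , drop = FALSE]
      if (nrow(A) == 0 || nrow(B) == 0) next
      d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
      if (min(d2) < min_clear^2) return(FALSE)
    }
  }
  TRUE
}

# collect (truth, estimate) junction pairs for resolvable, non-overlapping,
# interior fiber trees of one synthetic set
junction_pairs <- function(seed, n_fibers = 4, canvas = 400) {
  fs <- make_fiber_set(fiber_params(n_fibers = n_fibers, length_um = c(50, 8),
                                    thickness_um = c(1, 0.1), branch_rate = 3,
                                    orientation_kappa = 0, wiggle_sd = 0,
                                    canvas = c(canvas, canvas), seed = seed))
  cm <- collagen_mask(fs$truth_mask, 0.25)
  g <- skeletonize_mask(cm)
  rec <- decompose_fibers(g, cm)
  cnt <- matrix(0L, canvas, canvas)
  for (f in fs$fibers) cnt[f$footprint_px] <- cnt[f$footprint_px] + 1L
  pairs <- NULL
  for (f in fs$fibers) {
    if (any(cnt[f$footprint_px] > 1)) next
    rs <- (f$footprint_px - 1) %% canvas + 1
    cs <- (f$footprint_px - 1) %/% canvas + 1
    if (min(rs, cs) <= 2 || max(rs) >= canvas - 1 || max(cs) >= canvas - 1) next
    if (!tree_resolvable(f)) next
    ci <- g$labels[f$footprint_px[1]]
    pairs <- rbind(pairs, c(truth = f$n_junctions,
                            est = rec$n_junctions[rec$fiber_id == ci]))
  }
  pairs
}

# one cached synthetic sample shared by round-trip tests
.fx <- new.env(parent = emptyenv())
demo_sample <- function() {
  if (!is.null(.fx$demo)) return(.fx$demo)
  fs <- make_fiber_set(fiber_params(n_fibers = 30, canvas = c(256, 256),
                                    seed = 501))
  img <- render_trichrome(fs, seed = 502, sample_id = "demo")
  maps <- deconvolve_stains(img)
  tis <- tissue_mask(img)
  cm <- clean_mask(segment_collagen(maps$collagen, "otsu", tissue = tis,
                                    mpp = img$mpp))
  g <- skeletonize_mask(cm)
  rec <- decompose_fibers(g, cm)
  em <- glcm_entropy_map(maps$collagen, tissue = tis)
  .fx$demo <- list(fs = fs, img = img, maps = maps, tis = tis, cm = cm,
                   g = g, rec = rec, em = em)
  .fx$demo
}
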