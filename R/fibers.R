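#' Decompose a skeletonized mask into per-fiber records
#'
#' One fiber record is produced per connected mask component (a branched
#' collagen network counts as a single fiber object). Geometry is measured
#' on the skeleton graph; widths come from the Euclidean distance transform
#' of the mask sampled at skeleton pixels (width = 2 x EDT x mpp); every
#' mask pixel belongs to exactly one fiber, so fiber areas partition the
#' mask area.
#'
#' @param g a [skeletonize_mask()] graph
#' @param cm the [collagen_mask()] the graph was built from
#' @param node_threshold junction-count boundary for the fine/assembled
#'   class rule, passed to [classify_fiber()]
#' @return data.frame with one row per fiber: `fiber_id`, `length_um`,
#'   `n_junctions`, `n_endpoints`, `width_mean_um`, `width_max_um`,
#'   `orientation_deg`, `continuity`, `straightness`, `area_um2`,
#'   `fiber_class`, plus a list column `skeleton_px` of skeleton pixel
#'   indices used for compartment assignment
#' @export
decompose_fibers <- function(g, cm, node_threshold = 30) {
  stopifnot(inherits(g, "skeleton_graph"), inherits(cm, "collagen_mask"))
  mask <- cm$mask
  h <- nrow(mask)
  if (!any(mask)) {
    out <- data.frame(fiber_id = integer(), length_um = numeric(),
                      n_junctions = integer(), n_endpoints = integer(),
                      width_mean_um = numeric(), width_max_um = numeric(),
                      orientation_deg = numeric(), continuity = numeric(),
                      straightness = numeric(), area_um2 = numeric(),
                      fiber_class = character())
    out$skeleton_px <- list()
    return(out)
  }
  lab <- g$labels
  mpp <- g$mpp
  dt <- as_matrix(EBImage::distmap(mask * 1))
  stats <- skeleton_component_stats(g)
  comps <- seq_len(max(lab))
  areas_px <- tabulate(lab[lab > 0], nbins = max(lab))
  skel_px <- which(g$skeleton)
  skel_comp <- lab[skel_px]

  rows <- lapply(comps, function(ci) {
    spx <- skel_px[skel_comp == ci]
    st <- stats[match(ci, stats$comp), ]
    len_px <- if (!is.na(st$comp)) st$length_px else 0
    # single-anchor components carry the extent of their one pixel
    len_um <- max(len_px, 1) * mpp
    widths <- 2 * dt[spx] * mpp
    rs <- (spx - 1L) %% h + 1L; cs <- (spx - 1L) %/% h + 1L
    ori <- principal_orientation_deg(rs, cs)
    cont <- if (!is.na(st$comp) && st$length_px > 0) {
      min(1, st$longest_path_px / st$length_px)
    } else 1
    strt <- if (!is.na(st$comp) && st$longest_path_px > 0) {
      min(1, st$longest_chord_px / st$longest_path_px)
    } else 1
    data.frame(fiber_id = ci,
               length_um = len_um,
               n_junctions = if (!is.na(st$comp)) st$n_junctions else 0L,
               n_endpoints = if (!is.na(st$comp)) st$n_endpoints else 1L,
               width_mean_um = mean(widths),
               width_max_um = max(widths),
               orientation_deg = ori,
               continuity = cont,
               straightness = strt,
               area_um2 = areas_px[ci] * mpp^2)
  })
  out <- do.call(rbind, rows)
  out$fiber_class <- classify_fiber(out$n_junctions, node_threshold)
  out$skeleton_px <- lapply(comps, function(ci) skel_px[skel_comp == ci])
  out
}

#' Assign fibers to the fine or assembled structural class
#'
#' Assembled fibers are thick, bundled collagen networks identified by their
#' junction (node/branch point) count: a fiber is `assembled` when its
#' junction count strictly exceeds `node_threshold` (default 30), otherwise
#' `fine`. Only the junction-count rule is used; thickness is reported as a
#' trait but plays no part in the class assignment.
#'
#' @param n_junctions integer vector of per-fiber junction counts, or a
#'   data.frame with an `n_junctions` column
#' @param node_threshold class boundary (default 30; > threshold = assembled)
#' @return character vector, `"fine"` or `"assembled"`
#' @export
classify_fiber <- function(n_junctions, node_threshold = 30) {
  if (is.data.frame(n_junctions)) n_junctions <- n_junctions$n_junctions
  ifelse(n_junctions > node_threshold, "assembled", "fine")
}

#' Per-stratum fiber population summaries
#'
#' Summarizes per-fiber measures for the full population and for the fine
#' and assembled strata separately: counts, count density, and distribution
#' descriptors (mean, median, sd, skewness, kurtosis, p10, p90). Empty
#' strata report count 0 and NA descriptors, never silent zeros.
#'
#' @param records a [decompose_fibers()] data.frame
#' @param area_mm2 reference area for count densities, square millimeters
#' @param strata which strata to report
#' @return list with `counts` (stratum, n, density_per_mm2) and `stats`
#'   (long data.frame: stratum, measure, descriptor, value)
#' @export
fiber_summary <- function(records, area_mm2 = NA_real_,
                          strata = c("all", "fine", "assembled")) {
  measures <- c("length_um", "width_mean_um", "width_max_um", "area_um2",
                "n_junctions", "n_endpoints", "continuity", "straightness",
                "orientation_deg")
  counts <- data.frame(stratum = strata,
                       n = NA_integer_, density_per_mm2 = NA_real_)
  stats_rows <- list()
  for (s in strata) {
    sub <- if (s == "all") records else records[records$fiber_class == s, , drop = FALSE]
    counts$n[counts$stratum == s] <- nrow(sub)
    counts$density_per_mm2[counts$stratum == s] <-
      if (is.na(area_mm2)) NA_real_ else nrow(sub) / area_mm2
    for (m in measures) {
      d <- describe_values(sub[[m]])
      stats_rows[[length(stats_rows) + 1]] <-
        data.frame(stratum = s, measure = m, descriptor = names(d),
                   value = unname(d))
    }
  }
  list(counts = counts, stats = do.call(rbind, stats_rows))
}
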