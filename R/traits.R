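# The quantitative fibrosis trait (qFT) catalog and its extraction.
#
# Trait names follow the grammar
#   <compartment>.<family>.<base>.<descriptor>[.<stratum>]
# with compartment in {whole, myocardium, endocardium}, family in
# {content, morphometry, architecture}. The catalog is an open
# re-derivation spanning the same three families as commercial fibrosis
# phenotyping platforms; it is documented as non-identical to any
# proprietary nomenclature.

COMPARTMENTS <- c("whole", "myocardium", "endocardium")
MORPHO_BASES <- c("length", "width_mean", "width_max", "area", "n_junctions",
                  "n_endpoints", "continuity", "straightness")
MORPHO_DESCRIPTORS <- c("mean", "median", "sd", "skewness", "kurtosis",
                        "p10", "p90")
MORPHO_STRATA <- c("all", "fine", "assembled")

.morpho_units <- c(length = "um", width_mean = "um", width_max = "um",
                   area = "um2", n_junctions = "count", n_endpoints = "count",
                   continuity = "fraction", straightness = "fraction")

#' Enumerate the quantitative fibrosis trait catalog
#'
#' Builds the full trait catalog across compartments:
#' * content: collagen area fraction and absolute area, object count
#'   density, nodularity (mean object solidity x roundness), object area
#'   mean and p90;
#' * morphometry: per-fiber length, widths, area, junction and endpoint
#'   counts, continuity and straightness, each summarized by 7 descriptors
#'   over the all/fine/assembled strata;
#' * architecture: class-resolved fiber count densities, assembled-fiber
#'   area fraction, orientation order parameter, orientation entropy,
#'   length-weighted alignment coherence, and the GLCM entropy traits.
#'
#' Each trait declares a direction: `+1` when larger values indicate more
#' severe fibrosis, `-1` otherwise (the orientation order and coherence
#' traits, where stronger alignment reflects mature organized scar is
#' arguable; both are config-overridable downstream). `signed` marks the
#' only descriptor that may go negative (skewness).
#'
#' @param compartments compartments to enumerate (default all three)
#' @return data.frame of class `trait_catalog`: `name`, `compartment`,
#'   `family`, `base`, `descriptor`, `stratum`, `units`, `direction`,
#'   `signed`
#' @export
trait_catalog <- function(compartments = COMPARTMENTS) {
  rows <- list()
  add <- function(compartment, family, base, descriptor, stratum, units,
                  direction = 1, signed = FALSE) {
    nm <- paste(c(compartment, family, base, descriptor, stratum), collapse = ".")
    rows[[length(rows) + 1]] <<- data.frame(
      name = nm, compartment = compartment, family = family, base = base,
      descriptor = descriptor, stratum = stratum %||% NA_character_,
      units = units, direction = direction, signed = signed)
  }
  for (cp in compartments) {
    # content family
    add(cp, "content", "collagen", "area_fraction", NULL, "fraction")
    add(cp, "content", "collagen", "area_um2", NULL, "um2")
    add(cp, "content", "objects", "density_per_mm2", NULL, "per_mm2")
    add(cp, "content", "objects", "nodularity", NULL, "fraction")
    add(cp, "content", "objects", "area_mean", NULL, "um2")
    add(cp, "content", "objects", "area_p90", NULL, "um2")
    # morphometry family: 8 bases x 7 descriptors x 3 strata. Severity
    # directions: widths and junction counts rise as collagen matures and
    # bundles; continuity (the unbranched-path fraction) *falls* as
    # networks reticulate, at every stratum; fine-stratum length and area
    # fall because large fine fibers are recruited into assembled networks,
    # leaving small fragments (fine *density* stays positively oriented in
    # the architecture family).
    for (b in MORPHO_BASES) {
      for (dsc in MORPHO_DESCRIPTORS) {
        for (st in MORPHO_STRATA) {
          dir <- 1
          if (b == "continuity") dir <- -1
          if (st == "fine" && b %in% c("length", "area")) dir <- -1
          add(cp, "morphometry", b, dsc, st,
              units = if (dsc %in% c("skewness", "kurtosis")) "dimensionless"
                      else .morpho_units[[b]],
              direction = dir,
              signed = dsc == "skewness")
        }
      }
    }
    # architecture family
    for (st in MORPHO_STRATA) {
      add(cp, "architecture", "fibers", "density_per_mm2", st, "per_mm2")
    }
    add(cp, "architecture", "assembled", "area_fraction", NULL, "fraction")
    add(cp, "architecture", "orientation", "order_parameter", NULL,
        "fraction", direction = -1)
    add(cp, "architecture", "orientation", "entropy", NULL, "bits")
    add(cp, "architecture", "orientation", "coherence", NULL, "fraction",
        direction = -1)
    add(cp, "architecture", "entropy", "mean", NULL, "bits")
    add(cp, "architecture", "entropy", "sd", NULL, "bits")
    add(cp, "architecture", "entropy", "p90", NULL, "bits")
    add(cp, "architecture", "entropy", "high_fraction", NULL, "fraction")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("trait_catalog", "data.frame")
  out
}

#' Parse trait names back into their grammar parts
#'
#' @param names character vector of trait names
#' @return data.frame with `compartment`, `family`, `base`, `descriptor`,
#'   `stratum` (NA when absent)
#' @export
parse_trait_name <- function(names) {
  parts <- strsplit(names, ".", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) {
    if (length(p) < 4 || length(p) > 5) {
      abort("trait name '%s' does not parse", paste(p, collapse = "."))
    }
    data.frame(compartment = p[1], family = p[2], base = p[3],
               descriptor = p[4],
               stratum = if (length(p) == 5) p[5] else NA_character_)
  }))
}

# content-family statistics of one compartment's collagen mask
.content_traits <- function(cmask_mx, comp_area_px, mpp) {
  out <- c(area_fraction = NA_real_, area_um2 = NA_real_,
           density_per_mm2 = NA_real_, nodularity = NA_real_,
           area_mean = NA_real_, area_p90 = NA_real_)
  if (comp_area_px == 0) return(out)
  area_px <- sum(cmask_mx)
  comp_mm2 <- comp_area_px * mpp^2 / 1e6
  out["area_fraction"] <- area_px / comp_area_px
  out["area_um2"] <- area_px * mpp^2
  if (area_px == 0) {
    out["density_per_mm2"] <- 0
    return(out)  # no objects: shape statistics undefined, not zero
  }
  lab <- as_matrix(EBImage::bwlabel(cmask_mx * 1))
  nobj <- max(lab)
  areas <- tabulate(lab[lab > 0], nbins = nobj)
  out["density_per_mm2"] <- nobj / comp_mm2
  out["area_mean"] <- mean(areas) * mpp^2
  out["area_p90"] <- stats::quantile(areas, 0.9, names = FALSE) * mpp^2
  fs <- EBImage::computeFeatures.shape(lab)
  per <- fs[, "s.perimeter"]
  roundness <- pmin(1, 4 * pi * areas / pmax(per, 1)^2)
  h <- nrow(lab)
  px_by <- split(which(lab > 0), lab[lab > 0])
  solidity <- vapply(seq_len(nobj), function(i) {
    px <- px_by[[as.character(i)]]
    if (length(px) < 3) return(1)
    rs <- (px - 1L) %% h + 1L; cs <- (px - 1L) %/% h + 1L
    hull <- grDevices::chull(cs, rs)
    hx <- cs[hull]; hy <- rs[hull]
    ha <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    # hull of pixel centers: add half the hull perimeter + 1 (Pick-style
    # boundary correction) so solidity of convex blobs is ~1
    hp <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    min(1, length(px) / (ha + hp / 2 + 1))
  }, numeric(1))
  out["nodularity"] <- mean(solidity * roundness)
  out
}

# circular statistics of fiber orientations (axial, degrees in [0, 180))
.orientation_traits <- function(ori_deg, weights = NULL) {
  ori <- ori_deg[is.finite(ori_deg)]
  if (length(ori) == 0) {
    return(c(order_parameter = NA_real_, entropy = NA_real_,
             coherence = NA_real_))
  }
  a2 <- 2 * ori * pi / 180
  order_par <- sqrt(mean(cos(a2))^2 + mean(sin(a2))^2)
  w <- if (is.null(weights)) rep(1, length(ori_deg)) else weights
  w <- w[is.finite(ori_deg)]
  w <- w / sum(w)
  coher <- sqrt(sum(w * cos(a2))^2 + sum(w * sin(a2))^2)
  bins <- cut(ori, breaks = seq(0, 180, by = 10), include.lowest = TRUE)
  p <- tabulate(bins, nbins = 18)
  p <- p / sum(p)
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  c(order_parameter = order_par, entropy = ent, coherence = coher)
}

#' Extract all quantitative fibrosis traits of one sample
#'
#' Computes every catalog trait for each requested compartment. Area and
#' density traits use the compartment area as denominator; fibers are
#' assigned whole to one compartment by the majority of their skeleton
#' pixels; entropy traits summarize the windows whose centers fall inside
#' the compartment. Traits that are undefined on the data (e.g. the sd of a
#' single fiber, shape statistics of an empty mask, or any trait of a
#' zero-area compartment) are NA, never silent zeros.
#'
#' @param cm the cleaned [collagen_mask()]
#' @param records the [decompose_fibers()] table
#' @param emap the [glcm_entropy_map()] of the collagen channel
#' @param compartments a [rasterize_compartments()] raster, or `NULL` for
#'   whole-biopsy analysis only
#' @param tissue logical tissue mask (default: whole canvas)
#' @param which_compartments compartments to emit (subset of
#'   whole/myocardium/endocardium; non-whole entries need `compartments`)
#' @param high_quantile high-entropy cutoff passed to [entropy_traits()]
#' @return named numeric vector of traits (catalog order), with the sample
#'   id of `cm` as attribute `sample_id`
#' @export
extract_traits <- function(cm, records, emap, compartments = NULL,
                           tissue = NULL,
                           which_compartments = if (is.null(compartments))
                             "whole" else COMPARTMENTS,
                           high_quantile = 0.75) {
  stopifnot(inherits(cm, "collagen_mask"))
  mpp <- cm$mpp
  h <- nrow(cm$mask); w <- ncol(cm$mask)
  if (is.null(tissue)) tissue <- matrix(TRUE, h, w)
  fiber_comp <- if (!is.null(compartments)) {
    fiber_compartments(records, compartments)
  } else {
    rep("whole", nrow(records))
  }
  ctr <- entropy_window_centers(emap)
  ctr_px <- cbind(round(rep(ctr$rows, times = length(ctr$cols))),
                  round(rep(ctr$cols, each = length(ctr$rows))))
  ctr_idx <- (pmin(ctr_px[, 2], w) - 1) * h + pmin(ctr_px[, 1], h)

  out <- numeric(0)
  for (cp in which_compartments) {
    if (cp != "whole" && is.null(compartments)) {
      abort("compartment '%s' requested without ROI raster", cp)
    }
    comp_sel <- switch(cp,
                       whole = tissue,
                       myocardium = tissue & compartments$labels == 1L,
                       endocardium = tissue & compartments$labels == 2L)
    comp_area_px <- sum(comp_sel)
    comp_mm2 <- comp_area_px * mpp^2 / 1e6
    cmask <- cm$mask & comp_sel
    vals <- c()

    # content
    ct <- .content_traits(cmask, comp_area_px, mpp)
    vals[paste(cp, "content", "collagen", "area_fraction", sep = ".")] <- ct["area_fraction"]
    vals[paste(cp, "content", "collagen", "area_um2", sep = ".")] <- ct["area_um2"]
    vals[paste(cp, "content", "objects", "density_per_mm2", sep = ".")] <- ct["density_per_mm2"]
    vals[paste(cp, "content", "objects", "nodularity", sep = ".")] <- ct["nodularity"]
    vals[paste(cp, "content", "objects", "area_mean", sep = ".")] <- ct["area_mean"]
    vals[paste(cp, "content", "objects", "area_p90", sep = ".")] <- ct["area_p90"]

    # morphometry
    sub_all <- if (cp == "whole") records else
      records[fiber_comp == cp, , drop = FALSE]
    col_of <- c(length = "length_um", width_mean = "width_mean_um",
                width_max = "width_max_um", area = "area_um2",
                n_junctions = "n_junctions", n_endpoints = "n_endpoints",
                continuity = "continuity", straightness = "straightness")
    for (st in MORPHO_STRATA) {
      sub <- if (st == "all") sub_all else
        sub_all[sub_all$fiber_class == st, , drop = FALSE]
      for (b in MORPHO_BASES) {
        d <- if (comp_area_px == 0) {
          c(mean = NA_real_, median = NA_real_, sd = NA_real_,
            skewness = NA_real_, kurtosis = NA_real_, p10 = NA_real_,
            p90 = NA_real_)
        } else describe_values(sub[[col_of[[b]]]])
        vals[paste(cp, "morphometry", b, names(d), st, sep = ".")] <- d
      }
    }

    # architecture
    for (st in MORPHO_STRATA) {
      n <- if (st == "all") nrow(sub_all) else
        sum(sub_all$fiber_class == st)
      vals[paste(cp, "architecture", "fibers", "density_per_mm2", st, sep = ".")] <-
        if (comp_area_px == 0) NA_real_ else n / comp_mm2
    }
    tot_area <- sum(sub_all$area_um2)
    vals[paste(cp, "architecture", "assembled", "area_fraction", sep = ".")] <-
      if (comp_area_px == 0 || tot_area == 0) NA_real_ else
        sum(sub_all$area_um2[sub_all$fiber_class == "assembled"]) / tot_area
    ot <- .orientation_traits(sub_all$orientation_deg, sub_all$length_um)
    vals[paste(cp, "architecture", "orientation", "order_parameter", sep = ".")] <- ot["order_parameter"]
    vals[paste(cp, "architecture", "orientation", "entropy", sep = ".")] <- ot["entropy"]
    vals[paste(cp, "architecture", "orientation", "coherence", sep = ".")] <- ot["coherence"]
    in_comp <- comp_sel[ctr_idx]
    sub_map <- emap
    sub_map$values <- matrix(emap$values[in_comp], ncol = 1)
    et <- entropy_traits(sub_map, high_quantile)
    vals[paste(cp, "architecture", "entropy", "mean", sep = ".")] <- et$entropy_mean
    vals[paste(cp, "architecture", "entropy", "sd", sep = ".")] <- et$entropy_sd
    vals[paste(cp, "architecture", "entropy", "p90", sep = ".")] <- et$entropy_p90
    vals[paste(cp, "architecture", "entropy", "high_fraction", sep = ".")] <- et$high_entropy_area_fraction

    out <- c(out, vals)
  }
  attr(out, "sample_id") <- cm$sample_id
  out
}
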