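# Endocardium/myocardium region-of-interest handling: GeoJSON polygons in,
# compartment label rasters out. Pixel coordinate convention: 0-based,
# (x, y) = (column, row), polygons in image pixel space, even-odd fill.

ROI_LABELS <- c("endocardium", "myocardium")

#' Construct an ROI set
#'
#' @param labels character vector of compartment labels, one per polygon,
#'   drawn from `endocardium` / `myocardium`
#' @param polygons list of Nx2 numeric matrices of (x, y) vertices in
#'   0-based pixel coordinates (exterior rings; closing vertex optional)
#' @param source optional path the set was loaded from
#' @return an object of class `roi_set`
#' @export
roi_set <- function(labels, polygons, source = NA_character_) {
  if (length(labels) != length(polygons)) abort("one label per polygon required")
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2) abort("polygon %d must be an Nx2 matrix", i)
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) {
      polygons[[i]] <- p[-nrow(p), , drop = FALSE]  # drop closing vertex
    }
    if (nrow(polygons[[i]]) < 3) abort("polygon %d has fewer than 3 vertices", i)
    if (!labels[i] %in% ROI_LABELS) {
      abort("feature %d: unknown label '%s' (allowed: %s)",
            i, labels[i], paste(ROI_LABELS, collapse = ", "))
    }
    if (.self_intersects(polygons[[i]])) {
      abort("feature %d (%s): polygon is self-intersecting", i, labels[i])
    }
  }
  structure(list(labels = labels, polygons = polygons, source = source),
            class = "roi_set")
}

# proper segment-crossing test for non-adjacent edges
.self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Load ROI polygons from a GeoJSON FeatureCollection
#'
#' Expects polygon features with a `label` property of `endocardium` or
#' `myocardium`; coordinates are interpreted as (x = column, y = row) in
#' 0-based pixel space. Malformed GeoJSON, unknown labels and
#' self-intersecting polygons raise errors naming the feature index.
#'
#' @param path GeoJSON file path
#' @return an [roi_set()]
#' @export
load_rois <- function(path) {
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) abort("malformed GeoJSON: %s", conditionMessage(e)))
  if (!identical(gj$type, "FeatureCollection")) {
    abort("expected a GeoJSON FeatureCollection, got '%s'", gj$type %||% "?")
  }
  labels <- character(0); polys <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      abort("feature %d: geometry type must be Polygon, got '%s'",
            i, f$geometry$type %||% "?")
    }
    lab <- f$properties$label
    if (is.null(lab)) abort("feature %d: missing 'label' property", i)
    ring <- f$geometry$coordinates[[1]]  # exterior ring
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    labels <- c(labels, lab)
    polys[[length(polys) + 1]] <- m
  }
  roi_set(labels, polys, source = path)
}

#' Write an ROI set as GeoJSON
#'
#' @param rois an [roi_set()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  feats <- lapply(seq_along(rois$labels), function(i) {
    p <- rois$polygons[[i]]
    ring <- lapply(seq_len(nrow(p)), function(k) c(p[k, 1], p[k, 2]))
    ring[[length(ring) + 1]] <- ring[[1]]  # close the ring
    list(type = "Feature",
         properties = list(label = rois$labels[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize ROI polygons into a compartment label raster
#'
#' Pixels are labelled by even-odd polygon fill at 0-based pixel centers:
#' 0 = unassigned, 1 = myocardium, 2 = endocardium. Where polygons overlap,
#' endocardium takes precedence (the thinner, more specific structure).
#'
#' @param rois an [roi_set()]
#' @param shape image shape (height, width) in pixels
#' @return an object of class `compartment_raster`: list with `labels`
#'   (integer matrix) and `codes` (named label codes)
#' @export
rasterize_compartments <- function(rois, shape) {
  stopifnot(inherits(rois, "roi_set"))
  h <- shape[1]; w <- shape[2]
  ras <- matrix(0L, h, w)
  order <- c(which(rois$labels == "myocardium"), which(rois$labels == "endocardium"))
  for (i in order) {
    code <- if (rois$labels[i] == "endocardium") 2L else 1L
    p <- rois$polygons[[i]]
    # bounding box of candidate pixel centers (0-based x = col-1, y = row-1)
    cmin <- max(1, floor(min(p[, 1])) + 1); cmax <- min(w, ceiling(max(p[, 1])) + 1)
    rmin <- max(1, floor(min(p[, 2])) + 1); rmax <- min(h, ceiling(max(p[, 2])) + 1)
    if (cmin > cmax || rmin > rmax) next
    cc <- cmin:cmax; rr <- rmin:rmax
    gx <- rep(cc - 1, each = length(rr))
    gy <- rep(rr - 1, times = length(cc))
    inside <- pracma::inpolygon(gx, gy, p[, 1], p[, 2], boundary = TRUE)
    if (any(inside)) {
      sub <- ras[rr, cc, drop = FALSE]
      sub[matrix(inside, length(rr), length(cc))] <- code
      ras[rr, cc] <- sub
    }
  }
  structure(list(labels = ras, codes = c(unassigned = 0L, myocardium = 1L,
                                         endocardium = 2L)),
            class = "compartment_raster")
}

#' Restrict a mask or fiber table to one compartment
#'
#' Masks are intersected with the compartment raster. Fiber records are
#' assigned whole (no splitting) to the compartment containing the majority
#' of their skeleton pixels; ties break toward endocardium. `label =
#' "whole"` returns the input unchanged.
#'
#' @param x a [collagen_mask()] or a [decompose_fibers()] data.frame
#' @param raster a [rasterize_compartments()] result
#' @param label `"whole"`, `"myocardium"` or `"endocardium"`
#' @return the restricted mask or fiber table
#' @export
restrict_to_compartment <- function(x, raster, label) {
  if (label == "whole") return(x)
  code <- raster$codes[[label]]
  if (is.null(code)) abort("unknown compartment '%s'", label)
  if (inherits(x, "collagen_mask")) {
    m <- x$mask & (raster$labels == code)
    return(collagen_mask(m, x$mpp, x$provenance, x$sample_id))
  }
  if (is.data.frame(x)) {
    comp <- fiber_compartments(x, raster)
    return(x[comp == label, , drop = FALSE])
  }
  abort("cannot restrict object of class '%s'", class(x)[1])
}

#' Compartment assignment of each fiber
#'
#' Majority vote over skeleton pixels; ties prefer endocardium over
#' myocardium over unassigned.
#'
#' @param records fiber table with a `skeleton_px` list column
#' @param raster a [rasterize_compartments()] result
#' @return character vector: `"endocardium"`, `"myocardium"` or
#'   `"unassigned"` per fiber
#' @export
fiber_compartments <- function(records, raster) {
  vapply(records$skeleton_px, function(px) {
    if (length(px) == 0) return("unassigned")
    lab <- raster$labels[px]
    counts <- c(endocardium = sum(lab == 2L), myocardium = sum(lab == 1L),
                unassigned = sum(lab == 0L))
    names(counts)[which.max(counts)]  # which.max: first max wins -> endo > myo
  }, character(1))
}
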