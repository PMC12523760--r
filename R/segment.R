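#' A binary collagen mask
#'
#' @param mask logical HxW matrix
#' @param mpp micrometers per pixel
#' @param provenance named list recording how the mask was produced
#' @param sample_id optional sample identifier
#' @return an object of class `collagen_mask`
#' @export
collagen_mask <- function(mask, mpp, provenance = list(), sample_id = NA_character_) {
  if (!is.logical(mask) || length(dim(mask)) != 2) abort("mask must be a logical matrix")
  if (mpp <= 0) abort("mpp must be > 0")
  structure(list(mask = mask, mpp = mpp, provenance = provenance,
                 sample_id = sample_id),
            class = "collagen_mask")
}

#' @export
print.collagen_mask <- function(x, ...) {
  cat(sprintf("collagen_mask: %dx%d px, %.1f%% collagen (%.3g um/px)\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask), x$mpp))
  invisible(x)
}

#' Threshold a collagen concentration map into a binary mask
#'
#' With `threshold = "otsu"` the threshold is computed by Otsu's method on
#' the concentration values inside the tissue mask only (256-bin histogram
#' over their range), so glass/background does not bias the split. A fixed
#' numeric threshold can be given instead for full reproducibility.
#'
#' Otsu's method is unreliable when no collagen is present (it will split
#' the noise distribution), so the automatic threshold is floored at
#' `min_threshold`, a concentration below which staining is
#' indistinguishable from background bleed-through.
#'
#' @param collagen_map HxW concentration matrix from [deconvolve_stains()]
#' @param threshold `"otsu"` or a fixed numeric cutoff
#' @param tissue optional logical HxW tissue mask; `NULL` means all pixels
#' @param mpp micrometers per pixel recorded on the result
#' @param min_threshold floor applied to the automatic (Otsu) threshold;
#'   not applied to fixed thresholds
#' @param sample_id optional sample identifier
#' @return a [collagen_mask()] with the threshold recorded in `provenance`
#' @export
segment_collagen <- function(collagen_map, threshold = "otsu", tissue = NULL,
                             mpp = 0.25, min_threshold = 0.1,
                             sample_id = NA_character_) {
  if (!is.matrix(collagen_map)) abort("collagen_map must be a matrix")
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(collagen_map), ncol(collagen_map))
  if (!any(tissue)) abort("tissue mask is empty")
  if (identical(threshold, "otsu")) {
    v <- collagen_map[tissue]
    rng <- range(v)
    if (diff(rng) < 1e-12) {
      th <- Inf  # constant map: nothing stands out
    } else {
      th <- max(EBImage::otsu(matrix(v, ncol = 1), range = rng, levels = 256L),
                min_threshold)
    }
    policy <- "otsu"
  } else {
    th <- as.numeric(threshold)
    policy <- "fixed"
  }
  mask <- collagen_map > th & tissue
  collagen_mask(mask, mpp,
                provenance = list(threshold = th, policy = policy),
                sample_id = sample_id)
}

#' Morphological cleanup of a collagen mask
#'
#' Applies a morphological closing with a disc brush, then removes connected
#' components (8-connectivity) smaller than `min_object_area_um2`. The
#' operation is idempotent: applying it twice gives the same mask as once.
#'
#' @param cm a [collagen_mask()]
#' @param min_object_area_um2 minimum object area kept, square micrometers
#' @param closing_radius_px disc radius of the closing, pixels (0 = skip)
#' @return a cleaned [collagen_mask()]
#' @export
clean_mask <- function(cm, min_object_area_um2 = 30, closing_radius_px = 1) {
  stopifnot(inherits(cm, "collagen_mask"))
  m <- cm$mask
  if (closing_radius_px > 0 && any(m)) {
    brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
    m <- as_matrix(EBImage::closing(m * 1, brush)) > 0.5
  }
  if (any(m)) {
    lab <- as_matrix(EBImage::bwlabel(m))
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas * cm$mpp^2 < min_object_area_um2)
    if (length(drop)) m[lab %in% drop] <- FALSE
  }
  collagen_mask(m, cm$mpp,
                provenance = c(cm$provenance,
                               list(min_object_area_um2 = min_object_area_um2,
                                    closing_radius_px = closing_radius_px)),
                sample_id = cm$sample_id)
}
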