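#' GLCM entropy map of a collagen channel
#'
#' Quantizes the channel uniformly to `levels` gray bins over the tissue
#' intensity range, then slides a square window over the image; in each
#' window the symmetric gray-level co-occurrence matrix is accumulated over
#' all (distance, angle) offsets and reduced to its Shannon entropy
#' `-sum(p * log2(p))` in bits. High entropy marks disordered, heterogeneous
#' fibrillar texture; a constant window has entropy 0 and the theoretical
#' maximum is `log2(levels^2)`.
#'
#' @param channel HxW numeric matrix, typically the collagen concentration
#'   map from [deconvolve_stains()] so that disorder measures fibrillar
#'   texture rather than stain hue
#' @param window window side, pixels (must not exceed the image)
#' @param stride window step, pixels
#' @param levels number of gray quantization levels
#' @param distances co-occurrence offsets, pixels
#' @param angles co-occurrence directions, degrees (0, 45, 90, 135)
#' @param range quantization range `c(lo, hi)`; defaults to the range of
#'   `channel` inside `tissue`
#' @param tissue optional logical matrix restricting the quantization range
#' @return an object of class `entropy_map`: list with `values` (matrix of
#'   entropies at window centers), and the window/stride/levels/distances/
#'   angles/range used
#' @export
glcm_entropy_map <- function(channel, window = 64, stride = 32, levels = 8,
                             distances = 1, angles = c(0, 45, 90, 135),
                             range = NULL, tissue = NULL) {
  if (!is.matrix(channel)) abort("channel must be a matrix")
  if (window > nrow(channel) || window > ncol(channel)) {
    abort("window (%d px) larger than image (%dx%d)", window,
          nrow(channel), ncol(channel))
  }
  if (is.null(range)) {
    v <- if (is.null(tissue)) channel else channel[tissue]
    range <- base::range(v, finite = TRUE)
  }
  lo <- range[1]; hi <- range[2]
  if (hi - lo < 1e-12) {
    q <- matrix(1L, nrow(channel), ncol(channel))
  } else {
    q <- pmin(levels, pmax(1L, floor((channel - lo) / (hi - lo) * levels) + 1L))
    q <- matrix(as.integer(q), nrow(channel), ncol(channel))
  }
  dr <- integer(0); dc <- integer(0)
  for (d in distances) {
    for (a in angles) {
      off <- switch(as.character(a %% 180),
                    "0"   = c(0L, as.integer(d)),
                    "45"  = c(-as.integer(d), as.integer(d)),
                    "90"  = c(-as.integer(d), 0L),
                    "135" = c(-as.integer(d), -as.integer(d)),
                    abort("angle must be one of 0, 45, 90, 135 degrees"))
      dr <- c(dr, off[1]); dc <- c(dc, off[2])
    }
  }
  vals <- glcm_entropy_c(q, as.integer(window), as.integer(stride),
                         as.integer(levels), dr, dc)
  structure(list(values = vals, window = window, stride = stride,
                 levels = levels, distances = distances, angles = angles,
                 range = c(lo, hi)),
            class = "entropy_map")
}

# (row, col) pixel coordinates of window centers for an entropy map on an
# image of the given size
entropy_window_centers <- function(map) {
  wr <- nrow(map$values); wc <- ncol(map$values)
  list(rows = (seq_len(wr) - 1) * map$stride + map$window / 2 + 0.5,
       cols = (seq_len(wc) - 1) * map$stride + map$window / 2 + 0.5)
}

#' Entropy quantitative fibrosis traits
#'
#' Reduces an entropy map to the architecture-family qFTs: mean, sd, p90,
#' and the fraction of windows at or above `high_quantile` of the
#' theoretical maximum entropy `log2(levels^2)`.
#'
#' @param map an [glcm_entropy_map()] result
#' @param high_quantile fraction of the theoretical maximum defining "high
#'   entropy" windows (default 0.75)
#' @return named list: `entropy_mean`, `entropy_sd`, `entropy_p90`,
#'   `high_entropy_area_fraction`
#' @export
entropy_traits <- function(map, high_quantile = 0.75) {
  stopifnot(inherits(map, "entropy_map"))
  v <- map$values[is.finite(map$values)]
  if (length(v) == 0) {
    return(list(entropy_mean = NA_real_, entropy_sd = NA_real_,
                entropy_p90 = NA_real_, high_entropy_area_fraction = NA_real_))
  }
  hmax <- log2(map$levels^2)
  list(entropy_mean = mean(v),
       entropy_sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
       entropy_p90 = stats::quantile(v, 0.9, names = FALSE),
       high_entropy_area_fraction = mean(v >= high_quantile * hmax))
}

#' Render an entropy heatmap overlay
#'
#' Upsamples the entropy map to the image grid (nearest window center) and
#' maps it through a blue-green-yellow-red colormap scaled to
#' `[0, log2(levels^2)]`, alpha-blended over the slide.
#'
#' @param map an [glcm_entropy_map()] result
#' @param image the `slide_image` (or HxWx3 array) the map was computed on
#' @param alpha blend weight of the heatmap (default 0.5)
#' @return HxWx3 array of 8-bit RGB values
#' @export
render_heatmap <- function(map, image, alpha = 0.5) {
  stopifnot(inherits(map, "entropy_map"))
  px <- if (inherits(image, "slide_image")) image$pixels else image
  h <- dim(px)[1]; w <- dim(px)[2]
  hmax <- log2(map$levels^2)
  ctr <- entropy_window_centers(map)
  ri <- clamp(round((seq_len(h) - ctr$rows[1]) / map$stride) + 1, 1, nrow(map$values))
  ci <- clamp(round((seq_len(w) - ctr$cols[1]) / map$stride) + 1, 1, ncol(map$values))
  up <- map$values[ri, ci, drop = FALSE]
  up[!is.finite(up)] <- 0
  t <- clamp(up / hmax, 0, 1)
  ramp <- grDevices::colorRamp(c("blue", "green", "yellow", "red"))
  cols <- ramp(as.vector(t))  # N x 3 in 0..255
  out <- array(0, dim = c(h, w, 3))
  for (k in 1:3) {
    out[, , k] <- round((1 - alpha) * px[, , k] + alpha * matrix(cols[, k], h, w))
  }
  out
}
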