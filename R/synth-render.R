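#' A trichrome slide image
#'
#' @param pixels HxWx3 array of 8-bit RGB intensities (0-255)
#' @param mpp micrometers per pixel
#' @param sample_id optional sample identifier
#' @return an object of class `slide_image`
#' @export
slide_image <- function(pixels, mpp, sample_id = NA_character_) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) abort("pixels must be HxWx3")
  if (mpp <= 0) abort("mpp must be > 0")
  structure(list(pixels = pixels, mpp = mpp, sample_id = sample_id),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("slide_image %s: %dx%d px, %.3g um/px\n",
              x$sample_id, dim(x$pixels)[1], dim(x$pixels)[2], x$mpp))
  invisible(x)
}

#' Rendering parameters for the synthetic trichrome model
#'
#' @param collagen_od mean optical density of the collagen stain inside
#'   fiber footprints
#' @param cytoplasm_od mean OD of the cytoplasm stain over the tissue
#' @param cytoplasm_texture relative amplitude of the smooth cytoplasm
#'   texture field
#' @param noise_sd additive sensor noise, 8-bit intensity units
#' @param field_scale correlation scale of the texture field, pixels
#' @param stains stain matrix used for Beer-Lambert mixing
#' @return a list of class `render_params`
#' @export
render_params <- function(collagen_od = 1.0, cytoplasm_od = 0.45,
                          cytoplasm_texture = 0.15, noise_sd = 1.5,
                          field_scale = 32, stains = masson_stain_matrix()) {
  structure(list(collagen_od = collagen_od, cytoplasm_od = cytoplasm_od,
                 cytoplasm_texture = cytoplasm_texture, noise_sd = noise_sd,
                 field_scale = field_scale, stains = stains),
            class = "render_params")
}

# smooth unit-variance random field by bilinear upsampling of coarse noise
.smooth_field <- function(h, w, scale) {
  hs <- max(2, ceiling(h / scale) + 1)
  ws <- max(2, ceiling(w / scale) + 1)
  g <- matrix(rnorm(hs * ws), hs, ws)
  ry <- seq(1, hs, length.out = h)
  rx <- seq(1, ws, length.out = w)
  y0 <- pmin(floor(ry), hs - 1); fy <- ry - y0
  x0 <- pmin(floor(rx), ws - 1); fx <- rx - x0
  a <- g[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
       g[y0 + 1, x0, drop = FALSE] * outer(fy, 1 - fx) +
       g[y0, x0 + 1, drop = FALSE] * outer(1 - fy, fx) +
       g[y0 + 1, x0 + 1, drop = FALSE] * outer(fy, fx)
  a
}

#' Render a fiber set as a trichrome-stained RGB image
#'
#' Pixel colours are composed in optical-density space by Beer-Lambert
#' mixing: collagen stain concentration accumulates over fiber footprints,
#' the cytoplasm stain follows a smooth textured background field (damped
#' where collagen replaces muscle), and i.i.d. Gaussian sensor noise of
#' stated scale is added in intensity space. Empty regions white-balance
#' near (255, 255, 255).
#'
#' @param fibers a [make_fiber_set()] result
#' @param background a [render_params()] object
#' @param seed integer RNG seed
#' @param sample_id passed through to the returned `slide_image`
#' @return a `slide_image` with 8-bit integer pixels
#' @export
render_trichrome <- function(fibers, background = render_params(), seed = 1L,
                             sample_id = NA_character_) {
  stopifnot(inherits(fibers, "fiber_set"))
  h <- nrow(fibers$truth_mask); w <- ncol(fibers$truth_mask)
  bp <- background
  withr::with_seed(as.integer(seed), {
    c_col <- matrix(0, h, w)
    for (f in fibers$fibers) {
      inten <- max(0.3, rnorm(1, bp$collagen_od, 0.1 * bp$collagen_od))
      c_col[f$footprint_px] <- c_col[f$footprint_px] + inten
    }
    c_col <- pmin(c_col, 2.5)
    field <- .smooth_field(h, w, bp$field_scale)
    c_cyt <- pmax(0, bp$cytoplasm_od * (1 + bp$cytoplasm_texture * field))
    c_cyt <- c_cyt * (1 - 0.5 * pmin(c_col, 1))
    v1 <- bp$stains["collagen", ]; v2 <- bp$stains["cytoplasm", ]
    px <- array(0, dim = c(h, w, 3))
    for (k in 1:3) {
      od <- c_col * v1[k] + c_cyt * v2[k]
      ch <- 255 * 10^(-od) + rnorm(h * w, 0, bp$noise_sd)
      px[, , k] <- round(clamp(ch, 0, 255))
    }
  })
  slide_image(px, fibers$params$mpp, sample_id)
}
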