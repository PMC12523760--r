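# Image and sidecar I/O. PNG and plain (non-pyramidal) TIFF only.

#' Read a slide image from PNG or TIFF
#'
#' @param path image path (.png, .tif/.tiff)
#' @param mpp micrometers per pixel of the scan
#' @param sample_id optional sample identifier
#' @return a [slide_image()] with 0-255 pixels
#' @export
read_slide <- function(path, mpp, sample_id = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              abort("unsupported image format '.%s' (PNG/TIFF only)", ext))
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  slide_image(round(a * 255), mpp, sample_id)
}

#' Write a slide image as PNG
#'
#' @param image a `slide_image` or HxWx3 array (0-255)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_slide <- function(image, path) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Write a collagen mask as a 0/255 PNG plus a JSON provenance sidecar
#'
#' @param cm a [collagen_mask()]
#' @param path output PNG path; the sidecar gets the extension `.json`
#' @return `path`, invisibly
#' @export
write_mask <- function(cm, path) {
  stopifnot(inherits(cm, "collagen_mask"))
  png::writePNG(cm$mask * 1, path)
  side <- sub("\\.png$", ".json", path)
  jsonlite::write_json(c(list(mpp = cm$mpp, sample_id = cm$sample_id),
                         cm$provenance),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mask PNG back into a collagen mask
#'
#' @param path PNG path written by [write_mask()] (sidecar optional)
#' @param mpp micrometers per pixel; taken from the sidecar when present
#' @return a [collagen_mask()]
#' @export
read_mask <- function(path, mpp = NULL) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  side <- sub("\\.png$", ".json", path)
  prov <- list()
  if (file.exists(side)) {
    prov <- jsonlite::fromJSON(side)
    mpp <- mpp %||% prov$mpp
  }
  if (is.null(mpp)) abort("mpp not given and no sidecar found")
  collagen_mask(m > 0.5, mpp, provenance = prov)
}
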