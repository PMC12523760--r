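#' Construct a stain matrix for colour deconvolution
#'
#' Rows are unit optical-density (OD) vectors in RGB-OD space for the
#' collagen stain, the cytoplasm/muscle stain, and a residual channel. The
#' residual defaults to the normalized cross product of the first two.
#'
#' @param collagen,cytoplasm,residual numeric length-3 OD vectors
#' @return a 3x3 matrix of class `stain_matrix` with rows
#'   (collagen, cytoplasm, residual), each non-negative and unit length
#' @export
stain_matrix <- function(collagen, cytoplasm, residual = NULL) {
  if (is.null(residual)) {
    residual <- c(collagen[2] * cytoplasm[3] - collagen[3] * cytoplasm[2],
                  collagen[3] * cytoplasm[1] - collagen[1] * cytoplasm[3],
                  collagen[1] * cytoplasm[2] - collagen[2] * cytoplasm[1])
    residual <- abs(residual)
  }
  m <- rbind(collagen = collagen, cytoplasm = cytoplasm, residual = residual)
  if (any(m < 0)) abort("stain vectors must be non-negative in OD space")
  m <- m / sqrt(rowSums(m^2))
  colnames(m) <- c("R", "G", "B")
  if (abs(det(m)) < 1e-8) abort("stain matrix is singular")
  structure(m, class = c("stain_matrix", "matrix"))
}

#' Masson's trichrome stain vectors
#'
#' Published colour-deconvolution vectors for Masson's trichrome: an aniline
#' blue (collagen) vector and a Biebrich scarlet-acid fuchsin (cytoplasm)
#' vector, with the residual completing the basis.
#'
#' @return a `stain_matrix`
#' @export
masson_stain_matrix <- function() {
  stain_matrix(collagen  = c(0.7995107, 0.5913521, 0.10528667),
               cytoplasm = c(0.09997159, 0.73738605, 0.6680326))
}

#' Separate stains by colour deconvolution in optical-density space
#'
#' Per-channel OD is computed as `-log10(max(I, 1) / 255)` and unmixed by the
#' inverse stain matrix into per-stain concentration maps.
#'
#' @param image a `slide_image`, or an HxWx3 numeric array on the 0-255 scale
#' @param stains a [stain_matrix()]; defaults to [masson_stain_matrix()]
#' @param clip clip negative concentrations to zero (default `TRUE`); pass
#'   `FALSE` to inspect the raw unmixing, e.g. for reconstruction checks
#' @return a list of HxW concentration matrices named `collagen`,
#'   `cytoplasm`, `residual`, with the stain matrix attached as an attribute
#' @export
deconvolve_stains <- function(image, stains = masson_stain_matrix(), clip = TRUE) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  if (length(dim(px)) != 3 || dim(px)[3] != 3) abort("image must be HxWx3 RGB")
  if (abs(det(stains)) < 1e-8) abort("stain matrix is singular")
  h <- dim(px)[1]; w <- dim(px)[2]
  od <- -log10(pmax(px, 1) / 255)
  dim(od) <- c(h * w, 3)
  conc <- od %*% solve(stains)  # OD = conc %*% stains
  if (clip) conc[conc < 0] <- 0
  out <- lapply(1:3, function(k) matrix(conc[, k], h, w))
  names(out) <- rownames(stains)
  attr(out, "stains") <- stains
  attr(out, "mpp") <- if (inherits(image, "slide_image")) image$mpp else NULL
  out
}

#' Tissue mask from total optical density
#'
#' Pixels whose summed RGB optical density exceeds `od_min` are considered
#' tissue; the rest is glass/background and is excluded from thresholding.
#'
#' @param image a `slide_image` or HxWx3 array (0-255)
#' @param od_min total-OD cutoff (default 0.05)
#' @return logical HxW matrix
#' @export
tissue_mask <- function(image, od_min = 0.05) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  od <- -log10(pmax(px, 1) / 255)
  tot <- od[, , 1] + od[, , 2] + od[, , 3]
  tot > od_min
}
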