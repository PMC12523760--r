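# End-to-end analysis: image -> stains -> mask -> fibers -> entropy ->
# compartments -> traits; study level: traits -> selection -> composites.

#' Analysis options for the fibrosis pipeline
#'
#' @param stains stain matrix for deconvolution
#' @param threshold `"otsu"` or a fixed collagen-concentration cutoff
#' @param tissue_od_min total-OD tissue cutoff
#' @param min_object_area_um2,closing_radius_px mask cleanup parameters
#' @param prune_px skeleton spur-pruning length, pixels
#' @param node_threshold fine/assembled junction-count boundary
#' @param entropy_window,entropy_stride,entropy_levels GLCM parameters
#' @param high_quantile high-entropy cutoff fraction
#' @return list of class `pipeline_options`
#' @export
pipeline_options <- function(stains = masson_stain_matrix(),
                             threshold = "otsu",
                             tissue_od_min = 0.05,
                             min_object_area_um2 = 30,
                             closing_radius_px = 1,
                             prune_px = 3,
                             node_threshold = 30,
                             entropy_window = 64,
                             entropy_stride = 32,
                             entropy_levels = 8,
                             high_quantile = 0.75) {
  structure(list(stains = stains, threshold = threshold,
                 tissue_od_min = tissue_od_min,
                 min_object_area_um2 = min_object_area_um2,
                 closing_radius_px = closing_radius_px, prune_px = prune_px,
                 node_threshold = node_threshold,
                 entropy_window = entropy_window,
                 entropy_stride = entropy_stride,
                 entropy_levels = entropy_levels,
                 high_quantile = high_quantile),
            class = "pipeline_options")
}

#' Analyze one trichrome slide image
#'
#' Runs stain deconvolution, collagen segmentation and cleanup, skeleton
#' fiber morphometry and classification, GLCM entropy mapping, compartment
#' rasterization (when ROIs are given) and trait extraction.
#'
#' @param image a [slide_image()] (or HxWx3 array with `mpp` supplied)
#' @param rois optional [roi_set()] for endocardium/myocardium analysis
#' @param mpp micrometers per pixel when `image` is a bare array
#' @param opts a [pipeline_options()] list
#' @param compartments compartments to extract (defaults to whole +
#'   endo/myo when ROIs are present)
#' @param raster optional pre-rasterized [rasterize_compartments()] result
#'   for `rois` (reused across samples sharing one ROI geometry)
#' @return list of class `sample_analysis`: `traits` (named vector),
#'   `records`, `mask`, `maps`, `entropy_map`, `compartments`, `tissue`
#' @export
analyze_sample <- function(image, rois = NULL, mpp = NULL,
                           opts = pipeline_options(),
                           compartments = NULL, raster = NULL) {
  if (!inherits(image, "slide_image")) {
    if (is.null(mpp)) abort("mpp required for a bare pixel array")
    image <- slide_image(image, mpp)
  }
  maps <- deconvolve_stains(image, opts$stains)
  tis <- tissue_mask(image, opts$tissue_od_min)
  cm <- segment_collagen(maps$collagen, opts$threshold, tissue = tis,
                         mpp = image$mpp, sample_id = image$sample_id)
  cm <- clean_mask(cm, opts$min_object_area_um2, opts$closing_radius_px)
  g <- skeletonize_mask(cm, opts$prune_px)
  records <- decompose_fibers(g, cm, opts$node_threshold)
  emap <- glcm_entropy_map(maps$collagen,
                           window = min(opts$entropy_window, dim(maps$collagen)),
                           stride = opts$entropy_stride,
                           levels = opts$entropy_levels, tissue = tis)
  which_cp <- compartments %||% (if (is.null(rois) && is.null(raster))
    "whole" else COMPARTMENTS)
  ras <- raster %||%
    (if (!is.null(rois) && any(which_cp != "whole"))
       rasterize_compartments(rois, dim(cm$mask)) else NULL)
  traits <- extract_traits(cm, records, emap, compartments = ras,
                           tissue = tis, which_compartments = which_cp,
                           high_quantile = opts$high_quantile)
  structure(list(traits = traits, records = records, mask = cm, maps = maps,
                 entropy_map = emap, compartments = ras, tissue = tis),
            class = "sample_analysis")
}

#' Run the full pipeline over a synthetic or loaded study
#'
#' Analyzes every sample of a [make_study()] bundle, assembles the trait
#' matrix, and scores each compartment: trait selection, normalization,
#' composite scores and group comparison.
#'
#' @param bundle a [make_study()] result
#' @param opts a [pipeline_options()] list
#' @param compartments compartments to analyze and score
#' @param change_min,alpha,p_rule,scale scoring parameters, see
#'   [select_traits()] and [composite_scores()]
#' @param out_dir optional report output directory
#' @return list of class `study_analysis`: `traits` (data.frame),
#'   `study` (table), `results` (per-compartment [composite_scores()]),
#'   `report`
#' @export
run_study <- function(bundle, opts = pipeline_options(),
                      compartments = NULL, change_min = 20, alpha = 0.05,
                      p_rule = "less", scale = 10, out_dir = NULL) {
  stopifnot(inherits(bundle, "study_bundle"))
  tab <- study_table(bundle)
  # samples of one synthetic study share identical ROI geometry: rasterize once
  ras_cache <- NULL; ras_key <- NULL
  rows <- lapply(names(bundle$samples), function(sid) {
    s <- bundle$samples[[sid]]
    ras <- NULL
    if (!is.null(s$rois) && !identical(compartments, "whole")) {
      if (is.null(ras_key) || !identical(ras_key, s$rois)) {
        ras_key <<- s$rois
        ras_cache <<- rasterize_compartments(s$rois, dim(s$image$pixels)[1:2])
      }
      ras <- ras_cache
    }
    an <- analyze_sample(s$image, rois = s$rois, opts = opts,
                         compartments = compartments, raster = ras)
    tv <- an$traits
    df <- as.data.frame(as.list(tv), check.names = FALSE)
    cbind(data.frame(sample_id = sid), df)
  })
  traits <- do.call(rbind, rows)
  cps <- compartments %||%
    (if (is.null(bundle$samples[[1]]$rois)) "whole" else COMPARTMENTS)
  catalog <- trait_catalog()
  results <- lapply(cps, function(cp) {
    score_study(traits, tab, compartment = cp, catalog = catalog,
                change_min = change_min, alpha = alpha, p_rule = p_rule,
                scale = scale)
  })
  names(results) <- cps
  report <- fibrosis_report(results, out_dir = out_dir,
                            params = list(change_min = change_min,
                                          alpha = alpha, p_rule = p_rule,
                                          scale = scale,
                                          seed = bundle$design$seed))
  structure(list(traits = traits, study = tab, results = results,
                 report = report),
            class = "study_analysis")
}
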