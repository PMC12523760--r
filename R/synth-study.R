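#' Design of a synthetic two-region biopsy study
#'
#' Describes a paired study: `n_patients` patients, each contributing one
#' peri-papillary and one remote sample. Remote samples are drawn at the
#' baseline fiber parameters; peri-papillary samples get the `effects`
#' multipliers (fiber density, thickness, branching, orientation
#' concentration), emulating dense, thick, branched, aligned collagen
#' networks near the papillary muscle versus sparse fine fibrils remotely.
#' Both regions carry a densely collagenous endocardial band along the top
#' image edge, which the auto-generated ROI polygons label `endocardium`
#' (the remainder is `myocardium`). Lognormal patient- and sample-level
#' factors add paired biological and sampling variability.
#'
#' @param n_patients number of patients (>= 2; default 6)
#' @param canvas image size (height, width), pixels
#' @param mpp micrometers per pixel (default 0.25, typical of 40x scans)
#' @param fiber_density_mm2 baseline fiber count density, per mm^2
#' @param length_um,thickness_um baseline (mean, sd) fiber length/thickness
#' @param branch_rate baseline branch events per 100 um
#' @param orientation_kappa baseline orientation concentration
#' @param effects named multipliers applied to the peri-papillary group:
#'   `n_fibers`, `thickness`, `branch_rate`, `orientation_kappa` (all > 0)
#' @param endocardial_band_um thickness of the endocardial band, um
#'   (`0` disables the band and the ROI files)
#' @param band_density_factor fiber density multiplier inside the band
#' @param patient_sd sd of the lognormal per-patient factor (shared by both
#'   regions of a patient, applied to density and thickness)
#' @param sample_sd sd of the lognormal per-sample density factor
#' @param seed integer RNG seed
#' @return an object of class `study_design`
#' @export
study_design <- function(n_patients = 6,
                         canvas = c(512, 512),
                         mpp = 0.25,
                         fiber_density_mm2 = 3000,
                         length_um = c(30, 10),
                         thickness_um = c(1.5, 0.4),
                         branch_rate = 1.5,
                         orientation_kappa = 0.7,
                         effects = list(n_fibers = 1.8, thickness = 2,
                                        branch_rate = 2.5,
                                        orientation_kappa = 2),
                         endocardial_band_um = 20,
                         band_density_factor = 3,
                         patient_sd = 0.15,
                         sample_sd = 0.10,
                         seed = 1L) {
  if (n_patients < 2) abort("n_patients must be >= 2")
  if (any(unlist(effects) <= 0)) abort("effect multipliers must be > 0")
  structure(list(n_patients = as.integer(n_patients), canvas = as.integer(canvas),
                 mpp = mpp, fiber_density_mm2 = fiber_density_mm2,
                 length_um = length_um, thickness_um = thickness_um,
                 branch_rate = branch_rate, orientation_kappa = orientation_kappa,
                 effects = effects, endocardial_band_um = endocardial_band_um,
                 band_density_factor = band_density_factor,
                 patient_sd = patient_sd, sample_sd = sample_sd,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Generate a complete synthetic study
#'
#' Builds one sample per patient x region: ground-truth fibers, the
#' rendered trichrome image, the ROI annotation splitting the canvas into
#' the endocardial band and the myocardial remainder, and a manifest row.
#' Deterministic given the design seed.
#'
#' @param design a [study_design()]
#' @param out_dir optional directory; when given, images (PNG), ROI files
#'   (GeoJSON), per-sample ground-truth sidecars (JSON) and the manifest
#'   (CSV) are written there
#' @return an object of class `study_bundle`: list with `samples` (named
#'   list, each with `image`, `fibers`, `rois`, `patient_id`, `region`),
#'   `manifest` (data.frame), and `design`
#' @export
make_study <- function(design, out_dir = NULL) {
  stopifnot(inherits(design, "study_design"))
  d <- design
  h <- d$canvas[1]; w <- d$canvas[2]
  area_mm2 <- h * w * d$mpp^2 / 1e6
  band_px <- if (d$endocardial_band_um > 0) {
    max(2L, as.integer(round(d$endocardial_band_um / d$mpp)))
  } else 0L
  band_area_mm2 <- band_px * w * d$mpp^2 / 1e6

  samples <- list()
  manifest <- list()
  withr::with_seed(d$seed, {
    for (p in seq_len(d$n_patients)) {
      f_patient <- exp(rnorm(1, 0, d$patient_sd))
      for (region in c("peri_papillary", "remote")) {
        mult <- if (region == "peri_papillary") d$effects else {
          list(n_fibers = 1, thickness = 1, branch_rate = 1, orientation_kappa = 1)
        }
        f_sample <- exp(rnorm(1, 0, d$sample_sd))
        dens <- d$fiber_density_mm2 * f_patient * f_sample * mult$n_fibers
        th_mean <- d$thickness_um[1] * f_patient * mult$thickness
        th_sd <- d$thickness_um[2] * f_patient * mult$thickness
        n_main <- rpois(1, dens * area_mm2)
        seed_main <- sample.int(2^30, 1)
        main <- make_fiber_set(fiber_params(
          n_fibers = n_main, length_um = d$length_um,
          thickness_um = c(th_mean, th_sd),
          branch_rate = d$branch_rate * mult$branch_rate,
          orientation_kappa = d$orientation_kappa * mult$orientation_kappa,
          canvas = d$canvas, mpp = d$mpp, seed = seed_main))
        fibers <- main
        if (band_px > 0) {
          n_band <- rpois(1, d$band_density_factor * dens * band_area_mm2)
          seed_band <- sample.int(2^30, 1)
          band <- make_fiber_set(fiber_params(
            n_fibers = n_band, length_um = d$length_um,
            thickness_um = c(th_mean, th_sd),
            branch_rate = d$branch_rate * mult$branch_rate,
            orientation_kappa = 4,          # band fibers align with the edge
            mean_direction_deg = 0,
            canvas = d$canvas, mpp = d$mpp,
            start_rows = c(1, band_px), seed = seed_band))
          fibers <- combine_fiber_sets(main, band)
        }
        sid <- sprintf("P%02d_%s", p, region)
        img <- render_trichrome(fibers, seed = sample.int(2^30, 1),
                                sample_id = sid)
        rois <- if (band_px > 0) {
          roi_set(labels = c("endocardium", "myocardium"),
                  polygons = list(
                    cbind(c(-0.5, w - 0.5, w - 0.5, -0.5),
                          c(-0.5, -0.5, band_px - 0.5, band_px - 0.5)),
                    cbind(c(-0.5, w - 0.5, w - 0.5, -0.5),
                          c(band_px - 0.5, band_px - 0.5, h - 0.5, h - 0.5))))
        } else NULL
        samples[[sid]] <- list(image = img, fibers = fibers, rois = rois,
                               patient_id = sprintf("P%02d", p), region = region)
        manifest[[length(manifest) + 1]] <- data.frame(
          sample_id = sid, patient_id = sprintf("P%02d", p), region = region,
          image_path = if (is.null(out_dir)) NA_character_ else
            file.path(out_dir, paste0(sid, ".png")),
          roi_path = if (is.null(out_dir) || band_px == 0) NA_character_ else
            file.path(out_dir, paste0(sid, "_roi.geojson")))
      }
    }
  })
  manifest <- do.call(rbind, manifest)
  bundle <- structure(list(samples = samples, manifest = manifest,
                           design = design),
                      class = "study_bundle")
  if (!is.null(out_dir)) write_study(bundle, out_dir)
  bundle
}

#' Write a study bundle to disk
#'
#' Writes per-sample PNG images, GeoJSON ROI files, JSON ground-truth
#' sidecars (per-fiber scalar truth, not the centerlines), and the study
#' manifest CSV.
#'
#' @param bundle a [make_study()] result
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_study <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(bundle$samples)) {
    s <- bundle$samples[[sid]]
    write_slide(s$image, file.path(out_dir, paste0(sid, ".png")))
    if (!is.null(s$rois)) {
      write_rois(s$rois, file.path(out_dir, paste0(sid, "_roi.geojson")))
    }
    gt <- lapply(s$fibers$fibers, function(f) {
      list(length_um = f$length_um, thickness_um = f$thickness_um,
           n_junctions = f$n_junctions, footprint_area_px = length(f$footprint_px))
    })
    jsonlite::write_json(list(sample_id = sid,
                              mean_direction_deg = s$fibers$mean_direction_deg,
                              fibers = gt),
                         file.path(out_dir, paste0(sid, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  write.csv(bundle$manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Study table of a bundle
#'
#' @param bundle a [make_study()] result
#' @return data.frame with `sample_id`, `patient_id`, `region`
#' @export
study_table <- function(bundle) {
  bundle$manifest[, c("sample_id", "patient_id", "region")]
}
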