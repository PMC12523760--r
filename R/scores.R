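# Trait selection, normalization, and the four equi-weighted composite
# fibrosis scores (Ph-FCS, CCS, MCS, ACS), with Mann-Whitney group
# comparison between the peri-papillary and remote regions.

REGIONS <- c("peri_papillary", "remote")
SCORE_FAMILIES <- c(phfcs = "all", ccs = "content", mcs = "morphometry",
                    acs = "architecture")

#' Group mean change of each trait
#'
#' Relative change of the peri-papillary group mean against the remote
#' group mean: `100 * (mean_peri - mean_remote) / |mean_remote|`. A remote
#' mean of zero with a nonzero peri mean is flagged as infinite change;
#' both zero gives 0. Traits the catalog declares non-negative are
#' validated; signed descriptors (skewness) skip the domain check.
#'
#' @param values numeric trait values, one per sample
#' @param regions character vector of regions aligned with `values`
#' @param nonnegative validate that values are >= 0 (default `TRUE`)
#' @return the signed percent change (possibly `Inf`/`-Inf`), or `NA` if a
#'   group has no finite values
#' @export
group_mean_change <- function(values, regions, nonnegative = TRUE) {
  if (nonnegative && any(values < 0, na.rm = TRUE)) {
    abort("negative trait values in a non-negative trait")
  }
  mp <- mean(values[regions == "peri_papillary"], na.rm = TRUE)
  mr <- mean(values[regions == "remote"], na.rm = TRUE)
  if (!is.finite(mp) || !is.finite(mr)) return(NA_real_)
  if (mr == 0) {
    if (mp == 0) return(0)
    return(sign(mp) * Inf)
  }
  100 * (mp - mr) / abs(mr)
}

#' Select significantly changed traits
#'
#' A trait is selected when its absolute group mean change exceeds
#' `change_min` percent and its Mann-Whitney p-value clears `alpha`. The
#' default significance rule is `p < alpha`; `p_rule = "greater"` runs the
#' literal rule `p > alpha` instead. Traits missing in more than half the
#' samples are dropped from selection (flagged in the result); group
#' statistics use the available values otherwise. Benjamini-Hochberg
#' q-values are reported alongside for transparency; they play no part in
#' selection.
#'
#' @param traits data.frame of samples x traits; must contain `sample_id`,
#'   other columns are trait values named by the catalog grammar
#' @param study study table with `sample_id` and `region`
#' @param catalog a [trait_catalog()] (for directions and families)
#' @param change_min minimum absolute group mean change, percent
#' @param alpha significance level
#' @param p_rule `"less"` (default) or `"greater"` (literal reading)
#' @param max_missing_frac drop traits missing in more than this fraction
#'   of samples
#' @return data.frame of class `selection_result`: per trait the group
#'   means, `delta_pct`, `U`, `p`, `q`, `selected`, `family`, `stratum`,
#'   `dropped_missing`
#' @export
select_traits <- function(traits, study, catalog = trait_catalog(),
                          change_min = 20, alpha = 0.05,
                          p_rule = c("less", "greater"),
                          max_missing_frac = 0.5) {
  p_rule <- match.arg(p_rule)
  regions <- study$region[match(traits$sample_id, study$sample_id)]
  if (any(is.na(regions))) abort("samples missing from the study table")
  trait_cols <- setdiff(names(traits), "sample_id")
  rows <- lapply(trait_cols, function(nm) {
    v <- traits[[nm]]
    info <- catalog[match(nm, catalog$name), ]
    missing_frac <- mean(!is.finite(v))
    dropped <- missing_frac > max_missing_frac
    ok <- is.finite(v)
    x <- v[ok & regions == "peri_papillary"]
    y <- v[ok & regions == "remote"]
    if (dropped || length(x) == 0 || length(y) == 0) {
      return(data.frame(trait = nm, family = info$family,
                        stratum = info$stratum,
                        mean_peri = NA_real_, mean_remote = NA_real_,
                        delta_pct = NA_real_, U = NA_real_, p = NA_real_,
                        selected = FALSE, dropped_missing = TRUE))
    }
    dpct <- group_mean_change(v[ok], regions[ok],
                              nonnegative = isTRUE(!info$signed))
    mw <- mann_whitney_u(x, y)
    sig <- if (p_rule == "less") mw$p < alpha else mw$p > alpha
    data.frame(trait = nm, family = info$family, stratum = info$stratum,
               mean_peri = mean(x), mean_remote = mean(y),
               delta_pct = dpct, U = mw$U, p = mw$p,
               selected = isTRUE(abs(dpct) > change_min && sig),
               dropped_missing = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("selection_result", "data.frame")
  attr(out, "params") <- list(change_min = change_min, alpha = alpha,
                              p_rule = p_rule)
  out
}

#' Orient and min-max normalize selected traits
#'
#' Each trait is first oriented by its catalog direction (sign-flipped when
#' larger raw values indicate less severe fibrosis), then min-max scaled to
#' `[0, 1]` across the cohort. Traits constant across the cohort carry no
#' contrast and are dropped (recorded in the `dropped_constant` attribute).
#'
#' @param traits samples x traits data.frame with `sample_id`
#' @param selected character vector of trait names to normalize
#' @param catalog a [trait_catalog()] for directions
#' @return data.frame `sample_id` + normalized columns in `[0, 1]`
#' @export
normalize_traits <- function(traits, selected, catalog = trait_catalog()) {
  out <- data.frame(sample_id = traits$sample_id)
  dropped <- character(0)
  for (nm in selected) {
    v <- traits[[nm]]
    dir <- catalog$direction[match(nm, catalog$name)]
    if (is.na(dir)) dir <- 1
    v <- v * dir
    rng <- range(v, na.rm = TRUE)
    if (!is.finite(rng[1]) || diff(rng) < 1e-12) {
      dropped <- c(dropped, nm)
      next
    }
    out[[nm]] <- (v - rng[1]) / diff(rng)
  }
  attr(out, "dropped_constant") <- dropped
  out
}

#' Equi-weighted composite fibrosis scores
#'
#' Per sample, each composite is `scale` times the unweighted mean of the
#' normalized, direction-oriented selected traits of its family: CCS over
#' content, MCS over morphometry, ACS over architecture, and Ph-FCS over
#' the union of all selected traits. Fine/assembled sub-scores are derived
#' from the stratum tag the same way. Families with no selected trait give
#' an NA score (flagged), and each score is compared between regions with
#' [mann_whitney_u()].
#'
#' @param normalized a [normalize_traits()] result
#' @param selection a [select_traits()] result
#' @param study study table with `sample_id` and `region`
#' @param scale presentation scale of the scores (default 10)
#' @return object of class `composite_result`: list with `scores`
#'   (per-sample data.frame), `group_stats` (per-score comparison),
#'   `boxplot_data`, `selection`, `empty_selection`, `scale`
#' @export
composite_scores <- function(normalized, selection, study, scale = 10) {
  sel <- selection[selection$selected, , drop = FALSE]
  sel <- sel[sel$trait %in% names(normalized), , drop = FALSE]
  region <- study$region[match(normalized$sample_id, study$sample_id)]
  empty <- nrow(sel) == 0
  fam_traits <- list(
    phfcs = sel$trait,
    ccs = sel$trait[sel$family == "content"],
    mcs = sel$trait[sel$family == "morphometry"],
    acs = sel$trait[sel$family == "architecture"],
    fcs_fine = sel$trait[!is.na(sel$stratum) & sel$stratum == "fine"],
    fcs_assembled = sel$trait[!is.na(sel$stratum) & sel$stratum == "assembled"])
  scores <- data.frame(sample_id = normalized$sample_id, region = region)
  for (sc in names(fam_traits)) {
    cols <- fam_traits[[sc]]
    scores[[sc]] <- if (length(cols) == 0) NA_real_ else {
      m <- as.matrix(normalized[, cols, drop = FALSE])
      scale * rowMeans(m, na.rm = TRUE)
    }
  }
  gs <- lapply(names(fam_traits), function(sc) {
    v <- scores[[sc]]
    ok <- is.finite(v)
    x <- v[ok & region == "peri_papillary"]; y <- v[ok & region == "remote"]
    if (length(x) == 0 || length(y) == 0) {
      return(data.frame(score = sc, n_traits = length(fam_traits[[sc]]),
                        mean_peri = NA_real_, sd_peri = NA_real_,
                        mean_remote = NA_real_, sd_remote = NA_real_,
                        median_peri = NA_real_, median_remote = NA_real_,
                        U = NA_real_, p = NA_real_, stars = ""))
    }
    mw <- mann_whitney_u(x, y)
    data.frame(score = sc, n_traits = length(fam_traits[[sc]]),
               mean_peri = mean(x), sd_peri = stats::sd(x),
               mean_remote = mean(y), sd_remote = stats::sd(y),
               median_peri = stats::median(x), median_remote = stats::median(y),
               U = mw$U, p = mw$p, stars = significance_stars(mw$p))
  })
  group_stats <- do.call(rbind, gs)
  bp <- lapply(names(fam_traits), function(sc) {
    do.call(rbind, lapply(REGIONS, function(rg) {
      v <- scores[[sc]][region == rg]
      v <- v[is.finite(v)]
      if (length(v) == 0) return(NULL)
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      data.frame(score = sc, region = rg, min = q[1], q1 = q[2],
                 median = q[3], q3 = q[4], max = q[5])
    }))
  })
  structure(list(scores = scores, group_stats = group_stats,
                 boxplot_data = do.call(rbind, bp), selection = selection,
                 empty_selection = empty, scale = scale),
            class = "composite_result")
}

#' Run selection, normalization and scoring for one compartment
#'
#' @param traits samples x traits data.frame (`sample_id` + trait columns)
#' @param study study table with `sample_id`, `region`
#' @param compartment compartment whose traits to score
#' @param catalog a [trait_catalog()]
#' @param change_min,alpha,p_rule selection parameters, see [select_traits()]
#' @param scale composite score scale
#' @return a [composite_scores()] result
#' @export
score_study <- function(traits, study, compartment = "whole",
                        catalog = trait_catalog(), change_min = 20,
                        alpha = 0.05, p_rule = "less", scale = 10) {
  cols <- names(traits)[startsWith(names(traits), paste0(compartment, "."))]
  sub <- traits[, c("sample_id", cols), drop = FALSE]
  sel <- select_traits(sub, study, catalog, change_min, alpha, p_rule)
  norm <- normalize_traits(sub, sel$trait[sel$selected], catalog)
  composite_scores(norm, sel, study, scale)
}

#' Format a study report across compartments
#'
#' One table per compartment with group mean +/- sd, U, p and significance
#' stars per composite score; optionally written as CSV/JSON together with
#' a run manifest.
#'
#' @param results named list of [composite_scores()] results, keyed by
#'   compartment
#' @param out_dir optional output directory
#' @param params optional list of run parameters recorded in the manifest
#' @return data.frame of class `fibrosis_report` (all compartments stacked)
#' @export
fibrosis_report <- function(results, out_dir = NULL, params = list()) {
  tabs <- lapply(names(results), function(cp) {
    gs <- results[[cp]]$group_stats
    cbind(compartment = cp, gs)
  })
  report <- do.call(rbind, tabs)
  class(report) <- c("fibrosis_report", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report, file.path(out_dir, "composite_report.csv"),
              row.names = FALSE)
    for (cp in names(results)) {
      write.csv(results[[cp]]$scores,
                file.path(out_dir, paste0("scores_", cp, ".csv")),
                row.names = FALSE)
      write.csv(results[[cp]]$selection,
                file.path(out_dir, paste0("selection_", cp, ".csv")),
                row.names = FALSE)
      write.csv(results[[cp]]$boxplot_data,
                file.path(out_dir, paste0("boxplot_", cp, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(
      list(report = report, params = params,
           empty_selection = lapply(results, function(r) r$empty_selection)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  report
}
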