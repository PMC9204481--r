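## Tissue-composition and rupture metrics at lesion and frame level.

#' Round half-up
#'
#' Printed clinical tables round .5 upward; R's `round()` rounds to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded values.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Prevalence percentage with table rounding
#'
#' `100 * count / total`, rounded half-up to one decimal — the aggregation
#' used for every frame- and site-level percentage the package reports.
#'
#' @param count,total non-negative counts, `total > 0`.
#' @return Percent, one decimal.
#' @examples
#' prevalence_pct(391, 2307)  # 16.9
#' @export
prevalence_pct <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  if (count < 0 || count > total) stop("count must be in [0, total]")
  round_half_up(100 * count / total, 1)
}

#' Tissue index
#'
#' Fraction of the unrolled lesion surface occupied by a tissue:
#' `100 * (mean arc in degrees * tissue length) / (lesion length * 360)`.
#'
#' @param mean_arc_deg mean circumferential arc of the tissue (degrees,
#'   0-360).
#' @param tissue_length_mm longitudinal extent of the tissue (mm), at most
#'   the lesion length.
#' @param lesion_length_mm lesion length (mm), positive.
#' @return Index in percent of the lesion surface.
#' @examples
#' tissue_index(150.5, 6.1, 16.3)  # 15.65
#' @export
tissue_index <- function(mean_arc_deg, tissue_length_mm, lesion_length_mm) {
  if (lesion_length_mm <= 0) stop("lesion length must be positive")
  if (mean_arc_deg < 0 || mean_arc_deg > 360) {
    stop("mean arc must be in [0, 360] degrees")
  }
  if (tissue_length_mm < 0 || tissue_length_mm > lesion_length_mm + 1e-9) {
    stop("tissue length must be in [0, lesion length]")
  }
  100 * (mean_arc_deg * tissue_length_mm) / (lesion_length_mm * 360)
}

#' Classify the lesion phenotype
#'
#' A lesion is a fibroatheroma when any frame carries more than one quadrant
#' (90 degrees) of lipid tissue; fibroatheromas are thin-cap (TCFA) when the
#' lesion-minimum fibrous cap thickness is at or below the TCFA threshold
#' (65 micrometres, inclusive), else thick-cap (ThCFA). Lesions without a
#' quadrant of lipid are non-fibroatheromas.
#'
#' @param frames list of `oct_frame` (the lesion's frames).
#' @param thresholds a [threshold_config()].
#' @return `"TCFA"`, `"ThCFA"` or `"non_fibroatheroma"`.
#' @export
classify_phenotype <- function(frames, thresholds = threshold_config()) {
  lipid_arcs <- vapply(frames, frame_arc_deg, numeric(1), kind = "lipid")
  if (!any(lipid_arcs > thresholds$quadrant_deg)) return("non_fibroatheroma")
  caps <- cap_statistics(frames)
  if (!is.finite(caps$min_fct_um)) {
    stop("fibroatheroma lesion with no cap-thickness data")
  }
  if (caps$min_fct_um <= thresholds$tcfa_cap_um) "TCFA" else "ThCFA"
}

#' Fibrous cap thickness statistics
#'
#' Minimum and mean cap thickness over the lesion. Angular cap samples are
#' pooled across all lipid-bearing frames with equal weight (the alternative
#' — averaging per-frame means — is not used; see the methods vignette).
#'
#' @param frames list of `oct_frame`.
#' @return List with `min_fct_um` and `mean_fct_um` (both `NA` when no frame
#'   carries cap samples).
#' @export
cap_statistics <- function(frames) {
  samples <- unlist(lapply(frames, `[[`, "cap_thickness_um"))
  if (is.null(samples) || !length(samples)) {
    return(list(min_fct_um = NA_real_, mean_fct_um = NA_real_))
  }
  list(min_fct_um = min(samples), mean_fct_um = mean(samples))
}

#' Detect a qualifying microchannel run
#'
#' Microchannels must appear as signal-poor holes of diameter at most
#' 300 micrometres in at least 3 consecutive frames.
#'
#' @param frames list of `oct_frame` in axial order.
#' @param thresholds a [threshold_config()].
#' @return `TRUE` iff a qualifying run exists.
#' @export
detect_microchannel_runs <- function(frames, thresholds = threshold_config()) {
  cand <- vapply(frames, function(fr) {
    !is.null(fr$microchannel_diameter_um) &&
      fr$microchannel_diameter_um <= thresholds$microchannel_max_diameter_um
  }, logical(1))
  if (!any(cand)) return(FALSE)
  runs <- rle(cand)
  any(runs$values &
        runs$lengths >= thresholds$microchannel_min_consecutive_frames)
}

#' Thrombus score
#'
#' Percentage of analyzed lumen quadrants containing thrombus:
#' `100 * (flagged quadrants) / (4 * analyzed frames)`.
#'
#' @param frames list of `oct_frame` (the analyzed frames).
#' @return Score in percent, 0-100.
#' @export
thrombus_score <- function(frames) {
  if (!length(frames)) stop("no analyzed frames")
  flagged <- sum(vapply(frames, function(fr) sum(fr$thrombus_quadrants),
                        numeric(1)))
  100 * flagged / (4 * length(frames))
}

#' Rupture cavity metrics
#'
#' Rupture length is the number of rupture frames per contiguous site times
#' the frame spacing, summed over sites. Depth is the maximum over frames of
#' the largest radial distance between the approximated (pre-rupture) lumen
#' border and the cavity border; an annotated per-frame `rupture_depth_mm`
#' takes precedence over profile subtraction. Arc is the mean over rupture
#' frames of the per-frame maximum rupture span. The extent index applies
#' the [tissue_index()] formula to the rupture arc and length.
#'
#' @param frames list of `oct_frame` (the lesion's frames, axial order).
#' @param spacing_mm frame spacing (mm).
#' @param lesion_length_mm lesion length (mm) for the extent index.
#' @return List with `n_rupture_sites`, `rupture_length_mm`,
#'   `rupture_depth_mm`, `rupture_arc_deg`, `rupture_extent_index`.
#'   All zero / `NA` when no frame ruptures. A cavity lying everywhere
#'   inside the approximated lumen yields depth 0 with a warning.
#' @export
rupture_metrics <- function(frames, spacing_mm, lesion_length_mm) {
  rup <- vapply(frames, `[[`, logical(1), "rupture_present")
  if (!any(rup)) {
    return(list(n_rupture_sites = 0L, rupture_length_mm = 0,
                rupture_depth_mm = NA_real_, rupture_arc_deg = NA_real_,
                rupture_extent_index = 0))
  }
  runs <- rle(rup)
  n_sites <- sum(runs$values)
  length_mm <- sum(runs$lengths[runs$values]) * spacing_mm
  depths <- vapply(frames[rup], function(fr) {
    if (!is.null(fr$rupture_depth_mm)) return(fr$rupture_depth_mm)
    if (is.null(fr$approximated_lumen_radius) || is.null(fr$lumen_radius)) {
      return(NA_real_)
    }
    max(fr$lumen_radius - fr$approximated_lumen_radius)
  }, numeric(1))
  depth <- if (all(is.na(depths))) NA_real_ else max(depths, na.rm = TRUE)
  if (is.finite(depth) && depth < 0) {
    warning("cavity border lies inside the approximated lumen everywhere; ",
            "depth set to 0")
    depth <- 0
  }
  max_arcs <- vapply(frames[rup], function(fr) {
    w <- vapply(Filter(function(a) a$kind == "rupture", fr$arcs),
                arc_width, numeric(1))
    if (length(w)) max(w) else NA_real_
  }, numeric(1))
  arc <- mean(max_arcs, na.rm = TRUE)
  idx <- if (is.finite(arc)) {
    tissue_index(arc, min(length_mm, lesion_length_mm), lesion_length_mm)
  } else 0
  list(n_rupture_sites = n_sites, rupture_length_mm = length_mm,
       rupture_depth_mm = depth, rupture_arc_deg = arc,
       rupture_extent_index = idx)
}

frame_feature_predicates <- function(thresholds) {
  cap_ok <- function(fr) !is.null(fr$cap_thickness_um) &&
    length(fr$cap_thickness_um) > 0
  list(
    tcfa = function(fr) {
      frame_arc_deg(fr, "lipid") > thresholds$quadrant_deg && cap_ok(fr) &&
        min(fr$cap_thickness_um) <= thresholds$tcfa_cap_um
    },
    thcfa = function(fr) {
      frame_arc_deg(fr, "lipid") > thresholds$quadrant_deg && cap_ok(fr) &&
        min(fr$cap_thickness_um) > thresholds$tcfa_cap_um
    },
    lipid = function(fr) frame_arc_deg(fr, "lipid") > 0,
    calcific = function(fr) frame_arc_deg(fr, "calcific") > 0,
    macrophages = function(fr) {
      frame_arc_deg(fr, "macrophage_spotted") > 0 ||
        frame_arc_deg(fr, "macrophage_lined") > 0
    },
    macrophages_spotted = function(fr) {
      frame_arc_deg(fr, "macrophage_spotted") > 0
    },
    macrophages_lined = function(fr) frame_arc_deg(fr, "macrophage_lined") > 0,
    microchannel = function(fr) {
      !is.null(fr$microchannel_diameter_um) &&
        fr$microchannel_diameter_um <= thresholds$microchannel_max_diameter_um
    },
    cholesterol_crystal = function(fr) fr$cholesterol_crystal,
    rupture = function(fr) fr$rupture_present,
    thrombus = function(fr) any(fr$thrombus_quadrants)
  )
}

#' Frame-level feature prevalence over a cohort
#'
#' Counts analyzed (culprit-lesion) frames where a feature predicate holds,
#' over all pullbacks of a cohort. Frame-level TCFA/ThCFA are the per-frame
#' analogues of the lesion rule: more than a quadrant of lipid with a local
#' minimum cap at or below / above the TCFA threshold.
#'
#' @param cohort list of `oct_pullback` objects.
#' @param feature one of `"tcfa"`, `"thcfa"`, `"lipid"`, `"calcific"`,
#'   `"macrophages"`, `"macrophages_spotted"`, `"macrophages_lined"`,
#'   `"microchannel"`, `"cholesterol_crystal"`, `"rupture"`, `"thrombus"`.
#' @param thresholds a [threshold_config()].
#' @return List with `count`, `total` and `percent` (half-up, 1 decimal).
#' @export
frame_prevalence <- function(cohort, feature, thresholds = threshold_config()) {
  preds <- frame_feature_predicates(thresholds)
  if (!feature %in% names(preds)) stop("unknown feature: ", feature)
  pred <- preds[[feature]]
  count <- 0L
  total <- 0L
  for (pb in cohort) {
    lim <- delimit_lesion(pb, thresholds)
    frames <- frames_in_range(pb, lim[1], lim[2])
    total <- total + length(frames)
    count <- count + sum(vapply(frames, pred, logical(1)))
  }
  list(count = count, total = total, percent = prevalence_pct(count, total))
}

#' Per-lesion morphometry
#'
#' Computes the full morphological block for one culprit lesion: phenotype,
#' cap statistics, lipid / calcific / lined-macrophage descriptors and
#' indices, microchannel and crystal flags, rupture metrics and thrombus
#' score. The per-frame arc of a tissue is the sum of that tissue's arc
#' spans in the frame; a tissue's length is the count of frames carrying it
#' times the frame spacing. Each index is also emitted in a raw
#' (un-normalized) `arc x length` variant in degree-millimetres.
#'
#' @param pb an `oct_pullback`.
#' @param lesion optional precomputed [lesion_record()]; computed if `NULL`.
#' @param thresholds a [threshold_config()].
#' @return An object of class `morphometry_result` (named list).
#' @export
morphometry <- function(pb, lesion = NULL, thresholds = threshold_config()) {
  if (is.null(lesion)) lesion <- lesion_record(pb, thresholds)
  frames <- frames_in_range(pb, lesion$start_frame, lesion$end_frame)
  llen <- lesion$lesion_length_mm
  sp <- pb$frame_spacing_mm

  arc_stats <- function(kind) {
    arcs <- vapply(frames, frame_arc_deg, numeric(1), kind = kind)
    n <- sum(arcs > 0)
    list(mean_arc = if (n) mean(arcs[arcs > 0]) else NA_real_,
         length_mm = n * sp)
  }
  lip <- arc_stats("lipid")
  cal <- arc_stats("calcific")
  lin <- arc_stats("macrophage_lined")
  spo <- arc_stats("macrophage_spotted")
  idx <- function(s) {
    if (!is.finite(s$mean_arc) || s$length_mm == 0) return(0)
    tissue_index(s$mean_arc, min(s$length_mm, llen), llen)
  }
  raw <- function(s) if (is.finite(s$mean_arc)) s$mean_arc * s$length_mm else 0

  caps <- cap_statistics(frames)
  rup <- rupture_metrics(frames, sp, llen)

  res <- list(
    pullback_ref = pb$id, group = pb$group,
    phenotype = classify_phenotype(frames, thresholds),
    min_fct_um = caps$min_fct_um, mean_fct_um = caps$mean_fct_um,
    mean_lipid_arc_deg = lip$mean_arc, lipid_length_mm = lip$length_mm,
    lipid_index = idx(lip), lipid_surface_deg_mm = raw(lip),
    calcific_present = cal$length_mm > 0,
    mean_calcific_arc_deg = cal$mean_arc, calcific_length_mm = cal$length_mm,
    calcific_index = idx(cal), calcific_surface_deg_mm = raw(cal),
    macrophages_spotted = spo$length_mm > 0,
    macrophages_lined = lin$length_mm > 0,
    lined_macrophage_index = idx(lin),
    microchannel_present = detect_microchannel_runs(frames, thresholds),
    crystal_present = any(vapply(frames, `[[`, logical(1),
                                 "cholesterol_crystal")),
    n_rupture_sites = rup$n_rupture_sites,
    rupture_length_mm = rup$rupture_length_mm,
    rupture_depth_mm = rup$rupture_depth_mm,
    rupture_arc_deg = rup$rupture_arc_deg,
    rupture_extent_index = rup$rupture_extent_index,
    thrombus_present = any(vapply(frames, function(fr) {
      any(fr$thrombus_quadrants)
    }, logical(1))),
    thrombus_score_pct = thrombus_score(frames))
  class(res) <- "morphometry_result"
  res
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("Morphometry [%s, %s]: %s\n", x$pullback_ref, x$group,
              x$phenotype))
  cat(sprintf("  FCT min/mean %.0f/%.0f um; lipid arc %.1f deg x %.1f mm (index %.1f)\n",
              x$min_fct_um, x$mean_fct_um, x$mean_lipid_arc_deg,
              x$lipid_length_mm, x$lipid_index))
  cat(sprintf("  %d rupture site(s), depth %.2f mm, thrombus score %.1f%%\n",
              x$n_rupture_sites, x$rupture_depth_mm, x$thrombus_score_pct))
  invisible(x)
}

#' Flatten lesion + morphometry records to a one-row data.frame
#'
#' @param lesion a [lesion_record()].
#' @param morph the matching [morphometry()] result.
#' @return A one-row data.frame with the Table-style lesion-level metrics.
#' @export
lesion_metric_row <- function(lesion, morph) {
  data.frame(
    pullback_ref = lesion$pullback_ref, group = lesion$group,
    lesion_length_mm = lesion$lesion_length_mm, mla_mm2 = lesion$mla_mm2,
    prox_ref_area_mm2 = lesion$prox_ref_area_mm2,
    dist_ref_area_mm2 = lesion$dist_ref_area_mm2,
    area_stenosis_pct = lesion$area_stenosis_pct,
    rg_upstream = lesion$rg_upstream, rg_downstream = lesion$rg_downstream,
    phenotype = morph$phenotype,
    min_fct_um = morph$min_fct_um, mean_fct_um = morph$mean_fct_um,
    mean_lipid_arc_deg = morph$mean_lipid_arc_deg,
    lipid_length_mm = morph$lipid_length_mm, lipid_index = morph$lipid_index,
    calcific_present = morph$calcific_present,
    mean_calcific_arc_deg = morph$mean_calcific_arc_deg,
    calcific_index = morph$calcific_index,
    macrophages_spotted = morph$macrophages_spotted,
    macrophages_lined = morph$macrophages_lined,
    lined_macrophage_index = morph$lined_macrophage_index,
    microchannel_present = morph$microchannel_present,
    crystal_present = morph$crystal_present,
    n_rupture_sites = morph$n_rupture_sites,
    rupture_length_mm = morph$rupture_length_mm,
    rupture_depth_mm = morph$rupture_depth_mm,
    rupture_arc_deg = morph$rupture_arc_deg,
    rupture_extent_index = morph$rupture_extent_index,
    thrombus_present = morph$thrombus_present,
    thrombus_score_pct = morph$thrombus_score_pct,
    stringsAsFactors = FALSE)
}
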