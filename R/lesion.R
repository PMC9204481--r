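## Culprit-lesion delimitation and geometric metrics.
##
## Axial convention: frames are stored proximal-to-distal, so frame 0 is the
## most proximal analyzed cross-section and z_mm increases towards the distal
## vessel. "Upstream" therefore means lower z than the MLA. Ties for the
## minimum lumen area are broken towards the distal frame (higher index) by
## default; both this and the boundary-frame rule (exact 2.5 mm boundaries
## belong to the MLA site) are documented conventions.

#' Delimit the culprit lesion
#'
#' Applies the group-specific border rule. Native-vessel (PR-NV) lesions run
#' from the first to the last frame that carries lipid tissue or has a plaque
#' burden (EEM area minus lumen area, over EEM area) of at least 40 percent;
#' frames whose EEM is not annotated (not visible) are skipped for the burden
#' criterion. Neoatherosclerotic (PR-NA) lesions run from the most proximal
#' to the most distal frame with mean neointima thickness of at least 0.5 mm;
#' where a PR-NA lesion extends beyond the stented segment (frames without a
#' stent contour), the native-vessel rule is applied to those frames.
#'
#' @param pb an `oct_pullback`.
#' @param thresholds a [threshold_config()].
#' @return Integer vector `c(start_frame, end_frame)` of frame indices
#'   (proximal, distal).
#' @export
delimit_lesion <- function(pb, thresholds = threshold_config()) {
  validate_pullback(pb)
  qual <- vapply(pb$frames, function(fr) {
    in_stent <- !is.null(fr$stent_area_mm2) ||
      !is.null(fr$neointima_thickness_mm)
    if (pb$group == "PR-NA" && in_stent) {
      !is.null(fr$neointima_thickness_mm) &&
        fr$neointima_thickness_mm >= thresholds$neointima_min_thickness_mm
    } else {
      frame_qualifies_nv(fr, thresholds)
    }
  }, logical(1))
  if (!any(qual)) stop("no lesion: no frame satisfies the border rule")
  idx <- vapply(pb$frames, `[[`, integer(1), "frame_index")
  c(start_frame = idx[which(qual)[1]],
    end_frame = idx[which(qual)[sum(qual)]])
}

frame_qualifies_nv <- function(fr, thresholds) {
  if (frame_arc_deg(fr, "lipid") > 0) return(TRUE)
  if (is.null(fr$eem_area_mm2)) return(FALSE)  # EEM not visible: skip burden
  burden <- 100 * (fr$eem_area_mm2 - frame_lumen_area(fr)) / fr$eem_area_mm2
  burden >= thresholds$plaque_burden_min_pct
}

frames_in_range <- function(pb, start_frame, end_frame) {
  idx <- vapply(pb$frames, `[[`, integer(1), "frame_index")
  pb$frames[idx >= start_frame & idx <= end_frame]
}

#' Minimum lumen area within a frame range
#'
#' @param pb an `oct_pullback`.
#' @param start_frame,end_frame inclusive frame-index range.
#' @param tie `"distal"` (default) or `"proximal"`: which frame wins an exact
#'   tie in lumen area.
#' @return List with `mla_frame` (frame index) and `mla_mm2`.
#' @export
find_mla <- function(pb, start_frame, end_frame, tie = c("distal", "proximal")) {
  tie <- match.arg(tie)
  if (start_frame > end_frame) stop("empty frame range")
  frames <- frames_in_range(pb, start_frame, end_frame)
  if (!length(frames)) stop("empty frame range")
  areas <- vapply(frames, frame_lumen_area, numeric(1))
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  hit <- which(areas == min(areas))
  k <- if (tie == "distal") hit[length(hit)] else hit[1]
  list(mla_frame = idx[k], mla_mm2 = areas[k])
}

#' Split a lesion into upstream, MLA-site and downstream segments
#'
#' The MLA site spans 2.5 mm proximal and distal to the minimum lumen area;
#' upstream and downstream are the remaining proximal and distal portions.
#' Frames landing exactly on a 2.5 mm boundary are assigned to the MLA site.
#'
#' @param pb an `oct_pullback`.
#' @param start_frame,end_frame lesion limits (frame indices).
#' @param mla_frame MLA frame index.
#' @param thresholds a [threshold_config()] (uses `segment_half_length_mm`).
#' @return Named character vector mapping frame index to `"upstream"`,
#'   `"mla_site"` or `"downstream"`; segments may be empty for short lesions.
#' @export
split_segments <- function(pb, start_frame, end_frame, mla_frame,
                           thresholds = threshold_config()) {
  frames <- frames_in_range(pb, start_frame, end_frame)
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  z <- vapply(frames, `[[`, numeric(1), "z_mm")
  z_mla <- z[idx == mla_frame]
  if (!length(z_mla)) stop("mla_frame not inside lesion")
  h <- thresholds$segment_half_length_mm
  dz <- z - z_mla
  seg <- ifelse(dz < -h - 1e-9, "upstream",
                ifelse(dz > h + 1e-9, "downstream", "mla_site"))
  stats::setNames(seg, idx)
}

#' Radius gradient of the lesion shoulders
#'
#' Longitudinal lumen taper: `(R_end - R_MLA) / L` for the proximal
#' (upstream) and distal (downstream) sides, with radii taken as equivalent
#' circular radii of the lumen areas and lengths measured along z from the
#' lesion end to the MLA frame. A side of zero length (MLA at a lesion end)
#' has an undefined gradient, reported as `NA` rather than 0.
#'
#' @param pb an `oct_pullback`.
#' @param start_frame,end_frame,mla_frame lesion limits and MLA frame index.
#' @return Named numeric vector `c(rg_up, rg_down)` in mm/mm.
#' @export
radius_gradient <- function(pb, start_frame, end_frame, mla_frame) {
  frames <- frames_in_range(pb, start_frame, end_frame)
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  z <- vapply(frames, `[[`, numeric(1), "z_mm")
  r <- equivalent_radius(vapply(frames, frame_lumen_area, numeric(1)))
  k <- which(idx == mla_frame)
  l_up <- z[k] - z[1]
  l_down <- z[length(z)] - z[k]
  c(rg_up = if (l_up > 0) (r[1] - r[k]) / l_up else NA_real_,
    rg_down = if (l_down > 0) (r[length(r)] - r[k]) / l_down else NA_real_)
}

#' Percent area stenosis
#'
#' `100 * (1 - MLA / mean(proximal, distal reference area))`, with the
#' reference areas taken at the lesion end frames.
#'
#' @param mla_mm2 minimum lumen area (mm^2).
#' @param prox_ref_mm2,dist_ref_mm2 reference lumen areas (mm^2).
#' @return Percent area stenosis.
#' @examples
#' area_stenosis(2.93, 9.21, 7.78)  # 65.5
#' @export
area_stenosis <- function(mla_mm2, prox_ref_mm2, dist_ref_mm2) {
  if (any(!is.finite(c(mla_mm2, prox_ref_mm2, dist_ref_mm2)))) {
    stop("missing reference or MLA area")
  }
  100 * (1 - mla_mm2 / mean(c(prox_ref_mm2, dist_ref_mm2)))
}

#' Group rupture frames into sites and classify their location
#'
#' Contiguous runs of rupture frames form rupture sites. Each site's peak
#' frame is the one with the largest rupture arc; the site is classed
#' longitudinally by the peak frame's segment (the MLA-site segment is
#' reported as the "throat") and circumferentially as "shoulder" when the
#' rupture-arc midpoint lies within `shoulder_edge_tol_deg` (default 30
#' degrees) of a lipid-pool edge in the peak frame, else "center". The
#' shoulder/center rule is a package convention (no standard definition
#' exists) and is configurable through the thresholds object.
#'
#' @param pb an `oct_pullback`.
#' @param start_frame,end_frame,mla_frame lesion limits and MLA frame.
#' @param thresholds a [threshold_config()].
#' @return A list of `rupture_site` records, each with `frame_range`,
#'   `longitudinal_class` (`"upstream"`, `"throat"`, `"downstream"`),
#'   `circumferential_class` (`"center"`, `"shoulder"`), `peak_frame` and
#'   `distance_to_mla_mm`.
#' @export
classify_rupture_sites <- function(pb, start_frame, end_frame, mla_frame,
                                   thresholds = threshold_config()) {
  frames <- frames_in_range(pb, start_frame, end_frame)
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  z <- vapply(frames, `[[`, numeric(1), "z_mm")
  z_mla <- z[idx == mla_frame]
  rup <- vapply(frames, `[[`, logical(1), "rupture_present")
  if (!any(rup)) return(list())
  for (fr in frames[rup]) {
    if (frame_arc_deg(fr, "rupture") <= 0) {
      stop(sprintf("frame %d flagged rupture_present without a rupture arc",
                   fr$frame_index))
    }
  }
  seg <- split_segments(pb, start_frame, end_frame, mla_frame, thresholds)
  runs <- rle(rup)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sites <- list()
  for (j in which(runs$values)) {
    sel <- starts[j]:ends[j]
    arcs <- vapply(frames[sel], frame_arc_deg, numeric(1), kind = "rupture")
    pk <- sel[which.max(arcs)]
    peak <- frames[[pk]]
    long <- unname(seg[as.character(idx[pk])])
    if (long == "mla_site") long <- "throat"
    circ <- rupture_circumferential_class(peak, thresholds)
    sites[[length(sites) + 1L]] <- structure(
      list(frame_range = idx[sel], peak_frame = idx[pk],
           longitudinal_class = long, circumferential_class = circ,
           distance_to_mla_mm = abs(z[pk] - z_mla)),
      class = "rupture_site")
  }
  sites
}

rupture_circumferential_class <- function(frame, thresholds) {
  rup <- Filter(function(a) a$kind == "rupture", frame$arcs)
  widths <- vapply(rup, arc_width, numeric(1))
  mid <- arc_midpoint(rup[[which.max(widths)]])
  lip <- Filter(function(a) a$kind == "lipid", frame$arcs)
  if (!length(lip)) return("center")
  edges <- unlist(lapply(lip, function(a) c(a$start_deg, a$end_deg)))
  if (any(angle_distance(mid, edges) <= thresholds$shoulder_edge_tol_deg)) {
    "shoulder"
  } else {
    "center"
  }
}

#' Aggregate rupture-site locations over a cohort
#'
#' Tallies site counts by longitudinal and circumferential class with the
#' number of rupture SITES (not lesions) as the percentage denominator: a
#' lesion with two sites contributes two to the denominator.
#'
#' @param sites list of `rupture_site` records pooled over a cohort.
#' @return A data.frame with columns `longitudinal_class`,
#'   `circumferential_class` (`"any"` rows give the longitudinal margins),
#'   `count`, `total` and `percent` (half-up, 1 decimal).
#' @export
aggregate_rupture_sites <- function(sites) {
  total <- length(sites)
  long <- vapply(sites, `[[`, character(1), "longitudinal_class")
  circ <- vapply(sites, `[[`, character(1), "circumferential_class")
  rows <- list()
  for (lc in c("upstream", "throat", "downstream")) {
    rows[[length(rows) + 1L]] <- data.frame(
      longitudinal_class = lc, circumferential_class = "any",
      count = sum(long == lc), total = total,
      percent = prevalence_pct(sum(long == lc), total))
    for (cc in c("center", "shoulder")) {
      n <- sum(long == lc & circ == cc)
      rows[[length(rows) + 1L]] <- data.frame(
        longitudinal_class = lc, circumferential_class = cc,
        count = n, total = total, percent = prevalence_pct(n, total))
    }
  }
  do.call(rbind, rows)
}

#' Geometric lesion record
#'
#' Runs delimitation, MLA search, segment split, radius gradients and area
#' stenosis on one pullback and returns the geometric block of the lesion
#' analysis.
#'
#' @param pb an `oct_pullback`.
#' @param thresholds a [threshold_config()].
#' @return An object of class `lesion_record`: a list with `pullback_ref`,
#'   `group`, `start_frame`, `end_frame`, `lesion_length_mm`, `mla_frame`,
#'   `mla_mm2`, `prox_ref_area_mm2`, `dist_ref_area_mm2`,
#'   `area_stenosis_pct`, `rg_upstream`, `rg_downstream`, `segments`, and
#'   `rupture_sites`.
#' @export
lesion_record <- function(pb, thresholds = threshold_config()) {
  lim <- delimit_lesion(pb, thresholds)
  mla <- find_mla(pb, lim[1], lim[2], tie = thresholds$mla_tie)
  frames <- frames_in_range(pb, lim[1], lim[2])
  z <- vapply(frames, `[[`, numeric(1), "z_mm")
  areas <- vapply(frames, frame_lumen_area, numeric(1))
  rg <- radius_gradient(pb, lim[1], lim[2], mla$mla_frame)
  rec <- list(
    pullback_ref = pb$id, group = pb$group,
    start_frame = unname(lim[1]), end_frame = unname(lim[2]),
    lesion_length_mm = z[length(z)] - z[1],
    mla_frame = mla$mla_frame, mla_mm2 = mla$mla_mm2,
    prox_ref_area_mm2 = areas[1], dist_ref_area_mm2 = areas[length(areas)],
    area_stenosis_pct = area_stenosis(mla$mla_mm2, areas[1],
                                      areas[length(areas)]),
    rg_upstream = unname(rg["rg_up"]), rg_downstream = unname(rg["rg_down"]),
    segments = split_segments(pb, lim[1], lim[2], mla$mla_frame, thresholds),
    rupture_sites = classify_rupture_sites(pb, lim[1], lim[2],
                                           mla$mla_frame, thresholds))
  class(rec) <- "lesion_record"
  rec
}

#' @export
print.lesion_record <- function(x, ...) {
  cat(sprintf(
    "Lesion [%s, %s]: frames %d-%d (%.1f mm), MLA %.2f mm2 at frame %d\n",
    x$pullback_ref, x$group, x$start_frame, x$end_frame, x$lesion_length_mm,
    x$mla_mm2, x$mla_frame))
  cat(sprintf("  area stenosis %.1f%%, RG up %.3f / down %.3f, %d rupture site(s)\n",
              x$area_stenosis_pct, x$rg_upstream, x$rg_downstream,
              length(x$rupture_sites)))
  invisible(x)
}
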