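## Frame-level OCT annotation data model.
##
## Angular convention (fixed for the whole package): angles in degrees,
## counter-clockwise, origin (0 deg) at 3 o'clock on the cross-sectional
## image. Arcs are stored as (start_deg, end_deg) running counter-clockwise
## from start to end; the circumferential width is (end - start) mod 360,
## with 0 mapped to 360 so a full ring is representable.

ARC_KINDS <- c("lipid", "calcific", "macrophage_spotted", "macrophage_lined",
               "rupture", "thrombus")
PULLBACK_GROUPS <- c("PR-NV", "PR-NA")
PULLBACK_VESSELS <- c("LAD", "LCx", "RCA")
SCHEMA_VERSION <- 1L

#' Circumferential arc span
#'
#' A tissue (or rupture/thrombus) arc on one OCT cross-section, stored as a
#' counter-clockwise (start, end) pair in degrees with 0 deg at 3 o'clock.
#' Spans crossing the angular origin are handled exactly by modular
#' arithmetic.
#'
#' @param start_deg,end_deg angles in degrees, reduced modulo 360 into
#'   `[0, 360)`.
#' @param kind one of `"lipid"`, `"calcific"`, `"macrophage_spotted"`,
#'   `"macrophage_lined"`, `"rupture"`, `"thrombus"`.
#' @return An object of class `arc_span`.
#' @examples
#' arc_width(arc_span(350, 20, "lipid"))  # 30, exact across 0 deg
#' @export
arc_span <- function(start_deg, end_deg, kind) {
  kind <- match.arg(kind, ARC_KINDS)
  stopifnot(is.numeric(start_deg), is.numeric(end_deg),
            length(start_deg) == 1L, length(end_deg) == 1L,
            is.finite(start_deg), is.finite(end_deg))
  a <- list(start_deg = start_deg %% 360, end_deg = end_deg %% 360,
            kind = kind)
  class(a) <- "arc_span"
  a
}

#' Width of a circumferential arc in degrees
#'
#' @param arc an [arc_span()].
#' @return Width in degrees, in `(0, 360]`; a span with coincident endpoints
#'   is read as a full ring.
#' @export
arc_width <- function(arc) {
  w <- (arc$end_deg - arc$start_deg) %% 360
  if (w == 0) 360 else w
}

#' Midpoint angle of a circumferential arc
#'
#' @param arc an [arc_span()].
#' @return Midpoint in degrees in `[0, 360)`, measured counter-clockwise from
#'   the start of the span.
#' @export
arc_midpoint <- function(arc) {
  (arc$start_deg + arc_width(arc) / 2) %% 360
}

#' Signed-minimal angular distance between two angles
#'
#' @param a,b angles in degrees.
#' @return Absolute circular distance in `[0, 180]`.
#' @keywords internal
angle_distance <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' One annotated OCT cross-section
#'
#' Constructs and validates a single frame's annotation record. The lumen can
#' be given either as a full angular radius profile (at least 36 uniformly
#' spaced samples, starting at the angular origin) or as an area alone;
#' operations that need the full profile say so in their documentation.
#'
#' @param frame_index non-negative integer position in the pullback.
#' @param z_mm axial position in millimetres.
#' @param lumen_radius optional numeric vector of >= 36 angular radius
#'   samples (mm), uniformly spaced over 360 degrees.
#' @param lumen_area_mm2 optional positive lumen area (mm^2); required when
#'   `lumen_radius` is absent.
#' @param eem_area_mm2 optional external elastic membrane area (mm^2);
#'   must be >= the lumen area when both are present.
#' @param stent_area_mm2 optional stent area (mm^2); must be >= the lumen
#'   area when both are present.
#' @param neointima_thickness_mm optional mean neointima thickness (mm).
#' @param arcs list of [arc_span()] objects.
#' @param cap_thickness_um optional numeric vector of fibrous-cap thickness
#'   samples (micrometres) over the frame's lipid arcs.
#' @param rupture_present logical flag.
#' @param approximated_lumen_radius optional reconstructed pre-rupture lumen
#'   radius profile (mm); only allowed when `rupture_present`.
#' @param rupture_depth_mm optional non-negative rupture cavity depth (mm).
#' @param thrombus_quadrants logical vector of exactly 4 per-quadrant
#'   thrombus flags (quadrant 1 spans 0-90 deg, counter-clockwise).
#' @param microchannel_diameter_um optional positive microchannel candidate
#'   diameter (micrometres).
#' @param cholesterol_crystal logical flag.
#' @param meta named list of extra fields carried through serialization.
#' @return An object of class `oct_frame`.
#' @export
frame_annotation <- function(frame_index, z_mm,
                             lumen_radius = NULL, lumen_area_mm2 = NULL,
                             eem_area_mm2 = NULL, stent_area_mm2 = NULL,
                             neointima_thickness_mm = NULL,
                             arcs = list(),
                             cap_thickness_um = NULL,
                             rupture_present = FALSE,
                             approximated_lumen_radius = NULL,
                             rupture_depth_mm = NULL,
                             thrombus_quadrants = rep(FALSE, 4),
                             microchannel_diameter_um = NULL,
                             cholesterol_crystal = FALSE,
                             meta = list()) {
  fr <- list(frame_index = as.integer(frame_index), z_mm = z_mm,
             lumen_radius = lumen_radius, lumen_area_mm2 = lumen_area_mm2,
             eem_area_mm2 = eem_area_mm2, stent_area_mm2 = stent_area_mm2,
             neointima_thickness_mm = neointima_thickness_mm,
             arcs = arcs, cap_thickness_um = cap_thickness_um,
             rupture_present = isTRUE(rupture_present),
             approximated_lumen_radius = approximated_lumen_radius,
             rupture_depth_mm = rupture_depth_mm,
             thrombus_quadrants = as.logical(thrombus_quadrants),
             microchannel_diameter_um = microchannel_diameter_um,
             cholesterol_crystal = isTRUE(cholesterol_crystal),
             meta = meta)
  class(fr) <- "oct_frame"
  validate_frame(fr)
  fr
}

frame_err <- function(fr, field, msg) {
  stop(sprintf("frame %d, field '%s': %s", fr$frame_index, field, msg),
       call. = FALSE)
}

validate_frame <- function(fr) {
  if (fr$frame_index < 0L) frame_err(fr, "frame_index", "must be >= 0")
  if (!is.numeric(fr$z_mm) || !is.finite(fr$z_mm)) {
    frame_err(fr, "z_mm", "must be a finite number")
  }
  if (is.null(fr$lumen_radius) && is.null(fr$lumen_area_mm2)) {
    frame_err(fr, "lumen_radius",
              "either a radius profile or lumen_area_mm2 is required")
  }
  if (!is.null(fr$lumen_radius)) {
    if (length(fr$lumen_radius) < 36L) {
      frame_err(fr, "lumen_radius", "needs >= 36 angular samples")
    }
    if (any(!is.finite(fr$lumen_radius)) || any(fr$lumen_radius <= 0)) {
      frame_err(fr, "lumen_radius", "all radii must be positive")
    }
  }
  for (f in c("lumen_area_mm2", "eem_area_mm2", "stent_area_mm2",
              "microchannel_diameter_um")) {
    v <- fr[[f]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L ||
                        !is.finite(v) || v <= 0)) {
      frame_err(fr, f, "must be a single positive number")
    }
  }
  if (!is.null(fr$neointima_thickness_mm) &&
      (!is.numeric(fr$neointima_thickness_mm) ||
       fr$neointima_thickness_mm < 0)) {
    frame_err(fr, "neointima_thickness_mm", "must be non-negative")
  }
  la <- frame_lumen_area(fr)
  if (!is.null(fr$eem_area_mm2) && fr$eem_area_mm2 < la - 1e-9) {
    frame_err(fr, "eem_area_mm2", "must be >= lumen area")
  }
  if (!is.null(fr$stent_area_mm2) && fr$stent_area_mm2 < la - 1e-9) {
    frame_err(fr, "stent_area_mm2", "must be >= lumen area")
  }
  if (!all(vapply(fr$arcs, inherits, logical(1), "arc_span"))) {
    frame_err(fr, "arcs", "every element must be an arc_span")
  }
  if (!is.null(fr$cap_thickness_um)) {
    if (any(!is.finite(fr$cap_thickness_um)) || any(fr$cap_thickness_um <= 0)) {
      frame_err(fr, "cap_thickness_um", "all samples must be positive")
    }
  }
  if (!is.null(fr$approximated_lumen_radius)) {
    if (!fr$rupture_present) {
      frame_err(fr, "approximated_lumen_radius",
                "only allowed when rupture_present")
    }
    if (any(fr$approximated_lumen_radius <= 0)) {
      frame_err(fr, "approximated_lumen_radius", "all radii must be positive")
    }
  }
  if (!is.null(fr$rupture_depth_mm) && fr$rupture_depth_mm < 0) {
    frame_err(fr, "rupture_depth_mm", "must be non-negative")
  }
  if (length(fr$thrombus_quadrants) != 4L ||
      any(is.na(fr$thrombus_quadrants))) {
    frame_err(fr, "thrombus_quadrants", "exactly 4 logical flags required")
  }
  invisible(fr)
}

#' Lumen area of a frame
#'
#' Uses the annotated area when present, otherwise integrates the angular
#' radius profile as sectors: `A = (dtheta/2) * sum(r_i^2)`.
#'
#' @param frame an `oct_frame`.
#' @return Lumen area in mm^2.
#' @export
frame_lumen_area <- function(frame) {
  if (!is.null(frame$lumen_area_mm2)) return(frame$lumen_area_mm2)
  r <- frame$lumen_radius
  dtheta <- 2 * pi / length(r)
  dtheta / 2 * sum(r^2)
}

#' Total arc width of a given kind in one frame
#'
#' Per-frame "lipid arc" (and analogues) is the sum of that kind's arc-span
#' widths in the frame; overlap between spans of the same kind is not
#' expected from analysts and is not merged.
#'
#' @param frame an `oct_frame`.
#' @param kind an arc kind (see [arc_span()]).
#' @return Total width in degrees (0 when no such arc).
#' @export
frame_arc_deg <- function(frame, kind) {
  w <- vapply(frame$arcs, function(a) {
    if (a$kind == kind) arc_width(a) else 0
  }, numeric(1))
  if (length(w)) sum(w) else 0
}

#' Annotated OCT pullback
#'
#' An ordered sequence of annotated frames for one culprit vessel, with the
#' pullback-level constants: frame spacing (0.4 mm, or 0.375 mm for the
#' Lunawave system), cohort group and vessel.
#'
#' @param frames list of [frame_annotation()] objects, ordered by `z_mm`.
#' @param frame_spacing_mm 0.4 or 0.375.
#' @param group `"PR-NV"` (plaque rupture, native vessel) or `"PR-NA"`
#'   (plaque rupture, neoatherosclerosis).
#' @param vessel `"LAD"`, `"LCx"` or `"RCA"`.
#' @param patient_meta optional named list of patient-level fields.
#' @param id optional pullback identifier string.
#' @return An object of class `oct_pullback`.
#' @export
pullback <- function(frames, frame_spacing_mm = 0.4, group = "PR-NV",
                     vessel = "LAD", patient_meta = list(), id = NULL) {
  group <- match.arg(group, PULLBACK_GROUPS)
  vessel <- match.arg(vessel, PULLBACK_VESSELS)
  if (!frame_spacing_mm %in% c(0.4, 0.375)) {
    stop("frame_spacing_mm must be 0.4 or 0.375")
  }
  pb <- list(frames = frames, frame_spacing_mm = frame_spacing_mm,
             group = group, vessel = vessel, patient_meta = patient_meta,
             id = if (is.null(id)) "pullback" else as.character(id))
  class(pb) <- "oct_pullback"
  validate_pullback(pb)
  pb
}

#' Validate an annotated pullback
#'
#' Checks every frame invariant plus pullback-level monotonicity: frames must
#' be sorted by axial position with successive differences equal to the frame
#' spacing (to 1e-9 mm).
#'
#' @param pb an `oct_pullback`.
#' @return The pullback, invisibly; stops with an informative error naming
#'   the offending frame and field otherwise.
#' @export
validate_pullback <- function(pb) {
  stopifnot(inherits(pb, "oct_pullback"))
  if (!length(pb$frames)) stop("pullback has no frames")
  lapply(pb$frames, validate_frame)
  z <- vapply(pb$frames, `[[`, numeric(1), "z_mm")
  if (is.unsorted(z, strictly = TRUE)) {
    stop("frames not sorted by z_mm (non-monotone axial positions)")
  }
  dz <- diff(z)
  if (any(abs(dz - pb$frame_spacing_mm) > 1e-9)) {
    bad <- which(abs(dz - pb$frame_spacing_mm) > 1e-9)[1]
    stop(sprintf("z spacing between frames %d and %d is %.6f, expected %.6f",
                 pb$frames[[bad]]$frame_index,
                 pb$frames[[bad + 1L]]$frame_index,
                 dz[bad], pb$frame_spacing_mm))
  }
  invisible(pb)
}

#' @export
print.oct_pullback <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("OCT pullback '%s': %d frames at %.3f mm (%s, %s), %.1f mm\n",
              x$id, n, x$frame_spacing_mm, x$group, x$vessel,
              (n - 1) * x$frame_spacing_mm))
  nr <- sum(vapply(x$frames, `[[`, logical(1), "rupture_present"))
  cat(sprintf("  frames with rupture: %d\n", nr))
  invisible(x)
}

#' Equivalent circular radius of a cross-sectional area
#'
#' Converts an area to the radius of the circle of equal area,
#' `r = sqrt(A / pi)`. Used to turn printed lumen areas into model radii.
#'
#' @param area_mm2 positive area (mm^2); vectorized.
#' @return Radius in mm.
#' @examples
#' equivalent_radius(pi)    # 1
#' equivalent_radius(2.93)  # 0.9657
#' @export
equivalent_radius <- function(area_mm2) {
  if (any(!is.finite(area_mm2)) || any(area_mm2 <= 0)) {
    stop("area must be positive")
  }
  sqrt(area_mm2 / pi)
}
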