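#' Diagnostic threshold configuration
#'
#' Bundles every diagnostic threshold used by the morphometric pipeline into a
#' single configuration object. Defaults are the values in routine use for
#' intravascular OCT plaque analysis: a lesion is a thin-cap fibroatheroma
#' (TCFA) when the minimum fibrous cap thickness over lipid is at or below
#' 65 micrometres; a lipid pool requires a circumferential arc above 45
#' degrees; macrophage accumulations require a lateral extent above 20
#' degrees; microchannels are signal-poor holes of diameter at most 300
#' micrometres seen in at least 3 consecutive frames; thrombus requires a
#' dimension of at least 250 micrometres; native-vessel lesion borders use a
#' plaque burden of at least 40 percent; neoatherosclerotic lesion borders use
#' a mean neointima thickness of at least 0.5 mm; the MLA-site segment extends
#' 2.5 mm either side of the minimum lumen area; a lumen quadrant spans 90
#' degrees; high endothelial shear stress means above 7 Pa; "superficial"
#' wall stress means within 200 micrometres of the lumen.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return An object of class `threshold_config`: a named list with fields
#'   `tcfa_cap_um` (65), `lipid_pool_min_arc_deg` (45),
#'   `macrophage_min_extent_deg` (20), `microchannel_max_diameter_um` (300),
#'   `microchannel_min_consecutive_frames` (3), `thrombus_min_dimension_um`
#'   (250), `plaque_burden_min_pct` (40), `neointima_min_thickness_mm` (0.5),
#'   `segment_half_length_mm` (2.5), `quadrant_deg` (90), `high_ess_pa` (7),
#'   `superficial_depth_um` (200), `shoulder_edge_tol_deg` (30),
#'   `mla_tie` ("distal").
#'
#' `shoulder_edge_tol_deg` and `mla_tie` are analysis conventions rather than
#' diagnostic thresholds: a rupture whose arc midpoint lies within
#' `shoulder_edge_tol_deg` of a lipid-pool edge is classed "shoulder", and
#' ties for the minimum lumen area are broken towards the `mla_tie` end.
#'
#' @examples
#' th <- threshold_config()
#' th$tcfa_cap_um
#' threshold_config(high_ess_pa = 5)$high_ess_pa
#' @export
threshold_config <- function(...) {
  th <- list(
    tcfa_cap_um = 65,
    lipid_pool_min_arc_deg = 45,
    macrophage_min_extent_deg = 20,
    microchannel_max_diameter_um = 300,
    microchannel_min_consecutive_frames = 3,
    thrombus_min_dimension_um = 250,
    plaque_burden_min_pct = 40,
    neointima_min_thickness_mm = 0.5,
    segment_half_length_mm = 2.5,
    quadrant_deg = 90,
    high_ess_pa = 7,
    superficial_depth_um = 200,
    shoulder_edge_tol_deg = 30,
    mla_tie = "distal"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(th))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown threshold field(s): ", paste(bad, collapse = ", "))
    }
    th[names(dots)] <- dots
  }
  num <- setdiff(names(th), "mla_tie")
  for (f in num) {
    if (!is.numeric(th[[f]]) || length(th[[f]]) != 1L || !is.finite(th[[f]]) ||
        th[[f]] <= 0) {
      stop("threshold '", f, "' must be a single positive number")
    }
  }
  th$mla_tie <- match.arg(th$mla_tie, c("distal", "proximal"))
  class(th) <- "threshold_config"
  th
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("OCT analysis thresholds:\n")
  for (f in names(x)) cat(sprintf("  %-36s %s\n", f, format(x[[f]])))
  invisible(x)
}
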