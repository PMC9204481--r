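## Idealized pre-rupture lesion geometry: a straight vessel with a smooth
## cosine-taper stenosis, a fibrous cap / lipid pool wall layering, an EEM
## envelope from the reference sites (remodeling index 1.20 at the MLA where
## the EEM is invisible), and an optional stent ring lattice.

#' Stent specification
#'
#' Circular-strut ring lattice typical of a drug-eluting stent: 90 um strut
#' thickness, 1 mm inter-strut distance, L605 Co-Cr mechanical constants
#' (elastic modulus 243 GPa, Poisson ratio 0.29).
#'
#' @param stent_diameter_mm stent diameter (mm).
#' @param strut_thickness_um strut cross-section diameter (default 90).
#' @param inter_strut_distance_mm axial ring spacing (default 1.0).
#' @param elastic_modulus_gpa strut elastic modulus (default 243).
#' @param poisson_ratio strut Poisson ratio (default 0.29).
#' @return An object of class `stent_spec`.
#' @export
stent_spec <- function(stent_diameter_mm, strut_thickness_um = 90,
                       inter_strut_distance_mm = 1.0,
                       elastic_modulus_gpa = 243, poisson_ratio = 0.29) {
  stopifnot(stent_diameter_mm > 0, strut_thickness_um > 0,
            inter_strut_distance_mm > 0)
  s <- list(stent_diameter_mm = stent_diameter_mm,
            strut_thickness_um = strut_thickness_um,
            inter_strut_distance_mm = inter_strut_distance_mm,
            elastic_modulus_gpa = elastic_modulus_gpa,
            poisson_ratio = poisson_ratio)
  class(s) <- "stent_spec"
  s
}

#' Representative lesion specification
#'
#' Mean geometric parameters from which the idealized pre-rupture geometry
#' is built. Distances are in mm, cap thicknesses in micrometres, arcs in
#' degrees. The MLA axial position defaults to mid-lesion. Reference EEM
#' areas, when not measured, are estimated from the reference lumen areas
#' assuming a 25 percent reference-site plaque burden; the EEM at the MLA is
#' always `remodeling_index` times the mean reference EEM area.
#'
#' @param prox_ref_diameter_mm,dist_ref_diameter_mm,min_lumen_diameter_mm
#'   lumen diameters at the references and the MLA.
#' @param lesion_length_mm lesion length.
#' @param mla_axial_position_mm MLA position in `[0, L]`; default `L/2`.
#' @param cap_min_um,cap_mean_um fibrous cap thickness minimum and mean.
#' @param lipid_arc_deg,lipid_length_mm lipid-pool circumferential arc and
#'   longitudinal extent.
#' @param lipid_offset_from_mla_mm axial offset of the pool center from the
#'   MLA (negative = proximal); default 0.
#' @param remodeling_index EEM-area remodeling ratio at the MLA (default
#'   1.20).
#' @param prox_ref_eem_mm2,dist_ref_eem_mm2 optional measured reference EEM
#'   areas.
#' @param reference_burden_pct assumed reference-site plaque burden used
#'   when reference EEM areas are not given (default 25).
#' @param stent optional [stent_spec()]; its diameter defaults to the mean
#'   reference lumen diameter when built via [mean_lesion_spec()].
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(prox_ref_diameter_mm, dist_ref_diameter_mm,
                        min_lumen_diameter_mm, lesion_length_mm,
                        mla_axial_position_mm = lesion_length_mm / 2,
                        cap_min_um = 49, cap_mean_um = 186,
                        lipid_arc_deg = 150, lipid_length_mm = 6,
                        lipid_offset_from_mla_mm = 0,
                        remodeling_index = 1.20,
                        prox_ref_eem_mm2 = NULL, dist_ref_eem_mm2 = NULL,
                        reference_burden_pct = 25, stent = NULL) {
  if (min_lumen_diameter_mm > prox_ref_diameter_mm ||
      min_lumen_diameter_mm > dist_ref_diameter_mm) {
    stop("minimum lumen diameter must not exceed the reference diameters")
  }
  if (remodeling_index < 1) stop("remodeling_index must be >= 1")
  if (cap_min_um > cap_mean_um) stop("cap_min_um must be <= cap_mean_um")
  if (lipid_length_mm > lesion_length_mm) {
    stop("lipid length cannot exceed lesion length")
  }
  sp <- list(prox_ref_diameter_mm = prox_ref_diameter_mm,
             dist_ref_diameter_mm = dist_ref_diameter_mm,
             min_lumen_diameter_mm = min_lumen_diameter_mm,
             lesion_length_mm = lesion_length_mm,
             mla_axial_position_mm = mla_axial_position_mm,
             cap_min_um = cap_min_um, cap_mean_um = cap_mean_um,
             lipid_arc_deg = lipid_arc_deg, lipid_length_mm = lipid_length_mm,
             lipid_offset_from_mla_mm = lipid_offset_from_mla_mm,
             remodeling_index = remodeling_index,
             prox_ref_eem_mm2 = prox_ref_eem_mm2,
             dist_ref_eem_mm2 = dist_ref_eem_mm2,
             reference_burden_pct = reference_burden_pct,
             stent = stent)
  class(sp) <- "lesion_spec"
  sp
}

#' Cosine-taper lumen radius profile
#'
#' Smooth stenosis through (0, proximal reference radius) -> (MLA position,
#' minimum radius) -> (L, distal reference radius) built from two
#' half-cosine tapers; the derivative vanishes at both ends and at the MLA,
#' so the profile is C1-continuous. The profile family is a package choice
#' and is pluggable (any function z -> r can be handed to downstream steps).
#'
#' @param spec a [lesion_spec()].
#' @param n_stations number of axial stations (>= 41).
#' @return List with `z` (mm), `r` (lumen radius, mm) and `spec`.
#' @export
build_lumen_profile <- function(spec, n_stations = 201) {
  stopifnot(inherits(spec, "lesion_spec"), n_stations >= 41)
  L <- spec$lesion_length_mm
  zm <- spec$mla_axial_position_mm
  if (zm < 0 || zm > L) stop("MLA position outside [0, lesion length]")
  z <- seq(0, L, length.out = n_stations)
  rp <- spec$prox_ref_diameter_mm / 2
  rd <- spec$dist_ref_diameter_mm / 2
  rm <- spec$min_lumen_diameter_mm / 2
  r <- numeric(n_stations)
  up <- z <= zm
  if (zm > 0) {
    r[up] <- rm + (rp - rm) * (1 + cos(pi * z[up] / zm)) / 2
  } else {
    r[up] <- rm
  }
  if (zm < L) {
    r[!up] <- rm + (rd - rm) * (1 - cos(pi * (z[!up] - zm) / (L - zm))) / 2
  }
  list(z = z, r = r, spec = spec)
}

#' Build the layered wall around a lumen profile
#'
#' Adds to the lumen profile: a fibrous-cap thickness field whose minimum
#' equals `cap_min_um` at the lipid-pool crown (a quarter pool-length
#' proximal to the pool center, snapped to the station grid) and which
#' relaxes to `cap_mean_um` away from the crown; the lipid pool region
#' (axial range x circumferential arc); the EEM radius interpolated (in
#' area) between the reference-site EEM values and the remodeled EEM at the
#' MLA; and, for stented specs, the strut ring lattice at the stent radius
#' with one ring per `inter_strut_distance_mm` starting at z = 0.
#'
#' @param spec a [lesion_spec()].
#' @param profile a [build_lumen_profile()] result (built if `NULL`).
#' @param n_stations stations used when `profile` is `NULL`.
#' @return An object of class `idealized_geometry`: list with `z`,
#'   `lumen_r`, `cap_thickness_mm`, `cap_outer_r`, `eem_r`, `lipid_pool`
#'   (`z_range`, `arc_deg`, `crown_z`), `strut_z`, `stent_r`, `spec`.
#' @export
build_wall <- function(spec, profile = NULL, n_stations = 201) {
  if (is.null(profile)) profile <- build_lumen_profile(spec, n_stations)
  z <- profile$z
  r <- profile$r
  L <- spec$lesion_length_mm
  zm <- spec$mla_axial_position_mm

  pool_center <- zm + spec$lipid_offset_from_mla_mm
  pool <- c(pool_center - spec$lipid_length_mm / 2,
            pool_center + spec$lipid_length_mm / 2)
  pool <- pmin(pmax(pool, 0), L)
  crown_target <- max(pool_center - spec$lipid_length_mm / 4, pool[1])
  crown_z <- z[which.min(abs(z - crown_target))]  # snap to grid

  cap_mean <- spec$cap_mean_um / 1000
  cap_min <- spec$cap_min_um / 1000
  w <- max(spec$lipid_length_mm / 6, 3 * (z[2] - z[1]))
  cap <- cap_mean - (cap_mean - cap_min) * exp(-((z - crown_z) / w)^2)
  if (min(cap) < cap_min - 1e-12) stop("cap thinner than cap_min")

  ref_eem <- function(d_ref, measured) {
    if (!is.null(measured)) return(measured)
    pi * (d_ref / 2)^2 / (1 - spec$reference_burden_pct / 100)
  }
  eem_p <- ref_eem(spec$prox_ref_diameter_mm, spec$prox_ref_eem_mm2)
  eem_d <- ref_eem(spec$dist_ref_diameter_mm, spec$dist_ref_eem_mm2)
  eem_mla <- spec$remodeling_index * mean(c(eem_p, eem_d))
  eem_area <- stats::approx(c(0, zm, L), c(eem_p, eem_mla, eem_d),
                            xout = z, rule = 2)$y
  eem_r <- equivalent_radius(eem_area)

  cap_outer <- r + cap
  # the EEM must envelope the intimal layer; where the interpolated EEM
  # would cut into a thick cap, push it out with a 0.1 mm adventitial margin
  eem_r <- pmax(eem_r, cap_outer + 0.1)
  if (any(cap_outer > eem_r + 1e-9)) {
    stop("wall layering inconsistent: cap outer radius exceeds the EEM")
  }

  strut_z <- NULL
  stent_r <- NULL
  if (!is.null(spec$stent)) {
    strut_z <- seq(0, L, by = spec$stent$inter_strut_distance_mm)
    stent_r <- spec$stent$stent_diameter_mm / 2
  }
  g <- list(z = z, lumen_r = r, cap_thickness_mm = cap,
            cap_outer_r = cap_outer, eem_r = eem_r,
            lipid_pool = list(z_range = pool, arc_deg = spec$lipid_arc_deg,
                              crown_z = crown_z),
            strut_z = strut_z, stent_r = stent_r, spec = spec)
  class(g) <- "idealized_geometry"
  g
}

#' @export
print.idealized_geometry <- function(x, ...) {
  cat(sprintf("Idealized lesion geometry: L=%.1f mm, %d stations, MLA %.2f mm2 at z=%.1f mm\n",
              max(x$z), length(x$z), pi * min(x$lumen_r)^2,
              x$z[which.min(x$lumen_r)]))
  cat(sprintf("  cap %.0f-%.0f um, lipid pool %.1f-%.1f mm x %.0f deg%s\n",
              1000 * min(x$cap_thickness_mm), 1000 * max(x$cap_thickness_mm),
              x$lipid_pool$z_range[1], x$lipid_pool$z_range[2],
              x$lipid_pool$arc_deg,
              if (is.null(x$strut_z)) "" else
                sprintf(", %d stent rings", length(x$strut_z))))
  invisible(x)
}

#' Lumen volume of a geometry
#'
#' Trapezoidal integration of `pi * r(z)^2` along the axis.
#'
#' @param geom an `idealized_geometry` or a lumen profile.
#' @return Volume in mm^3.
#' @export
lumen_volume <- function(geom) {
  z <- geom$z
  r <- if (!is.null(geom$lumen_r)) geom$lumen_r else geom$r
  a <- pi * r^2
  sum(diff(z) * (a[-1] + a[-length(a)]) / 2)
}

#' Mean lesion specification of a cohort
#'
#' Arithmetic means of the per-lesion geometric descriptors, with diameters
#' obtained from areas via twice the equivalent circular radius. Rupture
#' frames contribute their approximated (pre-rupture) lumen, which is
#' already reflected in the per-lesion metric table.
#'
#' @param metrics data.frame of per-lesion metrics (columns `mla_mm2`,
#'   `prox_ref_area_mm2`, `dist_ref_area_mm2`, `lesion_length_mm`,
#'   `min_fct_um`, `mean_fct_um`, `mean_lipid_arc_deg`, `lipid_length_mm`;
#'   optional `lipid_offset_from_mla_mm`).
#' @param stented build a stented spec (stent diameter = mean reference
#'   lumen diameter unless `stent_diameter_mm` given).
#' @param stent_diameter_mm optional explicit stent diameter.
#' @return A [lesion_spec()].
#' @export
mean_lesion_spec <- function(metrics, stented = FALSE,
                             stent_diameter_mm = NULL) {
  if (!nrow(metrics)) stop("empty cohort")
  m <- function(v) mean(metrics[[v]], na.rm = TRUE)
  dia <- function(v) mean(2 * equivalent_radius(
    metrics[[v]][is.finite(metrics[[v]])]))
  prox_d <- dia("prox_ref_area_mm2")
  dist_d <- dia("dist_ref_area_mm2")
  offset <- if ("lipid_offset_from_mla_mm" %in% names(metrics)) {
    m("lipid_offset_from_mla_mm")
  } else 0
  stent <- NULL
  if (stented) {
    d <- if (!is.null(stent_diameter_mm)) stent_diameter_mm else
      mean(c(prox_d, dist_d))
    stent <- stent_spec(d)
  }
  lesion_spec(
    prox_ref_diameter_mm = prox_d, dist_ref_diameter_mm = dist_d,
    min_lumen_diameter_mm = dia("mla_mm2"),
    lesion_length_mm = m("lesion_length_mm"),
    cap_min_um = m("min_fct_um"), cap_mean_um = m("mean_fct_um"),
    lipid_arc_deg = m("mean_lipid_arc_deg"),
    lipid_length_mm = min(m("lipid_length_mm"), m("lesion_length_mm")),
    lipid_offset_from_mla_mm = offset, stent = stent)
}

#' Export a geometry to disk
#'
#' `"stl"` writes a watertight triangulated surface of revolution of the
#' lumen (ASCII STL — a text format readable by the same mesh tools as its
#' binary sibling); `"profile-csv"` writes the station table (z, lumen
#' radius, cap thickness, cap outer radius, EEM radius), which re-imports
#' losslessly.
#'
#' @param geom an `idealized_geometry`.
#' @param path output file path.
#' @param format `"stl"` or `"profile-csv"`.
#' @param n_theta circumferential facets for STL (default 48).
#' @return `path`, invisibly.
#' @export
export_geometry <- function(geom, path, format = c("stl", "profile-csv"),
                            n_theta = 48) {
  format <- match.arg(format)
  if (format == "profile-csv") {
    utils::write.csv(data.frame(z_mm = geom$z, lumen_r_mm = geom$lumen_r,
                                cap_thickness_mm = geom$cap_thickness_mm,
                                cap_outer_r_mm = geom$cap_outer_r,
                                eem_r_mm = geom$eem_r),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  tri <- revolve_mesh(geom$z, geom$lumen_r, n_theta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid lumen", con)
  for (k in seq_len(dim(tri)[1])) {
    v <- tri[k, , ]
    n <- pracma_cross(v[2, ] - v[1, ], v[3, ] - v[1, ])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         v[, 1], v[, 2], v[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid lumen", con)
  invisible(path)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Triangulated surface of revolution with end caps; returns an
# (n_tri x 3 vertices x 3 coords) array.
revolve_mesh <- function(z, r, n_theta = 48) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  nxt <- c(2:n_theta, 1)
  tris <- list()
  ring <- function(i) cbind(r[i] * cos(th), r[i] * sin(th), z[i])
  a <- ring(1)
  for (i in seq_len(length(z) - 1)) {
    b <- ring(i + 1)
    for (j in seq_len(n_theta)) {
      tris[[length(tris) + 1L]] <- rbind(a[j, ], b[j, ], b[nxt[j], ])
      tris[[length(tris) + 1L]] <- rbind(a[j, ], b[nxt[j], ], a[nxt[j], ])
    }
    a <- b
  }
  cap <- function(i, flip) {
    ctr <- c(0, 0, z[i])
    rg <- ring(i)
    for (j in seq_len(n_theta)) {
      t <- if (flip) rbind(ctr, rg[nxt[j], ], rg[j, ]) else
        rbind(ctr, rg[j, ], rg[nxt[j], ])
      tris[[length(tris) + 1L]] <<- t
    }
  }
  cap(1, flip = TRUE)
  cap(length(z), flip = FALSE)
  out <- array(0, dim = c(length(tris), 3, 3))
  for (k in seq_along(tris)) out[k, , ] <- tris[[k]]
  out
}

#' Check that a triangulated surface is watertight
#'
#' Every undirected edge must be shared by exactly two facets.
#'
#' @param path an ASCII STL file written by [export_geometry()].
#' @return `TRUE` if watertight.
#' @export
stl_watertight <- function(path) {
  lines <- readLines(path)
  vx <- lines[grepl("^\\s*vertex", lines)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  key <- apply(round(verts, 9), 1, paste, collapse = ",")
  id <- match(key, unique(key))
  n_tri <- length(id) / 3
  edges <- character(0)
  for (k in seq_len(n_tri)) {
    v <- id[(3 * k - 2):(3 * k)]
    e <- rbind(sort(v[1:2]), sort(v[2:3]), sort(v[c(1, 3)]))
    edges <- c(edges, paste(e[, 1], e[, 2], sep = "-"))
  }
  all(table(edges) == 2)
}
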