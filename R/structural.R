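## Plaque structural stress (PSS) surrogates: Lame thick-walled cylinder,
## incompressible Mooney-Rivlin uniaxial response, and a layered-cylinder /
## Laplace cap-stress estimator with a stent "caging" reduction.

#' Wall material model
#'
#' Either a 5-parameter incompressible Mooney-Rivlin hyperelastic model
#' (`W = c10(I1-3) + c01(I2-3) + c20(I1-3)^2 + c11(I1-3)(I2-3) +
#' c02(I2-3)^2`) for plaque / neointima tissue, or a linear elastic model
#' for stent struts (defaults: L605 Co-Cr, E = 243 GPa, nu = 0.29). The
#' Mooney-Rivlin coefficients default to values in common use for fibrous
#' arterial tissue; they are configuration, and every stress result records
#' the coefficients used.
#'
#' @param kind `"mooney_rivlin_5"` or `"linear_elastic"`.
#' @param c10,c01,c20,c11,c02 Mooney-Rivlin coefficients (kPa).
#' @param elastic_modulus_gpa,poisson_ratio linear-elastic constants.
#' @return An object of class `material_model`.
#' @export
material_model <- function(kind = c("mooney_rivlin_5", "linear_elastic"),
                           c10 = 18.9, c01 = 2.75, c20 = 85.72,
                           c11 = 0, c02 = 0,
                           elastic_modulus_gpa = 243, poisson_ratio = 0.29) {
  kind <- match.arg(kind)
  m <- list(kind = kind,
            c10 = c10, c01 = c01, c20 = c20, c11 = c11, c02 = c02,
            elastic_modulus_gpa = elastic_modulus_gpa,
            poisson_ratio = poisson_ratio)
  class(m) <- "material_model"
  m
}

#' Lame thick-walled cylinder stresses
#'
#' Closed-form hoop and radial stress through a pressurized thick-walled
#' cylinder — the analytic oracle for wall stress:
#' `sigma_theta(r) = A + B/r^2`, `sigma_r(r) = A - B/r^2` with
#' `A = (p_in a^2 - p_out b^2)/(b^2 - a^2)` and
#' `B = (p_in - p_out) a^2 b^2 / (b^2 - a^2)`.
#'
#' @param inner_r_mm,outer_r_mm inner and outer radii (mm), `0 < a < b`.
#' @param p_in_kpa,p_out_kpa internal and external pressure (kPa).
#' @param r_mm radii at which to evaluate (defaults to 50 points through
#'   the wall).
#' @return List with `r_mm`, `sigma_theta_kpa`, `sigma_r_kpa`.
#' @examples
#' # 100 mmHg in a 1 mm / 2 mm cylinder: inner hoop stress 22.2 kPa
#' lame_cylinder(1, 2, 13.3322, 0)$sigma_theta_kpa[1]
#' @export
lame_cylinder <- function(inner_r_mm, outer_r_mm, p_in_kpa, p_out_kpa = 0,
                          r_mm = NULL) {
  a <- inner_r_mm
  b <- outer_r_mm
  if (!(a > 0 && b > a)) stop("need 0 < inner radius < outer radius")
  if (is.null(r_mm)) r_mm <- seq(a, b, length.out = 50)
  A <- (p_in_kpa * a^2 - p_out_kpa * b^2) / (b^2 - a^2)
  B <- (p_in_kpa - p_out_kpa) * a^2 * b^2 / (b^2 - a^2)
  list(r_mm = r_mm,
       sigma_theta_kpa = A + B / r_mm^2,
       sigma_r_kpa = A - B / r_mm^2)
}

mr_invariant_derivs <- function(material, i1, i2) {
  list(w1 = material$c10 + 2 * material$c20 * (i1 - 3) +
         material$c11 * (i2 - 3),
       w2 = material$c01 + material$c11 * (i1 - 3) +
         2 * material$c02 * (i2 - 3))
}

#' Mooney-Rivlin strain energy at uniaxial stretch
#'
#' @param material a `material_model` of kind `"mooney_rivlin_5"`.
#' @param stretch uniaxial stretch ratio (> 0); incompressibility gives
#'   lateral stretches `1/sqrt(lambda)`.
#' @return Strain energy density (kPa).
#' @export
mooney_rivlin_energy <- function(material, stretch) {
  i1 <- stretch^2 + 2 / stretch
  i2 <- 2 * stretch + 1 / stretch^2
  material$c10 * (i1 - 3) + material$c01 * (i2 - 3) +
    material$c20 * (i1 - 3)^2 + material$c11 * (i1 - 3) * (i2 - 3) +
    material$c02 * (i2 - 3)^2
}

#' Uniaxial Cauchy stress of the incompressible Mooney-Rivlin solid
#'
#' `sigma = 2 (lambda^2 - 1/lambda) (W1 + W2 / lambda)` with `W1`, `W2` the
#' strain-energy derivatives with respect to the first and second
#' invariants. The small-strain slope is `6 (c10 + c01)` kPa (the effective
#' Young modulus of the incompressible solid).
#'
#' @param material a `material_model` of kind `"mooney_rivlin_5"`.
#' @param stretch uniaxial stretch ratio (> 0); vectorized.
#' @return Cauchy stress in kPa (0 at `stretch = 1`).
#' @export
mooney_rivlin_uniaxial <- function(material, stretch) {
  if (material$kind != "mooney_rivlin_5") {
    stop("material must be a 5-parameter Mooney-Rivlin model")
  }
  if (any(stretch <= 0)) stop("stretch must be positive")
  i1 <- stretch^2 + 2 / stretch
  i2 <- 2 * stretch + 1 / stretch^2
  d <- mr_invariant_derivs(material, i1, i2)
  2 * (stretch^2 - 1 / stretch) * (d$w1 + d$w2 / stretch)
}

#' Default stent caging factor
#'
#' Fraction of the circumferential (ring) tension still carried by the wall
#' between sparse stent rings. The lattice is far stiffer than tissue, so
#' within a strut's axial influence zone the wall is almost fully unloaded;
#' between rings the wall carries its load. The default takes the influence
#' zone as an empirical multiple of the strut thickness, giving
#' `1 - influence * t_strut / spacing` (0.46 for a 90 um strut at 1 mm
#' spacing with the default multiple of 6).
#'
#' @param stent a [stent_spec()].
#' @param influence_multiple axial influence zone per strut, in strut
#'   thicknesses (default 6).
#' @return Caging factor in (0, 1).
#' @export
stent_caging_factor <- function(stent, influence_multiple = 6) {
  f <- 1 - influence_multiple * (stent$strut_thickness_um * 1e-3) /
    stent$inter_strut_distance_mm
  min(max(f, 0.05), 0.95)
}

#' Superficial and deep plaque structural stress estimate
#'
#' Layered-cylinder surrogate for the wall stress field under luminal
#' pressure. Over the lipid pool the soft lipid layer carries negligible
#' load, so the superficial (cap) stress follows the thin-membrane Laplace
#' limit `sigma = p R / h_cap`; away from the pool the wall behaves as a
#' thick-walled cylinder (Lame, lumen to EEM). The luminal pressure at each
#' station combines the static outlet pressure and the local flow pressure
#' (the station value of the flow solution's pressure profile). In the
#' stented variant the lattice carries part of the ring tension: wall
#' stresses are scaled by a caging factor below 1, and the deep layer near
#' strut rings is reported with a contact stress concentration factor.
#'
#' @param geometry an `idealized_geometry` from [build_wall()].
#' @param flow a `flow_solution` for the same geometry (built with
#'   [quasi1d_flow()] if `NULL`).
#' @param material a [material_model()] (recorded in the result).
#' @param stented logical; defaults to `TRUE` when the geometry carries a
#'   stent lattice.
#' @param caging_factor wall-tension scaling for the stented variant;
#'   default [stent_caging_factor()] of the geometry's stent.
#' @param strut_concentration contact stress concentration factor applied
#'   to the deep-layer stress at strut rings (default 2.5).
#' @param thresholds a [threshold_config()] (uses `superficial_depth_um`).
#' @return An object of class `stress_solution`: `z` (mm),
#'   `superficial_kpa(z)`, `deep_kpa(z)`, `superficial_pss_kpa` and its
#'   station `superficial_pss_z_mm`, `max_pss_kpa`, `max_pss_location`
#'   (`"cap_crown"` or `"strut_vicinity"`), through-wall Lame profiles at
#'   the thinnest-cap station, the boundary-condition record, the material
#'   and the caging factor used.
#' @export
cap_stress_estimate <- function(geometry, flow = NULL,
                                material = material_model(),
                                stented = !is.null(geometry$strut_z),
                                caging_factor = NULL,
                                strut_concentration = 2.5,
                                thresholds = threshold_config()) {
  if (is.null(geometry$cap_thickness_mm)) stop("geometry has no cap layer")
  if (is.null(flow)) flow <- quasi1d_flow(geometry)
  z <- geometry$z
  p_kpa <- stats::approx(flow$z, flow$p_mmhg, xout = z, rule = 2)$y *
    MMHG_PA / 1000
  r <- geometry$lumen_r
  h <- geometry$cap_thickness_mm
  pool <- geometry$lipid_pool$z_range
  in_pool <- z >= pool[1] & z <= pool[2]

  sup <- numeric(length(z))
  deep <- numeric(length(z))
  for (i in seq_along(z)) {
    if (in_pool[i]) {
      sup[i] <- p_kpa[i] * r[i] / h[i]             # Laplace, lipid unloaded
      deep[i] <- 0                                 # lipid carries ~no load
    } else {
      lam <- lame_cylinder(r[i], geometry$eem_r[i], p_kpa[i], 0,
                           r_mm = c(r[i], geometry$eem_r[i]))
      sup[i] <- lam$sigma_theta_kpa[1]
      deep[i] <- lam$sigma_theta_kpa[2]
    }
  }

  cage <- 1
  strut_kpa <- NA_real_
  if (stented) {
    if (is.null(geometry$spec$stent)) stop("stented estimate needs a stent spec")
    if (is.null(caging_factor)) {
      caging_factor <- stent_caging_factor(geometry$spec$stent)
    }
    cage <- caging_factor
    sup <- sup * cage
    deep <- deep * cage
    # contact concentration at strut rings acts on the uncaged deep stress
    ring_deep <- vapply(geometry$strut_z, function(zs) {
      i <- which.min(abs(z - zs))
      lam <- lame_cylinder(r[i], geometry$eem_r[i], p_kpa[i], 0,
                           r_mm = geometry$eem_r[i])
      lam$sigma_theta_kpa[1]
    }, numeric(1))
    strut_kpa <- strut_concentration * max(ring_deep)
  }

  i_sup <- which.max(sup)
  sup_max <- sup[i_sup]
  if (stented && is.finite(strut_kpa) && strut_kpa > sup_max) {
    max_pss <- strut_kpa
    loc <- "strut_vicinity"
  } else {
    max_pss <- sup_max
    loc <- "cap_crown"
  }
  i_cap <- which.min(h)
  lam_cap <- lame_cylinder(r[i_cap], geometry$eem_r[i_cap], p_kpa[i_cap], 0)

  sol <- list(z = z, superficial_kpa = sup, deep_kpa = deep,
              superficial_pss_kpa = sup_max,
              superficial_pss_z_mm = z[i_sup],
              strut_vicinity_kpa = strut_kpa,
              max_pss_kpa = max_pss, max_pss_location = loc,
              wall_profile_at_min_cap = lam_cap,
              boundary_conditions = list(ends = "fixed",
                                         luminal_pressure_kpa = p_kpa),
              material = material, stented = stented,
              caging_factor = cage)
  class(sol) <- "stress_solution"
  sol
}

#' @export
print.stress_solution <- function(x, ...) {
  cat(sprintf("Stress solution (%s): superficial PSS %.1f kPa at z=%.1f mm\n",
              if (x$stented) "stented" else "native",
              x$superficial_pss_kpa, x$superficial_pss_z_mm))
  cat(sprintf("  max PSS %.1f kPa (%s)%s\n", x$max_pss_kpa,
              x$max_pss_location,
              if (x$stented) sprintf(", caging factor %.2f", x$caging_factor)
              else ""))
  invisible(x)
}
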