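## Synthetic lesion cohorts with the statistical structure of the two
## ruptured-plaque groups: per-lesion metrics drawn from truncated normals
## (moment-matched so realized mean/SD equal the printed ones) and Bernoulli
## feature incidences, plus a pullback synthesizer that inverts the
## morphometry pipeline so every stage is testable without patient data.

group_reference_params <- function(group) {
  if (group == "PR-NV") {
    cont <- data.frame(
      variable = c("lesion_length_mm", "mla_mm2", "prox_ref_area_mm2",
                   "dist_ref_area_mm2", "min_fct_um", "mean_fct_um",
                   "mean_lipid_arc_deg", "lipid_length_mm",
                   "mean_calcific_arc_deg", "rupture_length_mm",
                   "rupture_depth_mm", "rupture_arc_deg",
                   "thrombus_score_pct"),
      mean = c(16.3, 2.93, 9.21, 7.78, 49, 186, 150.5, 6.1, 62.8,
               2.4, 0.9, 58.7, 21.8),
      sd = c(6.0, 2.03, 4.11, 3.87, 22, 65, 49.4, 5.3, 31.0,
             2.2, 0.5, 35.1, 18.3),
      lower = c(2, 0, 0, 0, 0, 0, 46, 0.4, 5, 0.4, 0.05, 5, 0),
      upper = c(Inf, Inf, Inf, Inf, Inf, Inf, 360, Inf, 360, Inf, Inf,
                360, 100))
    bin <- data.frame(
      variable = c("calcific_present", "macrophages_spotted",
                   "macrophages_lined", "microchannel_present",
                   "crystal_present", "thrombus_present"),
      incidence = c(31 / 56, 50 / 56, 48 / 56, 0.414, 0.345, 43 / 56))
    site_probs <- c(upstream = 26, throat = 30, downstream = 8) / 64
    circ_probs <- c(center = 33, shoulder = 31) / 64
    extra_site_p <- 0.1
    n_default <- 56L
  } else {
    cont <- data.frame(
      variable = c("lesion_length_mm", "mla_mm2", "prox_ref_area_mm2",
                   "dist_ref_area_mm2", "min_fct_um", "mean_fct_um",
                   "mean_lipid_arc_deg", "lipid_length_mm",
                   "mean_calcific_arc_deg", "rupture_length_mm",
                   "rupture_depth_mm", "rupture_arc_deg",
                   "thrombus_score_pct"),
      mean = c(14.8, 2.00, 5.80, 4.96, 60, 232, 167.3, 7.8, 79.2,
               1.9, 0.6, 64.7, 21.5),
      sd = c(11.1, 1.26, 2.99, 2.11, 38, 80, 34.0, 8.6, 14.7,
             2.0, 0.3, 31.5, 17.3),
      lower = c(2, 0, 0, 0, 0, 0, 46, 0.4, 5, 0.4, 0.05, 5, 0),
      upper = c(Inf, Inf, Inf, Inf, Inf, Inf, 360, Inf, 360, Inf, Inf,
                360, 100))
    bin <- data.frame(
      variable = c("calcific_present", "macrophages_spotted",
                   "macrophages_lined", "microchannel_present",
                   "crystal_present", "thrombus_present"),
      incidence = c(5 / 24, 20 / 24, 18 / 24, 0.125, 0.33, 21 / 24))
    site_probs <- c(upstream = 5, throat = 20, downstream = 4) / 29
    circ_probs <- c(center = 12, shoulder = 17) / 29
    extra_site_p <- 0.2
    n_default <- 24L
  }
  list(continuous = cont, binary = bin, site_probs = site_probs,
       circ_probs = circ_probs, extra_site_p = extra_site_p,
       n_default = n_default)
}

#' Cohort generation parameters
#'
#' Per-variable distribution specifications for one lesion group:
#' continuous metrics as (mean, SD, truncation bounds) and binary features
#' as incidences, with the cohort size and seed. Defaults are the group
#' summaries of the ruptured-plaque study cohorts (native vessel n = 56,
#' neoatherosclerosis n = 24).
#'
#' @param group `"PR-NV"` or `"PR-NA"`.
#' @param n cohort size; defaults to the group's study size (56 or 24).
#' @param seed integer RNG seed.
#' @return An object of class `group_params` with elements `group`, `n`,
#'   `seed`, `continuous` (data.frame: variable, mean, sd, lower, upper),
#'   `binary` (variable, incidence), `site_probs` (rupture-site
#'   longitudinal class probabilities), `circ_probs` (center/shoulder
#'   probabilities) and `extra_site_p` (probability of a second rupture
#'   site).
#' @export
group_params <- function(group = c("PR-NV", "PR-NA"), n = NULL, seed = 7L) {
  group <- match.arg(group)
  ref <- group_reference_params(group)
  gp <- list(group = group,
             n = if (is.null(n)) ref$n_default else as.integer(n),
             seed = as.integer(seed),
             continuous = ref$continuous, binary = ref$binary,
             site_probs = ref$site_probs, circ_probs = ref$circ_probs,
             extra_site_p = ref$extra_site_p)
  if (gp$n < 1) stop("cohort size must be >= 1")
  if (any(gp$continuous$sd < 0) ||
      any(gp$binary$incidence < 0 | gp$binary$incidence > 1)) {
    stop("invalid distribution parameters")
  }
  class(gp) <- "group_params"
  gp
}

# Underlying normal parameters whose truncated-[lower,upper] moments match
# the target mean/SD. Returns the input when truncation mass is negligible.
trunc_norm_match <- function(mean, sd, lower, upper) {
  if (sd == 0) return(list(mu = mean, sigma = 0))
  mass_out <- stats::pnorm(lower, mean, sd) +
    stats::pnorm(upper, mean, sd, lower.tail = FALSE)
  if (mass_out < 1e-8) return(list(mu = mean, sigma = sd))
  moments <- function(mu, sigma) {
    a <- (lower - mu) / sigma
    b <- (upper - mu) / sigma
    zden <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a)
    db <- stats::dnorm(b)
    m <- mu + sigma * (da - db) / zden
    adA <- if (is.finite(a)) a * da else 0
    bdB <- if (is.finite(b)) b * db else 0
    v <- sigma^2 * (1 + (adA - bdB) / zden - ((da - db) / zden)^2)
    if (!is.finite(v) || v <= 0) return(c(NA_real_, NA_real_))
    c(m, sqrt(v))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    if (any(!is.finite(mm))) return(1e10)
    ((mm[1] - mean) / sd)^2 + ((mm[2] - sd) / sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtrunc_norm <- function(n, mu, sigma, lower, upper) {
  if (sigma == 0) return(rep(mu, n))
  lo <- stats::pnorm(lower, mu, sigma)
  hi <- stats::pnorm(upper, mu, sigma)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mu, sigma)
}

#' Simulate a lesion-metric cohort
#'
#' Draws `n` per-lesion metric rows: continuous metrics from truncated
#' normals whose realized moments are re-targeted to the printed mean/SD,
#' binary features from Bernoulli incidences, rupture-site classes from the
#' group's location distributions. Physical consistency is enforced by
#' redrawing the counterpart of each constraint — reference areas are
#' redrawn upward until they exceed the MLA, and the minimum cap is redrawn
#' until it sits at or below the mean cap — so the clinically primary
#' marginals (MLA, mean cap thickness) keep the printed moments exactly;
#' lipid and rupture lengths are redrawn to fit inside the lesion. Fully
#' reproducible under the params seed.
#'
#' @param params a [group_params()].
#' @return A data.frame with one row per lesion (columns: `lesion_id`,
#'   `group`, the 13 continuous metrics, the 6 binary features,
#'   `n_rupture_sites`, `rupture_long_class`, `rupture_circ_class`), with
#'   the params attached as attribute `"params"`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "group_params"))
  set.seed(params$seed)
  n <- params$n
  draw <- function(var, n_draw = n) {
    row <- params$continuous[params$continuous$variable == var, ]
    mm <- trunc_norm_match(row$mean, row$sd, row$lower, row$upper)
    rtrunc_norm(n_draw, mm$mu, mm$sigma, row$lower, row$upper)
  }
  out <- data.frame(lesion_id = sprintf("%s-%03d", params$group, seq_len(n)),
                    group = params$group, stringsAsFactors = FALSE)
  for (v in params$continuous$variable) out[[v]] <- draw(v)

  redraw <- function(values, var, bad_fn, clamp_fn) {
    for (k in 1:50) {
      bad <- bad_fn(values)
      if (!any(bad)) return(values)
      values[bad] <- draw(var, sum(bad))
    }
    clamp_fn(values)
  }
  # constraints are resolved by redrawing the counterpart variable, so the
  # clinically primary marginals (MLA, mean cap thickness) keep the printed
  # moments exactly
  out$prox_ref_area_mm2 <- redraw(out$prox_ref_area_mm2, "prox_ref_area_mm2",
    function(v) v < out$mla_mm2 / 0.95,
    function(v) pmax(v, out$mla_mm2 / 0.95))
  out$dist_ref_area_mm2 <- redraw(out$dist_ref_area_mm2, "dist_ref_area_mm2",
    function(v) v < out$mla_mm2 / 0.95,
    function(v) pmax(v, out$mla_mm2 / 0.95))
  out$min_fct_um <- redraw(out$min_fct_um, "min_fct_um",
    function(v) v > out$mean_fct_um,
    function(v) pmin(v, out$mean_fct_um))
  out$lipid_length_mm <- redraw(out$lipid_length_mm, "lipid_length_mm",
    function(v) v > out$lesion_length_mm - 0.8,
    function(v) pmin(v, out$lesion_length_mm - 0.8))
  out$rupture_length_mm <- redraw(out$rupture_length_mm, "rupture_length_mm",
    function(v) v > out$lesion_length_mm,
    function(v) pmin(v, out$lesion_length_mm))

  for (k in seq_len(nrow(params$binary))) {
    out[[params$binary$variable[k]]] <-
      stats::runif(n) < params$binary$incidence[k]
  }
  out$mean_calcific_arc_deg[!out$calcific_present] <- NA_real_
  out$thrombus_score_pct[!out$thrombus_present] <- 0

  out$n_rupture_sites <- 1L +
    stats::rbinom(n, 1L, params$extra_site_p)
  out$rupture_long_class <- sample(names(params$site_probs), n,
                                   replace = TRUE, prob = params$site_probs)
  out$rupture_circ_class <- sample(c("center", "shoulder"), n,
                                   replace = TRUE, prob = params$circ_probs)
  attr(out, "params") <- params
  out
}

# lumen radius of the cosine-taper stenosis at arbitrary z (mm)
cosine_radius <- function(z, L, zm, rp, rm, rd) {
  r <- numeric(length(z))
  up <- z <= zm
  r[up] <- if (zm > 0) {
    rm + (rp - rm) * (1 + cos(pi * pmin(z[up], zm) / zm)) / 2
  } else rm
  if (any(!up)) {
    r[!up] <- rm + (rd - rm) * (1 - cos(pi * (z[!up] - zm) / (L - zm))) / 2
  }
  r
}

#' Synthesize an annotated pullback from one cohort row
#'
#' Inverts the morphometry pipeline: builds a cosine-taper lumen through
#' the row's reference areas and MLA, samples frames at the OCT interval,
#' paints lipid / calcific / macrophage arcs, a cap-thickness profile whose
#' pooled minimum and mean equal the row's cap statistics exactly, a
#' rupture cavity (approximated pre-rupture border plus a bulged cavity
#' border of the row's depth), thrombus quadrants matching the row's
#' thrombus score, and microchannel / crystal flags — so that the lesion
#' and morphometry pipelines recover the row within discretization
#' tolerance (lengths to half a frame, arcs exactly, cap statistics
#' exactly).
#'
#' @param row one row of a [simulate_cohort()] table (data.frame or list).
#' @param seed integer seed for placement randomness.
#' @param spacing_mm frame spacing (default 0.4).
#' @param margin_frames non-lesion frames appended on each side (default 6).
#' @param n_cap_samples angular cap samples per lipid frame (default 12).
#' @param n_angular angular lumen samples on rupture frames (default 72).
#' @return A validated `oct_pullback`.
#' @export
synthesize_pullback <- function(row, seed = 1L, spacing_mm = 0.4,
                                margin_frames = 6L, n_cap_samples = 12L,
                                n_angular = 72L) {
  set.seed(seed)
  row <- as.list(row)
  n_les <- max(3L, round(row$lesion_length_mm / spacing_mm) + 1L)
  L <- (n_les - 1L) * spacing_mm
  i_mla <- round(0.5 * (n_les - 1L))
  z_mla <- i_mla * spacing_mm
  rp <- equivalent_radius(row$prox_ref_area_mm2)
  rd <- equivalent_radius(row$dist_ref_area_mm2)
  rm <- equivalent_radius(row$mla_mm2)

  n_tot <- n_les + 2L * margin_frames
  les_idx <- margin_frames + seq_len(n_les) - 1L      # 0-based frame indices
  z_all <- (seq_len(n_tot) - 1L) * spacing_mm
  z_les0 <- margin_frames * spacing_mm                # z of lesion start
  r_all <- numeric(n_tot)
  in_les <- seq_len(n_tot) %in% (les_idx + 1L)
  r_all[in_les] <- cosine_radius(z_all[in_les] - z_les0, L, z_mla, rp, rm, rd)
  r_all[!in_les & z_all < z_les0] <- rp
  r_all[!in_les & z_all > z_les0] <- rd
  area_all <- pi * r_all^2

  pos <- function(i_lesion) les_idx[i_lesion + 1L] + 1L  # lesion idx -> 1-based

  # lipid pool: contiguous frames centered on the MLA
  n_lip <- min(max(1L, round(row$lipid_length_mm / spacing_mm)), n_les)
  lip_start <- min(max(0L, i_mla - (n_lip - 1L) %/% 2L), n_les - n_lip)
  lip_frames <- lip_start + seq_len(n_lip) - 1L
  lipid_arc <- min(row$mean_lipid_arc_deg, 359.9)
  crown_target <- z_mla - row$lipid_length_mm / 4
  crown_i <- lip_frames[which.min(abs(lip_frames * spacing_mm - crown_target))]

  # pooled cap samples: one sample at the minimum, the rest at v so the
  # pooled mean is exact
  n_samp <- n_cap_samples * n_lip
  v <- if (n_samp > 1) {
    (row$mean_fct_um * n_samp - row$min_fct_um) / (n_samp - 1)
  } else row$min_fct_um

  calc_frames <- integer(0)
  if (isTRUE(row$calcific_present)) {
    n_cal <- max(1L, round(0.3 * n_lip))
    calc_frames <- seq(0L, length.out = n_cal)
    calc_frames <- calc_frames[calc_frames < n_les]
  }
  spot_frames <- if (isTRUE(row$macrophages_spotted)) {
    unique(round(seq(1L, max(1L, n_les %/% 2L),
                     length.out = max(1L, round(0.2 * n_les)))))
  } else integer(0)
  lined_frames <- if (isTRUE(row$macrophages_lined)) {
    unique(round(seq(max(0L, n_les %/% 2L), n_les - 1L,
                     length.out = max(1L, round(0.25 * n_les)))))
  } else integer(0)
  micro_frames <- if (isTRUE(row$microchannel_present)) {
    st <- max(0L, min(i_mla + 2L, n_les - 3L))
    st + 0:2
  } else integer(0)
  crystal_frames <- if (isTRUE(row$crystal_present)) {
    unique(c(max(0L, i_mla - 2L), min(n_les - 1L, i_mla + 3L)))
  } else integer(0)

  # rupture sites
  n_sites <- max(1L, as.integer(row$n_rupture_sites))
  n_rup_total <- min(max(round(row$rupture_length_mm / spacing_mm), n_sites),
                     n_les)
  n_rup1 <- n_rup_total - (n_sites - 1L)
  if (n_sites > 1L) n_rup1 <- min(n_rup1, n_les - 3L)  # keep room for site 2
  peak_target <- switch(as.character(row$rupture_long_class %||% "throat"),
    upstream = z_mla - 3.5,
    downstream = z_mla + 3.5,
    z_mla - min(1, z_mla))                           # throat
  peak_i <- min(max(round(peak_target / spacing_mm), 0L), n_les - 1L)
  s1 <- min(max(0L, peak_i - (n_rup1 - 1L) %/% 2L), n_les - n_rup1)
  site1 <- s1 + seq_len(n_rup1) - 1L
  site2 <- integer(0)
  if (n_sites > 1L) {
    cand <- setdiff(0:(n_les - 1L),
                    (min(site1) - 1L):(max(site1) + 1L))
    if (length(cand)) site2 <- cand[which.max(abs(cand - peak_i))]
  }
  rup_frames <- c(site1, site2)
  rup_arc <- min(row$rupture_arc_deg, 359.9)
  rup_center <- if (identical(row$rupture_circ_class, "shoulder")) {
    270 - lipid_arc / 2                              # at a lipid-pool edge
  } else 270

  # thrombus quadrants: exact inversion of the score
  q_total <- if (isTRUE(row$thrombus_present)) {
    round(row$thrombus_score_pct / 100 * 4 * n_les)
  } else 0L
  thrombus_q <- matrix(FALSE, n_les, 4)
  if (q_total > 0) {
    order_frames <- order(abs(seq_len(n_les) - 1L - peak_i))
    left <- q_total
    for (f in order_frames) {
      if (left <= 0) break
      k <- min(4L, left)
      thrombus_q[f, seq_len(k)] <- TRUE
      left <- left - k
    }
  }

  frames <- vector("list", n_tot)
  for (j in seq_len(n_tot)) {
    fi <- j - 1L
    i_les <- fi - margin_frames                      # lesion-local index
    lesion_frame <- i_les >= 0L && i_les < n_les
    arcs <- list()
    cap <- NULL
    rupture <- FALSE
    approx_r <- NULL
    lumen_prof <- NULL
    micro <- NULL
    crystal <- FALSE
    tq <- rep(FALSE, 4)
    if (lesion_frame) {
      if (i_les %in% lip_frames) {
        arcs <- c(arcs, list(arc_span(270 - lipid_arc / 2,
                                      270 + lipid_arc / 2, "lipid")))
        cap <- rep(v, n_cap_samples)
        if (i_les == crown_i) cap[1] <- row$min_fct_um
      }
      if (i_les %in% calc_frames) {
        ca <- min(row$mean_calcific_arc_deg, 359.9)
        arcs <- c(arcs, list(arc_span(90 - ca / 2, 90 + ca / 2, "calcific")))
      }
      if (i_les %in% spot_frames) {
        arcs <- c(arcs, list(arc_span(30, 55, "macrophage_spotted")))
      }
      if (i_les %in% lined_frames) {
        arcs <- c(arcs, list(arc_span(120, 150, "macrophage_lined")))
      }
      if (i_les %in% rup_frames) {
        rupture <- TRUE
        arcs <- c(arcs, list(arc_span(rup_center - rup_arc / 2,
                                      rup_center + rup_arc / 2, "rupture")))
        base_r <- r_all[j]
        approx_r <- rep(base_r, n_angular)
        depth <- if (i_les == site1[which.max(site1 == peak_i)] ||
                     i_les == peak_i) {
          row$rupture_depth_mm
        } else 0.6 * row$rupture_depth_mm
        th <- (seq_len(n_angular) - 1L) * 360 / n_angular
        bulge <- angle_distance(th, rup_center %% 360) <= rup_arc / 2
        lumen_prof <- base_r + ifelse(bulge, depth, 0)
      }
      if (i_les %in% micro_frames) micro <- 250
      crystal <- i_les %in% crystal_frames
      tq <- thrombus_q[i_les + 1L, ]
    }
    is_na_group <- identical(row$group, "PR-NA")
    frames[[j]] <- frame_annotation(
      frame_index = fi, z_mm = z_all[j],
      lumen_radius = lumen_prof,
      lumen_area_mm2 = area_all[j],
      eem_area_mm2 = if (is_na_group) NULL else
        area_all[j] / (1 - if (lesion_frame) 0.55 else 0.15),
      stent_area_mm2 = if (is_na_group) max(area_all) * 1.15 else NULL,
      neointima_thickness_mm = if (is_na_group) {
        if (lesion_frame) 0.7 else 0.2
      } else NULL,
      arcs = arcs, cap_thickness_um = cap,
      rupture_present = rupture,
      approximated_lumen_radius = approx_r,
      thrombus_quadrants = tq,
      microchannel_diameter_um = micro,
      cholesterol_crystal = crystal)
  }
  pullback(frames, frame_spacing_mm = spacing_mm,
           group = if (identical(row$group, "PR-NA")) "PR-NA" else "PR-NV",
           vessel = sample(PULLBACK_VESSELS, 1),
           id = row$lesion_id %||% "synthetic")
}

#' Synthesize a whole cohort of pullbacks
#'
#' @param cohort a [simulate_cohort()] table.
#' @param seed base seed; lesion `k` uses `seed + k`.
#' @param ... passed to [synthesize_pullback()].
#' @return List of `oct_pullback` objects.
#' @export
synthesize_cohort_pullbacks <- function(cohort, seed = 1L, ...) {
  lapply(seq_len(nrow(cohort)), function(k) {
    synthesize_pullback(cohort[k, ], seed = seed + k, ...)
  })
}
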