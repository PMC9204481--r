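test_that("tissue index follows the unrolled-surface formula", {
  expect_equal(tissue_index(360, 10, 10), 100)
  expect_equal(tissue_index(150.5, 6.1, 16.3), 15.645, tolerance = 1e-3)
  expect_equal(tissue_index(0, 3, 10), 0)
  expect_error(tissue_index(100, 12, 10), "lesion length")
  expect_error(tissue_index(400, 5, 10), "arc")
})

test_that("tissue index is bilinear and bounded by 100", {
  set.seed(4)
  for (k in 1:25) {
    arc <- runif(1, 0, 360)
    len <- runif(1, 0, 10)
    L <- runif(1, 10, 30)
    a <- runif(1, 0.1, min(2, 360 / max(arc, 1e-9)))
    expect_equal(tissue_index(arc * a, len, L), a * tissue_index(arc, len, L),
                 tolerance = 1e-12)
    b <- runif(1, 0.1, 1)
    expect_equal(tissue_index(arc, len * b, L), b * tissue_index(arc, len, L),
                 tolerance = 1e-12)
    expect_lte(tissue_index(arc, len, L), 100 + 1e-12)
  }
})

lipid_frame <- function(idx, arc, cap) {
  frame_annotation(idx, idx * 0.4, lumen_area_mm2 = 4,
                   arcs = if (arc > 0) list(arc_span(0, arc, "lipid")) else
                     list(),
                   cap_thickness_um = cap)
}

test_that("phenotype rule: quadrant of lipid, 65 um cap boundary inclusive", {
  expect_equal(classify_phenotype(list(lipid_frame(0, 120, c(50, 90)))),
               "TCFA")
  expect_equal(classify_phenotype(list(lipid_frame(0, 120, c(66, 90)))),
               "ThCFA")
  expect_equal(classify_phenotype(list(lipid_frame(0, 120, c(65, 90)))),
               "TCFA")                       # 65 um is inclusive
  expect_equal(classify_phenotype(list(lipid_frame(0, 80, c(50)))),
               "non_fibroatheroma")
  expect_error(classify_phenotype(list(lipid_frame(0, 120, NULL))),
               "no cap")
})

test_that("phenotype is monotone in cap thinning", {
  set.seed(9)
  for (k in 1:20) {
    caps <- runif(3, 40, 200)
    ph1 <- classify_phenotype(list(lipid_frame(0, 130, caps)))
    ph2 <- classify_phenotype(list(lipid_frame(0, 130, caps * 0.5)))
    expect_false(ph1 == "TCFA" && ph2 == "ThCFA")
  }
})

test_that("cap statistics pool angular samples across frames", {
  expect_equal(cap_statistics(list(lipid_frame(0, 100, c(100, 200, 300)))),
               list(min_fct_um = 100, mean_fct_um = 200))
  two <- list(lipid_frame(0, 100, 100), lipid_frame(1, 100, 300))
  expect_equal(cap_statistics(two), list(min_fct_um = 100, mean_fct_um = 200))
  none <- cap_statistics(list(lipid_frame(0, 0, NULL)))
  expect_true(is.na(none$min_fct_um) && is.na(none$mean_fct_um))
})

micro_frames <- function(cands, diam = 250, n = 10) {
  lapply(seq_len(n) - 1L, function(i) {
    frame_annotation(i, i * 0.4, lumen_area_mm2 = 4,
                     microchannel_diameter_um = if ((i + 1) %in% cands) diam
                     else NULL)
  })
}

test_that("microchannels need 3 consecutive frames at <= 300 um", {
  expect_true(detect_microchannel_runs(micro_frames(4:6)))
  expect_false(detect_microchannel_runs(micro_frames(c(4, 6, 8))))
  expect_false(detect_microchannel_runs(micro_frames(4:6, diam = 350)))
  expect_false(detect_microchannel_runs(micro_frames(4:5)))
})

test_that("thrombus score counts flagged quadrants over analyzed frames", {
  mk <- function(quads_per_frame) {
    lapply(seq_along(quads_per_frame) - 1L, function(i) {
      q <- rep(FALSE, 4)
      if (quads_per_frame[i + 1] > 0) q[seq_len(quads_per_frame[i + 1])] <- TRUE
      frame_annotation(i, i * 0.4, lumen_area_mm2 = 4, thrombus_quadrants = q)
    })
  }
  expect_equal(thrombus_score(mk(rep(0, 10))), 0)
  expect_equal(thrombus_score(mk(rep(4, 10))), 100)
  expect_equal(thrombus_score(mk(c(4, 4, rep(0, 8)))), 20)
  expect_error(thrombus_score(list()), "no analyzed frames")
})

test_that("thrombus score equals brute-force quadrant enumeration", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(3:15, 1)
    flags <- matrix(runif(4 * n) < 0.3, n, 4)
    frames <- lapply(seq_len(n) - 1L, function(i) {
      frame_annotation(i, i * 0.4, lumen_area_mm2 = 4,
                       thrombus_quadrants = flags[i + 1, ])
    })
    brute <- 0
    for (i in seq_len(n)) for (j in 1:4) brute <- brute + flags[i, j]
    expect_equal(thrombus_score(frames), 100 * brute / (4 * n))
  }
})

test_that("rupture metrics: length, profile depth, mean arc, extent index", {
  mk_rupture_frame <- function(i, arc, base_r = 1, depth = 0.5) {
    th <- (0:71) * 5
    prof <- rep(base_r, 72)
    prof[plaqrupt:::angle_distance(th, 20) <= arc / 2] <- base_r + depth
    frame_annotation(i, i * 0.4, lumen_area_mm2 = pi * base_r^2,
                     lumen_radius = prof,
                     arcs = list(arc_span(20 - arc / 2, 20 + arc / 2,
                                          "rupture")),
                     rupture_present = TRUE,
                     approximated_lumen_radius = rep(base_r, 72))
  }
  plainf <- function(i) frame_annotation(i, i * 0.4, lumen_area_mm2 = pi)
  frames <- c(lapply(0:1, plainf), list(mk_rupture_frame(2, 40)),
              lapply(3:9, plainf))
  m <- rupture_metrics(frames, 0.4, 4)
  expect_equal(m$n_rupture_sites, 1L)
  expect_equal(m$rupture_length_mm, 0.4)
  expect_equal(m$rupture_depth_mm, 0.5)   # 1.5 vs 1.0 mm over the arc
  expect_equal(m$rupture_arc_deg, 40)

  none <- rupture_metrics(lapply(0:4, plainf), 0.4, 2)
  expect_equal(none$n_rupture_sites, 0L)
  expect_equal(none$rupture_length_mm, 0)
  expect_true(is.na(none$rupture_depth_mm))

  # extent index: arc 60 deg, rupture length 2.4 mm, lesion 16.3 mm
  expect_equal(tissue_index(60, 2.4, 16.3), 2.454, tolerance = 1e-3)

  # cavity strictly inside the approximated lumen: depth 0 with a warning
  bad <- list(frame_annotation(
    0, 0, lumen_area_mm2 = pi, lumen_radius = rep(0.9, 72),
    arcs = list(arc_span(0, 40, "rupture")), rupture_present = TRUE,
    approximated_lumen_radius = rep(1, 72)))
  expect_warning(mbad <- rupture_metrics(bad, 0.4, 2), "inside")
  expect_equal(mbad$rupture_depth_mm, 0)
})

test_that("frame prevalence counts lesion frames with table rounding", {
  expect_equal(prevalence_pct(391, 2307), 16.9)
  expect_equal(prevalence_pct(344, 903), 38.1)
  expect_equal(prevalence_pct(0, 50), 0)
  expect_error(prevalence_pct(5, 0), "positive")

  co <- simulate_cohort(group_params("PR-NV", 4, seed = 13))
  cohort <- synthesize_cohort_pullbacks(co, seed = 50)
  pr <- frame_prevalence(cohort, "rupture")
  n_les <- sum(sapply(co$lesion_length_mm, function(l) {
    max(3, round(l / 0.4) + 1)
  }))
  expect_equal(pr$total, n_les)
  expect_gt(pr$count, 0)
  expect_equal(pr$percent, prevalence_pct(pr$count, pr$total))
  expect_error(frame_prevalence(cohort, "nonsense"), "unknown feature")

  # lipid-rich rows make every TCFA/ThCFA frame carry more than a quadrant
  tc <- frame_prevalence(cohort, "tcfa")
  th <- frame_prevalence(cohort, "thcfa")
  expect_lte(tc$count + th$count, pr$total)
})

test_that("morphometry recovers the generator row within discretization", {
  set.seed(2)
  for (g in c("PR-NV", "PR-NA")) {
    co <- simulate_cohort(group_params(g, 15, seed = 17))
    for (k in seq_len(nrow(co))) {
      row <- co[k, ]
      pb <- synthesize_pullback(row, seed = 1000 + k)
      m <- morphometry(pb)
      n_les <- max(3, round(row$lesion_length_mm / 0.4) + 1)
      L_snap <- (n_les - 1) * 0.4
      lbl <- sprintf("%s row %d", g, k)
      expect_equal(m$min_fct_um, row$min_fct_um, tolerance = 1e-9, label = lbl)
      expect_equal(m$mean_fct_um, row$mean_fct_um, tolerance = 1e-9,
                   label = lbl)
      expect_equal(m$mean_lipid_arc_deg, min(row$mean_lipid_arc_deg, 359.9),
                   tolerance = 1e-9, label = lbl)
      expect_lte(abs(m$lipid_length_mm - row$lipid_length_mm), 0.2 + 1e-9)
      # index matches the formula on the snapped lengths exactly
      expect_equal(m$lipid_index,
                   tissue_index(m$mean_lipid_arc_deg,
                                min(m$lipid_length_mm, L_snap), L_snap),
                   tolerance = 1e-9, label = lbl)
      expect_equal(m$calcific_present, row$calcific_present, label = lbl)
      expect_equal(m$microchannel_present, row$microchannel_present,
                   label = lbl)
      expect_equal(m$crystal_present, row$crystal_present, label = lbl)
      q_expected <- if (row$thrombus_present) {
        round(row$thrombus_score_pct / 100 * 4 * n_les)
      } else 0
      expect_equal(m$thrombus_present, q_expected > 0, label = lbl)
      expect_lte(abs(m$thrombus_score_pct - row$thrombus_score_pct),
                 100 * 0.5 / (4 * n_les) + 1e-9)
      expect_equal(m$n_rupture_sites, row$n_rupture_sites, label = lbl)
      expect_lte(abs(m$rupture_length_mm - row$rupture_length_mm),
                 0.2 + (row$n_rupture_sites - 1) * 0.4 + 1e-9)
      expect_equal(m$rupture_depth_mm, row$rupture_depth_mm,
                   tolerance = 1e-9, label = lbl)
      expect_equal(m$rupture_arc_deg, min(row$rupture_arc_deg, 359.9),
                   tolerance = 1e-9, label = lbl)
      # phenotype from the painted arcs and caps
      expected_ph <- if (min(row$mean_lipid_arc_deg, 359.9) > 90) {
        if (row$min_fct_um <= 65) "TCFA" else "ThCFA"
      } else "non_fibroatheroma"
      expect_equal(m$phenotype, expected_ph, label = lbl)
    }
  }
})
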