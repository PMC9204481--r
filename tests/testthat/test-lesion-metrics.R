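test_that("native lesions are delimited by the 40% plaque-burden rule", {
  burden <- c(30, 35, 45, 50, 45, 35, 30, 20, 10, 5)
  areas <- rep(5, 10)
  pb <- make_pullback(areas, eem_areas = eem_for_burden(areas, burden))
  expect_equal(unname(delimit_lesion(pb)), c(2, 4))

  pb_all <- make_pullback(areas, eem_areas = eem_for_burden(areas, 50))
  expect_equal(unname(delimit_lesion(pb_all)), c(0, 9))

  pb_none <- make_pullback(areas, eem_areas = eem_for_burden(areas, 10))
  expect_error(delimit_lesion(pb_none), "no lesion")
})

test_that("lipid tissue alone delimits a native lesion when EEM is invisible", {
  pb <- make_pullback(rep(5, 6), lipid_arcs = c(NA, NA, 100, 100, NA, NA))
  expect_equal(unname(delimit_lesion(pb)), c(2, 3))
})

test_that("neoatherosclerotic lesions use the 0.5 mm neointima rule", {
  pb <- make_pullback(rep(4, 4), group = "PR-NA",
                      neointima = c(0.2, 0.6, 0.7, 0.3),
                      stent_areas = rep(8, 4))
  expect_equal(unname(delimit_lesion(pb)), c(1, 2))
})

test_that("PR-NA lesions extending beyond the stent fall back to the native rule", {
  # frames 0-1 outside the stent with qualifying burden, 2-3 in-stent
  n <- 4
  frames <- list(
    frame_annotation(0, 0.0, lumen_area_mm2 = 5, eem_area_mm2 = 10),
    frame_annotation(1, 0.4, lumen_area_mm2 = 5, eem_area_mm2 = 10),
    frame_annotation(2, 0.8, lumen_area_mm2 = 4, stent_area_mm2 = 8,
                     neointima_thickness_mm = 0.7),
    frame_annotation(3, 1.2, lumen_area_mm2 = 4, stent_area_mm2 = 8,
                     neointima_thickness_mm = 0.2))
  pb <- pullback(frames, group = "PR-NA")
  expect_equal(unname(delimit_lesion(pb)), c(0, 2))
})

test_that("MLA search minimizes area and breaks ties distally", {
  pb <- make_pullback(c(5, 3, 4), eem_areas = eem_for_burden(c(5, 3, 4), 50))
  expect_equal(find_mla(pb, 0, 2), list(mla_frame = 1L, mla_mm2 = 3))
  pb2 <- make_pullback(c(4, 3, 3, 5), eem_areas = eem_for_burden(rep(4, 4), 50))
  expect_equal(find_mla(pb2, 0, 3)$mla_frame, 2L)
  expect_equal(find_mla(pb2, 0, 3, tie = "proximal")$mla_frame, 1L)
  expect_error(find_mla(pb2, 3, 1), "empty")
})

test_that("segment split puts 2.5 mm either side of the MLA in the MLA site", {
  # 16 mm lesion at 0.4 mm, MLA central: 13 MLA-site frames
  areas <- rep(5, 41)
  pb <- make_pullback(areas, eem_areas = eem_for_burden(areas, 50))
  seg <- split_segments(pb, 0, 40, 20)
  expect_equal(sum(seg == "mla_site"), 13)
  expect_equal(sum(seg == "upstream"), 14)
  expect_equal(sum(seg == "downstream"), 14)
  expect_equal(length(seg), 41)  # segment bookkeeping: no frame lost

  seg2 <- split_segments(pb, 0, 40, 0)    # MLA at lesion start
  expect_equal(sum(seg2 == "upstream"), 0)

  pb_short <- make_pullback(rep(5, 11), eem_areas = eem_for_burden(rep(5, 11), 50))
  seg3 <- split_segments(pb_short, 0, 10, 5)  # 4 mm lesion: all MLA site
  expect_true(all(seg3 == "mla_site"))
})

test_that("radius gradient follows the shoulder taper formula", {
  # radii from the printed group-mean areas, 8 mm upstream length
  areas <- c(9.21, rep(5, 19), 2.93, rep(5, 19), 9.21)
  pb <- make_pullback(areas, eem_areas = eem_for_burden(areas, 50))
  rg <- radius_gradient(pb, 0, 40, 20)
  expect_equal(unname(rg["rg_up"]), (1.7122 - 0.9657) / 8, tolerance = 1e-3)
  expect_equal(unname(rg["rg_up"]), 0.0933, tolerance = 1e-3)
  expect_equal(unname(rg["rg_up"]), unname(rg["rg_down"]))  # symmetric lesion

  flat <- make_pullback(rep(5, 5), eem_areas = eem_for_burden(rep(5, 5), 50))
  expect_equal(unname(radius_gradient(flat, 0, 4, 2)), c(0, 0))

  edge <- radius_gradient(pb, 0, 40, 0)    # MLA at the lesion end
  expect_true(is.na(edge["rg_up"]))
  expect_false(is.na(edge["rg_down"]))
})

test_that("radius gradient is invariant to uniform scaling", {
  areas <- c(9, 6, 3, 5, 8)
  pb1 <- make_pullback(areas, eem_areas = eem_for_burden(areas, 50))
  s <- (0.375 / 0.4)^2   # scale radii by the spacing ratio
  pb2 <- make_pullback(areas * s, spacing = 0.375,
                       eem_areas = eem_for_burden(areas * s, 50))
  expect_equal(radius_gradient(pb2, 0, 4, 2), radius_gradient(pb1, 0, 4, 2),
               tolerance = 1e-12)
})

test_that("area stenosis matches the reference-mean formula", {
  expect_equal(area_stenosis(2.93, 9.21, 7.78), 65.5, tolerance = 0.05)
  expect_equal(area_stenosis(5, 5, 5), 0)
  expect_equal(area_stenosis(1e-9, 5, 5), 100, tolerance = 1e-6)
  expect_error(area_stenosis(2, NA, 5), "missing")
})

test_that("rupture sites are grouped, classified and measured", {
  areas <- rep(5, 41)
  areas[21] <- 2.5
  lipid <- rep(NA_real_, 41)
  lipid[10:30] <- 120
  mk <- function(rupture_frames) {
    make_pullback(areas, eem_areas = eem_for_burden(rep(5, 41), 50),
                  lipid_arcs = lipid, rupture = list(frames = rupture_frames,
                                                     arc_deg = 40))
  }
  # peak (frame index 18) 0.8 mm proximal to the MLA -> throat
  pb <- mk(19:20)
  sites <- classify_rupture_sites(pb, 0, 40, 20)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$longitudinal_class, "throat")
  expect_equal(sites[[1]]$distance_to_mla_mm, 0.8, tolerance = 1e-9)

  # peak 4 mm proximal -> upstream; plus a separate distal site
  pb2 <- mk(c(10:11, 35))
  sites2 <- classify_rupture_sites(pb2, 0, 40, 20)
  expect_length(sites2, 2)
  expect_equal(sites2[[1]]$longitudinal_class, "upstream")
  expect_equal(sites2[[2]]$longitudinal_class, "downstream")

  # rupture flag without an arc is an annotation error
  pb3 <- mk(19)
  pb3$frames[[19]]$arcs <- Filter(function(a) a$kind != "rupture",
                                  pb3$frames[[19]]$arcs)
  expect_error(classify_rupture_sites(pb3, 0, 40, 20), "without a rupture arc")
})

test_that("circumferential class depends on distance to the lipid edge", {
  frame_center <- frame_annotation(
    0, 0, lumen_area_mm2 = 4,
    arcs = list(arc_span(210, 330, "lipid"),      # lipid centered at 270
                arc_span(250, 290, "rupture")),   # rupture at lipid center
    rupture_present = TRUE)
  frame_shoulder <- frame_annotation(
    0, 0, lumen_area_mm2 = 4,
    arcs = list(arc_span(210, 330, "lipid"),
                arc_span(190, 230, "rupture")),   # midpoint at edge 210
    rupture_present = TRUE)
  th <- threshold_config()
  expect_equal(plaqrupt:::rupture_circumferential_class(frame_center, th),
               "center")
  expect_equal(plaqrupt:::rupture_circumferential_class(frame_shoulder, th),
               "shoulder")
})

test_that("site aggregation uses rupture sites as the denominator", {
  mk_site <- function(long, circ) structure(
    list(frame_range = 0L, peak_frame = 0L, longitudinal_class = long,
         circumferential_class = circ, distance_to_mla_mm = 0),
    class = "rupture_site")
  sites <- c(replicate(26, mk_site("upstream", "center"), simplify = FALSE),
             replicate(30, mk_site("throat", "center"), simplify = FALSE),
             replicate(8, mk_site("downstream", "shoulder"), simplify = FALSE))
  tab <- aggregate_rupture_sites(sites)
  margins <- tab[tab$circumferential_class == "any", ]
  expect_equal(margins$total, rep(64, 3))
  expect_equal(margins$percent[margins$longitudinal_class == "upstream"], 40.6)
  expect_equal(margins$percent[margins$longitudinal_class == "throat"], 46.9)
  expect_equal(margins$percent[margins$longitudinal_class == "downstream"], 12.5)
})

test_that("lesion delimitation recovers the synthetic generator extent", {
  for (g in c("PR-NV", "PR-NA")) {
    co <- simulate_cohort(group_params(g, 6, seed = 31))
    for (k in seq_len(nrow(co))) {
      pb <- synthesize_pullback(co[k, ], seed = 100 + k, margin_frames = 5)
      lim <- delimit_lesion(pb)
      n_les <- max(3, round(co$lesion_length_mm[k] / 0.4) + 1)
      expect_true(abs(lim[1] - 5) <= 1 && abs(lim[2] - (5 + n_les - 1)) <= 1,
                  label = sprintf("%s lesion %d extent", g, k))
    }
  }
})
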