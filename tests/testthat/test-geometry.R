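test_that("cosine lumen profile hits the specified references and MLA", {
  # equal reference and minimum diameters: a straight tube
  tube <- build_lumen_profile(lesion_spec(3, 3, 3, 10))
  expect_true(all(abs(tube$r - 1.5) < 1e-12))

  # study-mean native lesion: MLA area reproduced to 0.1%
  sp <- lesion_spec(2 * equivalent_radius(9.21), 2 * equivalent_radius(7.78),
                    2 * equivalent_radius(2.93), 16.3,
                    mla_axial_position_mm = 8.15)
  prof <- build_lumen_profile(sp)
  expect_lt(abs(pi * min(prof$r)^2 - 2.93) / 2.93, 0.001)
  expect_equal(prof$z[which.min(prof$r)], 8.15, tolerance = 0.05)
  expect_equal(pi * prof$r[1]^2, 9.21, tolerance = 1e-9)
  expect_equal(pi * prof$r[length(prof$r)]^2, 7.78, tolerance = 1e-9)

  expect_error(build_lumen_profile(lesion_spec(3, 3, 2, 10,
                                               mla_axial_position_mm = 12)),
               "MLA position")
  expect_error(build_lumen_profile(lesion_spec(3, 3, 2, 10), n_stations = 21),
               "n_stations")
})

test_that("profile is C1: no derivative jumps at the MLA or the ends", {
  sp <- lesion_spec(4, 3.5, 1.8, 16, mla_axial_position_mm = 7)
  prof <- build_lumen_profile(sp, n_stations = 401)
  d <- diff(prof$r) / diff(prof$z)
  expect_lt(max(abs(diff(d))), 0.02)  # curvature bounded, no slope jump
})

test_that("wall layering: cap minimum, EEM remodeling, strut lattice", {
  sp <- lesion_spec(4, 4, 2, 16, cap_min_um = 60, cap_mean_um = 200,
                    lipid_arc_deg = 140, lipid_length_mm = 6)
  g <- build_wall(sp)
  expect_equal(min(g$cap_thickness_mm) * 1000, 60, tolerance = 1e-9)
  expect_lt(g$lipid_pool$crown_z, 8)          # crown proximal to the MLA
  expect_true(all(g$lumen_r < g$cap_outer_r & g$cap_outer_r <= g$eem_r + 1e-9))

  # remodeling index 1.0: EEM area at the MLA equals the mean reference EEM
  sp1 <- lesion_spec(4, 4, 3.2, 16, cap_min_um = 150, cap_mean_um = 160,
                     lipid_arc_deg = 120, lipid_length_mm = 5,
                     remodeling_index = 1.0,
                     prox_ref_eem_mm2 = 20, dist_ref_eem_mm2 = 18)
  g1 <- build_wall(sp1)
  i_mla <- which.min(g1$lumen_r)
  expect_equal(pi * g1$eem_r[i_mla]^2, 19, tolerance = 1e-6)

  # stent lattice: one ring per mm from z = 0
  sp2 <- lesion_spec(4, 4, 2, 14.8, cap_min_um = 60, cap_mean_um = 232,
                     lipid_arc_deg = 140, lipid_length_mm = 6,
                     stent = stent_spec(3.5))
  g2 <- build_wall(sp2)
  expect_equal(length(g2$strut_z), floor(14.8 / 1) + 1)
  expect_equal(g2$stent_r, 1.75)

  expect_error(lesion_spec(4, 4, 2, 16, cap_min_um = 300, cap_mean_um = 100),
               "cap_min_um")
})

test_that("lumen volume matches numerical integration of pi r^2 dz", {
  sp <- lesion_spec(4, 3, 1.6, 20, mla_axial_position_mm = 12)
  g <- build_wall(sp, n_stations = 801)
  z_fine <- seq(0, 20, length.out = 20001)
  r_fine <- approx(g$z, g$lumen_r, xout = z_fine)$y
  v_ref <- sum(diff(z_fine) * (pi * r_fine[-1]^2 +
                               pi * r_fine[-length(r_fine)]^2) / 2)
  expect_lt(abs(lumen_volume(g) - v_ref) / v_ref, 0.001)
})

test_that("symmetric specs build mirror-symmetric geometry", {
  sp <- lesion_spec(4, 4, 2, 16)  # MLA central, equal references
  g <- build_lumen_profile(sp, n_stations = 201)
  expect_equal(g$r, rev(g$r), tolerance = 1e-12)
})

test_that("frames sampled from a built geometry recover the spec MLA", {
  sp <- lesion_spec(2 * equivalent_radius(5.80), 2 * equivalent_radius(4.96),
                    2 * equivalent_radius(2.00), 14.8)
  prof <- build_lumen_profile(sp, n_stations = 501)
  z_frames <- seq(0, 14.8, by = 0.4)
  areas <- pi * approx(prof$z, prof$r, xout = z_frames)$y^2
  pb <- make_pullback(areas, eem_areas = eem_for_burden(areas, 50))
  mla <- find_mla(pb, 0, length(areas) - 1)
  expect_lt(abs(z_frames[mla$mla_frame + 1] - sp$mla_axial_position_mm), 0.41)
  expect_lt(abs(mla$mla_mm2 - 2.00) / 2.00, 0.005)  # cosine is flat at the MLA
})

test_that("mean lesion spec averages per-lesion diameters and lengths", {
  one <- data.frame(mla_mm2 = 2.5, prox_ref_area_mm2 = 9,
                    dist_ref_area_mm2 = 7, lesion_length_mm = 15,
                    min_fct_um = 50, mean_fct_um = 180,
                    mean_lipid_arc_deg = 140, lipid_length_mm = 6)
  sp <- mean_lesion_spec(one)
  expect_equal(sp$min_lumen_diameter_mm, 2 * equivalent_radius(2.5))
  expect_equal(sp$lesion_length_mm, 15)

  two <- rbind(one, within(one, lesion_length_mm <- 25))
  expect_equal(mean_lesion_spec(two)$lesion_length_mm, 20)

  # stent diameter defaults to the mean reference lumen diameter
  st <- mean_lesion_spec(one, stented = TRUE)
  expect_equal(st$stent$stent_diameter_mm,
               mean(2 * equivalent_radius(c(9, 7))))
  expect_error(mean_lesion_spec(one[0, ]), "empty")
})

test_that("geometry exports: watertight STL and lossless station CSV", {
  g <- uniform_tube_geometry(n_stations = 41)
  stl <- withr::local_tempfile(fileext = ".stl")
  export_geometry(g, stl, format = "stl", n_theta = 24)
  expect_true(stl_watertight(stl))

  sp <- lesion_spec(4, 3, 1.6, 16)
  g2 <- build_wall(sp, n_stations = 101)
  stl2 <- withr::local_tempfile(fileext = ".stl")
  export_geometry(g2, stl2, format = "stl", n_theta = 24)
  expect_true(stl_watertight(stl2))

  csvf <- withr::local_tempfile(fileext = ".csv")
  export_geometry(g2, csvf, format = "profile-csv")
  back <- read.csv(csvf)
  expect_equal(back$lumen_r_mm, g2$lumen_r, tolerance = 1e-9)
  expect_equal(back$eem_r_mm, g2$eem_r, tolerance = 1e-9)
})
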