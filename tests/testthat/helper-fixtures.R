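# Programmatic fixtures shared across the suite.

# A minimal hand-built native-vessel pullback: `areas` give the lumen area
# per frame; plaque burden, lipid arcs and other features are painted per
# frame via the painter functions.
make_pullback <- function(areas, spacing = 0.4, group = "PR-NV",
                          eem_areas = NULL, lipid_arcs = NULL,
                          caps = NULL, neointima = NULL, stent_areas = NULL,
                          rupture = NULL, id = "fixture") {
  n <- length(areas)
  frames <- lapply(seq_len(n), function(i) {
    arcs <- list()
    if (!is.null(lipid_arcs) && !is.na(lipid_arcs[i]) && lipid_arcs[i] > 0) {
      arcs <- c(arcs, list(arc_span(270 - lipid_arcs[i] / 2,
                                    270 + lipid_arcs[i] / 2, "lipid")))
    }
    rupt <- !is.null(rupture) && i %in% rupture$frames
    if (rupt) {
      arcs <- c(arcs, list(arc_span(250, 250 + rupture$arc_deg, "rupture")))
    }
    frame_annotation(
      frame_index = i - 1L, z_mm = (i - 1) * spacing,
      lumen_area_mm2 = areas[i],
      eem_area_mm2 = if (!is.null(eem_areas)) eem_areas[i] else NULL,
      neointima_thickness_mm = if (!is.null(neointima)) neointima[i] else NULL,
      stent_area_mm2 = if (!is.null(stent_areas)) stent_areas[i] else NULL,
      arcs = arcs,
      cap_thickness_um = if (!is.null(caps)) caps[[i]] else NULL,
      rupture_present = rupt)
  })
  pullback(frames, frame_spacing_mm = spacing, group = group, id = id)
}

# burden (%) -> EEM areas for given lumen areas
eem_for_burden <- function(areas, burden_pct) areas / (1 - burden_pct / 100)

# straight-tube geometry with uniform cap thickness
uniform_tube_geometry <- function(radius_mm = 1, length_mm = 20,
                                  cap_um = 100, n_stations = 201) {
  sp <- lesion_spec(2 * radius_mm, 2 * radius_mm, 2 * radius_mm, length_mm,
                    cap_min_um = cap_um, cap_mean_um = cap_um,
                    lipid_arc_deg = 120, lipid_length_mm = length_mm)
  build_wall(sp, n_stations = n_stations)
}

# the two study-mean lesion geometries (native / stented)
table_mean_geometries <- function() {
  nv <- lesion_spec(2 * equivalent_radius(9.21), 2 * equivalent_radius(7.78),
                    2 * equivalent_radius(2.93), 16.3,
                    cap_min_um = 49, cap_mean_um = 186,
                    lipid_arc_deg = 150.5, lipid_length_mm = 6.1)
  na <- lesion_spec(2 * equivalent_radius(5.80), 2 * equivalent_radius(4.96),
                    2 * equivalent_radius(2.00), 14.8,
                    cap_min_um = 60, cap_mean_um = 232,
                    lipid_arc_deg = 167.3, lipid_length_mm = 7.8,
                    stent = stent_spec(
                      mean(2 * equivalent_radius(c(5.80, 4.96)))))
  list(native = build_wall(nv), stented = build_wall(na))
}
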