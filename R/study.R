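## End-to-end study runner: simulated (or supplied) two-group cohorts ->
## per-lesion analyses -> comparison tables -> mean lesion specs ->
## idealized geometries -> flow and stress summaries.

#' Study run configuration
#'
#' Fully serializable bundle of every knob of the end-to-end analysis; a run
#' writes the resolved configuration next to its outputs.
#'
#' @param seed base seed for all randomness.
#' @param n_nv,n_na cohort sizes (defaults 56 native, 24 neoatherosclerotic).
#' @param thresholds a [threshold_config()].
#' @param conditions a [flow_conditions()].
#' @param material a [material_model()].
#' @param solver `"quasi1d"` or `"axisymmetric"` for the flow stage.
#' @param grid `c(nz, nr)` for the axisymmetric solver.
#' @param out_dir optional output directory; when given, tables and the
#'   resolved configuration are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 7L, n_nv = 56L, n_na = 24L,
                       thresholds = threshold_config(),
                       conditions = flow_conditions(),
                       material = material_model(),
                       solver = c("quasi1d", "axisymmetric"),
                       grid = c(121, 25), out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_nv = as.integer(n_nv),
              n_na = as.integer(n_na), thresholds = thresholds,
              conditions = conditions, material = material,
              solver = match.arg(solver), grid = grid, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full two-group study on simulated cohorts
#'
#' Simulates both lesion cohorts, synthesizes their pullbacks, runs the
#' lesion and morphometry pipelines on every pullback, builds the
#' lesion-level comparison table and the rupture-site location table,
#' derives the mean lesion specification per group, builds the native and
#' stented idealized geometries, and evaluates the flow and structural
#' stress surrogates on each.
#'
#' @param config a [run_config()].
#' @param cohorts optional list with elements `nv` and `na`: lists of
#'   `oct_pullback` objects to analyze instead of simulated ones.
#' @return An object of class `study_bundle`: list with `config`,
#'   `metrics_nv`, `metrics_na` (per-lesion tables), `comparison`
#'   (lesion-level table), `rupture_sites_nv`, `rupture_sites_na`
#'   (location tables), `frame_prevalence` (per-group feature table),
#'   `spec_nv`, `spec_na`, `geometry_nv`, `geometry_na`, `flow_nv`,
#'   `flow_na`, `stress_nv`, `stress_na`.
#' @export
run_full_study <- function(config = run_config(), cohorts = NULL) {
  th <- config$thresholds
  if (is.null(cohorts)) {
    cohort_tabs <- list(
      nv = simulate_cohort(group_params("PR-NV", config$n_nv,
                                        seed = config$seed + 1L)),
      na = simulate_cohort(group_params("PR-NA", config$n_na,
                                        seed = config$seed + 2L)))
    cohorts <- list(
      nv = synthesize_cohort_pullbacks(cohort_tabs$nv,
                                       seed = config$seed * 100L),
      na = synthesize_cohort_pullbacks(cohort_tabs$na,
                                       seed = config$seed * 100L + 1000L))
  }
  for (g in names(cohorts)) {
    if (!length(cohorts[[g]])) stop("empty group: ", g)
  }

  analyze_group <- function(pbs, label) {
    rows <- vector("list", length(pbs))
    sites <- list()
    for (k in seq_along(pbs)) {
      pb <- pbs[[k]]
      lesion <- tryCatch(lesion_record(pb, th), error = function(e) {
        stop("stage lesion_metrics failed for lesion '", pb$id, "': ",
             conditionMessage(e))
      })
      morph <- tryCatch(morphometry(pb, lesion, th), error = function(e) {
        stop("stage tissue_morphometry failed for lesion '", pb$id, "': ",
             conditionMessage(e))
      })
      rows[[k]] <- lesion_metric_row(lesion, morph)
      sites <- c(sites, lesion$rupture_sites)
    }
    list(metrics = do.call(rbind, rows), sites = sites)
  }
  nv <- analyze_group(cohorts$nv, "PR-NV")
  na <- analyze_group(cohorts$na, "PR-NA")

  feats <- c("tcfa", "thcfa", "calcific", "macrophages",
             "macrophages_spotted", "macrophages_lined", "microchannel",
             "cholesterol_crystal", "rupture", "thrombus")
  prev <- do.call(rbind, lapply(feats, function(f) {
    a <- frame_prevalence(cohorts$nv, f, th)
    b <- frame_prevalence(cohorts$na, f, th)
    data.frame(feature = f, nv_count = a$count, nv_total = a$total,
               nv_percent = a$percent, na_count = b$count,
               na_total = b$total, na_percent = b$percent)
  }))

  spec_nv <- mean_lesion_spec(nv$metrics, stented = FALSE)
  spec_na <- mean_lesion_spec(na$metrics, stented = TRUE)
  geom_nv <- build_wall(spec_nv)
  geom_na <- build_wall(spec_na)
  flow_of <- function(g) {
    if (config$solver == "axisymmetric") {
      axisymmetric_ns_solve(g, config$conditions,
                            nz = config$grid[1], nr = config$grid[2],
                            high_ess_pa = th$high_ess_pa)
    } else {
      quasi1d_flow(g, config$conditions, high_ess_pa = th$high_ess_pa)
    }
  }
  flow_nv <- flow_of(geom_nv)
  flow_na <- flow_of(geom_na)

  bundle <- list(
    config = config,
    metrics_nv = nv$metrics, metrics_na = na$metrics,
    comparison = build_comparison_table(nv$metrics, na$metrics),
    rupture_sites_nv = aggregate_rupture_sites(nv$sites),
    rupture_sites_na = aggregate_rupture_sites(na$sites),
    frame_prevalence = prev,
    spec_nv = spec_nv, spec_na = spec_na,
    geometry_nv = geom_nv, geometry_na = geom_na,
    flow_nv = flow_nv, flow_na = flow_na,
    stress_nv = cap_stress_estimate(geom_nv, flow_nv, config$material,
                                    stented = FALSE, thresholds = th),
    stress_na = cap_stress_estimate(geom_na, flow_na, config$material,
                                    stented = TRUE, thresholds = th))
  class(bundle) <- "study_bundle"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.csv(
      df, file.path(config$out_dir, f), row.names = FALSE)
    w(bundle$metrics_nv, "metrics_nv.csv")
    w(bundle$metrics_na, "metrics_na.csv")
    w(bundle$comparison, "comparison_table.csv")
    w(bundle$rupture_sites_nv, "rupture_sites_nv.csv")
    w(bundle$rupture_sites_na, "rupture_sites_na.csv")
    w(bundle$frame_prevalence, "frame_prevalence.csv")
    cfg <- config
    cfg$out_dir <- NULL
    jsonlite::write_json(
      lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x),
      file.path(config$out_dir, "resolved_config.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  bundle
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("Study bundle: %d native + %d neoatherosclerotic lesions\n",
              nrow(x$metrics_nv), nrow(x$metrics_na)))
  cat(sprintf("  flow (%s): tau_max %.1f vs %.1f Pa; dp %.2f vs %.2f mmHg\n",
              x$flow_nv$solver, x$flow_nv$tau_max, x$flow_na$tau_max,
              x$flow_nv$pressure_drop_mmhg, x$flow_na$pressure_drop_mmhg))
  cat(sprintf("  superficial PSS: %.1f (native) vs %.1f (stented) kPa\n",
              x$stress_nv$superficial_pss_kpa,
              x$stress_na$superficial_pss_kpa))
  invisible(x)
}
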