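#' Pipeline run configuration
#'
#' Bundles every stage's configuration for an end-to-end run: input table
#' (or synthetic cohort request), QC thresholds, phenotype rules, HLA-1
#' calling, aggregation, neighborhood analysis, and output directory.
#'
#' @param input Path to a cell-table CSV, or `NULL` to simulate a cohort.
#' @param schema Column mapping for [read_cell_table()].
#' @param markers Marker columns of the input.
#' @param unit Coordinate unit of the input (`"um"` or `"px"`).
#' @param qc A [qc_config()].
#' @param rules Phenotype rules (list of [phenotype_rule()]).
#' @param tumor_mask_marker Tumor mask marker name.
#' @param hla An [hla_call_config()].
#' @param caa A [caa_config()].
#' @param nbhd An [nbhd_config()].
#' @param cohort List of arguments for [generate_cohort()] (used when
#'   `input` is `NULL`).
#' @param out_dir Output directory.
#' @param seed Integer seed for any randomness (simulation).
#' @return A `run_config`.
#' @export
run_config <- function(input = NULL, schema = list(), markers = SYN_MARKERS,
                       unit = "um", qc = qc_config(),
                       rules = default_phenotype_rules(),
                       tumor_mask_marker = "S100",
                       hla = hla_call_config(),
                       caa = caa_config(growth_cutoff = 3),
                       nbhd = nbhd_config(
                         center_classes = c("CD3", "CD8PD1"),
                         nnd_pairs = list(c("CD3", "Tumor_HLA1pos"),
                                          c("CD3", "Tumor_HLA1neg"),
                                          c("CD8PD1", "Tumor_HLA1pos"),
                                          c("CD8PD1", "Tumor_HLA1neg"))),
                       cohort = list(n_brisk = 2L, n_nonbrisk = 2L,
                                     fovs_per_sample = 5L),
                       out_dir = tempfile("tmespat_run_"), seed = 1L) {
  structure(list(input = input, schema = schema, markers = markers,
                 unit = unit, qc = qc, rules = rules,
                 tumor_mask_marker = tumor_mask_marker, hla = hla,
                 caa = caa, nbhd = nbhd, cohort = cohort,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(cfg) {
  # stable fingerprint of the analysis configuration (output location
  # excluded), without external digest deps
  cfg$out_dir <- NULL
  ser <- serialize(cfg, connection = NULL, version = 2L)
  sum(as.integer(ser) * (seq_along(ser) %% 251L + 1L)) %% 2147483647L
}

stage_error <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' read/simulate -> QC -> phenotype -> HLA-1 call -> aggregation (per-FOV
#' tumor and CD3 aggregates, infiltration areas) -> neighborhood analysis
#' (region-tagged, NND summaries) -> quantification (per-FOV ratios inside
#' and over the whole FOV, correlogram, infiltration-fraction summaries,
#' group comparison when a cohort design is known). All outputs are written
#' under `cfg$out_dir` as CSV/GeoJSON plus a JSON run manifest with the
#' config fingerprint and per-stage row counts; reruns with the same
#' config and seed are byte-identical.
#'
#' @param cfg A [run_config()].
#' @return The output directory path, invisibly; the manifest is at
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("tmespat")),
                   config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = list())
  note <- function(stage, n) manifest$stages[[stage]] <<- n

  # --- input ---------------------------------------------------------------
  design <- NULL
  cells <- tryCatch({
    if (is.null(cfg$input)) {
      cohort <- do.call(generate_cohort, c(cfg$cohort, list(seed = cfg$seed)))
      design <- cohort$design
      cohort$cells
    } else {
      read_cell_table(cfg$input, schema = cfg$schema,
                      markers = cfg$markers, unit = cfg$unit)
    }
  }, error = function(e) stage_error("input", e))
  note("input", nrow(cells))
  if (identical(coord_unit(cells), "px")) {
    if (is.null(cfg$qc$pixel_size_um))
      stage_error("units", simpleError("input in pixels but pixel_size_um not set"))
    cells <- pixels_to_microns(cells, cfg$qc$pixel_size_um)
  }

  # --- QC ------------------------------------------------------------------
  qc_out <- tryCatch(apply_qc(cells, cfg$qc),
                     error = function(e) stage_error("qc", e))
  cells <- qc_out$cells
  note("qc", nrow(cells))

  # --- phenotyping + HLA-1 -------------------------------------------------
  cells <- tryCatch(
    assign_phenotypes(cells, cfg$rules, cfg$tumor_mask_marker),
    error = function(e) stage_error("phenotype", e))
  cells <- tryCatch(call_hla1_status(cells, cfg$hla),
                    error = function(e) stage_error("hla_call", e))
  note("phenotyped", nrow(cells))
  write_cell_table(cells, file.path(cfg$out_dir, "cells_phenotyped.csv"))

  # --- aggregation ---------------------------------------------------------
  classes <- cell_classes(cells)
  tumor_classes <- c("Tumor_HLA1pos", "Tumor_HLA1neg")
  fovs <- unique(cells$fov_id)
  ias <- list(); agg_rows <- list(); ia_regions <- list()
  tryCatch({
    for (f in fovs) {
      window <- fov_window(cells, f)
      grid <- grid_counts(cells, window, cfg$caa,
                          classes = unique(classes),
                          class_of = classes[cells$fov_id == f])
      # tumor aggregate on pooled tumor counts (both HLA-1 classes)
      tum <- grid
      tum$counts <- c(grid$counts,
                      list(Tumor_all = Reduce(`+`, grid$counts[
                        intersect(tumor_classes, names(grid$counts))])))
      tumor_aggs <- if (!is.null(tum$counts$Tumor_all))
        grow_aggregates(tum, "Tumor_all", cfg$caa) else list()
      cd3_aggs <- if ("CD3" %in% names(grid$counts))
        grow_aggregates(grid, "CD3", cfg$caa) else list()
      tumor_aggs <- aggregates_to_polygons(tumor_aggs)
      cd3_aggs <- aggregates_to_polygons(cd3_aggs)
      ia <- infiltration_areas(tumor_aggs, cd3_aggs, grid)
      ias[[as.character(f)]] <- ia
      ia_regions[[as.character(f)]] <- ia$region
      agg_rows[[length(agg_rows) + 1L]] <- aggregate_summary(
        list(Tumor = tumor_aggs, CD3 = cd3_aggs), ia)
    }
  }, error = function(e) stage_error("caa", e))
  agg_summary <- do.call(rbind, agg_rows)
  utils::write.csv(agg_summary, file.path(cfg$out_dir, "aggregates.csv"),
                   row.names = FALSE)
  regions_to_geojson(
    stats::setNames(lapply(names(ias), function(f) ias[[f]]$region), names(ias)),
    file.path(cfg$out_dir, "infiltration_areas.geojson"))
  note("fovs", length(fovs))

  # --- neighborhood analysis ----------------------------------------------
  records <- tryCatch({
    rec <- neighborhoods(cells, cfg$nbhd, class_of = classes)
    tag_regions(rec, ias)
  }, error = function(e) stage_error("cnaa", e))
  note("neighborhoods", nrow(records))
  utils::write.csv(as.data.frame(records),
                   file.path(cfg$out_dir, "neighborhoods.csv"),
                   row.names = FALSE)
  nnd_sum <- summarize_nnd(records)
  utils::write.csv(nnd_sum$per_fov, file.path(cfg$out_dir, "nnd_per_fov.csv"),
                   row.names = FALSE)
  utils::write.csv(nnd_sum$overall, file.path(cfg$out_dir, "nnd_overall.csv"),
                   row.names = FALSE)

  # --- quantification ------------------------------------------------------
  ratios <- tryCatch(fov_ratios(cells, class_of = classes),
                     error = function(e) stage_error("quantify", e))
  ratios_ia <- fov_ratios(cells, regions = ia_regions, class_of = classes)
  utils::write.csv(as.data.frame(ratios),
                   file.path(cfg$out_dir, "fov_ratios.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ratios_ia),
                   file.path(cfg$out_dir, "fov_ratios_in_ia.csv"),
                   row.names = FALSE)
  export_heatmap(ratios, file.path(cfg$out_dir, "ratio_heatmap.csv"))
  cg <- tryCatch(correlogram(ratios), error = function(e) NULL)
  if (!is.null(cg))
    utils::write.csv(correlogram_table(cg),
                     file.path(cfg$out_dir, "correlogram.csv"),
                     row.names = FALSE)

  infil <- data.frame(
    fov_id = names(ias),
    sample_id = vapply(names(ias), function(f)
      cells$sample_id[cells$fov_id == f][1], character(1)),
    ia_area_um2 = vapply(ias, `[[`, numeric(1), "area_um2"),
    tumor_area_um2 = vapply(ias, `[[`, numeric(1), "tumor_area_um2"),
    infiltration_fraction = vapply(ias, `[[`, numeric(1),
                                   "infiltration_fraction"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(design))
    infil$group <- design$group[match(infil$fov_id, design$fov_id)]
  utils::write.csv(infil, file.path(cfg$out_dir, "infiltration.csv"),
                   row.names = FALSE)
  group_cmp <- NULL
  if (!is.null(design) && length(unique(infil$group)) == 2L) {
    ok <- !is.na(infil$infiltration_fraction)
    med <- stats::median(infil$infiltration_fraction[ok])
    # outcome = FOV fraction above the cohort median, strata = sample;
    # degenerate strata are reported in the manifest, not warned about
    group_cmp <- tryCatch(
      suppressWarnings(
        cmh_test(outcome = infil$infiltration_fraction[ok] > med,
                 group = infil$group[ok],
                 stratum = infil$sample_id[ok])),
      error = function(e) list(error = conditionMessage(e)))
    grp_sum <- summarize_per_fov(infil, "infiltration_fraction", "group")
    utils::write.csv(grp_sum, file.path(cfg$out_dir, "infiltration_by_group.csv"),
                     row.names = FALSE)
  }

  manifest$hla_threshold <- as.list(attr(cells, "hla_threshold"))
  manifest$qc <- unclass(qc_out$report)[c("n_input", "n_retained", "n_excluded")]
  if (!is.null(group_cmp)) manifest$group_comparison <- group_cmp
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}
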