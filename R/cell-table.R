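#' Single-cell tables from multiplexed immunofluorescence
#'
#' A `cell_table` is a data frame with one row per segmented cell and a
#' small set of canonical columns: `cell_id`, `fov_id`, `sample_id`,
#' centroid coordinates `x`/`y`, per-cell QC metrics (`qc_alignment`,
#' `px_nucleus`/`px_membrane`/`px_cytoplasm`, `n_nuclei`), one intensity
#' column per marker, and (after phenotyping) a `phenotype` column.
#' Coordinate units are tracked in the `unit` attribute (`"px"` or `"um"`);
#' marker column names are tracked in the `markers` attribute. Any further
#' columns of the source file are carried through untouched.
#'
#' @name cell_table
NULL

QC_COLS <- c("qc_alignment", "px_nucleus", "px_membrane", "px_cytoplasm", "n_nuclei")

new_cell_table <- function(df, unit = "um", markers = character()) {
  stopifnot(is.data.frame(df))
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            unit = unit, markers = markers,
            class = c("cell_table", "data.frame"))
}

#' Coordinate unit of a cell table
#' @param x A `cell_table`.
#' @return `"px"` or `"um"`.
#' @export
coord_unit <- function(x) attr(x, "unit", exact = TRUE)

#' Marker columns of a cell table
#' @param x A `cell_table`.
#' @return Character vector of marker intensity column names.
#' @export
markers <- function(x) attr(x, "markers", exact = TRUE)

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d FOV(s), unit = %s\n",
              nrow(x), length(unique(x$fov_id)), coord_unit(x)))
  if (length(markers(x)))
    cat("  markers:", paste(markers(x), collapse = ", "), "\n")
  if ("phenotype" %in% names(x)) {
    tab <- table(x$phenotype, useNA = "ifany")
    cat("  phenotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

# subsetting keeps class and attributes
#' @export
`[.cell_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out))
    out <- new_cell_table(out, unit = coord_unit(x), markers = markers(x))
  out
}

validate_cell_table <- function(df) {
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("cell coordinates must be finite", call. = FALSE)
  if ("qc_alignment" %in% names(df)) {
    bad <- which(!is.na(df$qc_alignment) &
                   (df$qc_alignment < 0 | df$qc_alignment > 1))
    if (length(bad))
      stop(sprintf("qc_alignment outside [0,1] at row(s) %s",
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if ("n_nuclei" %in% names(df)) {
    bad <- which(!is.na(df$n_nuclei) & df$n_nuclei < 0)
    if (length(bad))
      stop("n_nuclei must be nonnegative", call. = FALSE)
  }
  invisible(df)
}

#' Read a single-cell table from delimited text
#'
#' Reads a CSV/TSV cell table as produced by multiplexed immunofluorescence
#' image analysis (cell centroid coordinates, per-marker fluorescence
#' intensities, per-cell QC metrics) and maps its columns onto the canonical
#' `cell_table` schema. Row order is preserved and unmapped columns are kept
#' as passthrough metadata.
#'
#' @param path Path to a delimited text file.
#' @param schema Named list/vector mapping canonical names (`cell_id`,
#'   `fov_id`, `sample_id`, `x`, `y`, and optionally `qc_alignment`,
#'   `px_nucleus`, `px_membrane`, `px_cytoplasm`, `n_nuclei`) to the file's
#'   column names. Identity mapping for any canonical column already named
#'   canonically in the file.
#' @param markers Character vector naming the intensity columns (after
#'   renaming) that hold marker fluorescence values.
#' @param unit Coordinate unit of the file, `"px"` or `"um"`.
#' @param sep Field separator (default `","`).
#' @return A [cell_table].
#' @export
read_cell_table <- function(path, schema = list(), markers = character(),
                            unit = "um", sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  schema <- unlist(schema)
  # rename mapped columns to canonical names
  for (canon in names(schema)) {
    src <- schema[[canon]]
    if (!src %in% names(df))
      stop(sprintf("schema maps '%s' to missing column '%s'", canon, src),
           call. = FALSE)
    names(df)[names(df) == src] <- canon
  }
  for (req in c("cell_id", "fov_id", "x", "y")) {
    if (!req %in% names(df))
      stop(sprintf("mandatory column missing: '%s'", req), call. = FALSE)
  }
  if (!"sample_id" %in% names(df)) df$sample_id <- "sample1"
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' coordinate at row(s) %s", cc,
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("missing '%s' coordinate", cc), call. = FALSE)
    df[[cc]] <- v
  }
  missing_markers <- setdiff(markers, names(df))
  if (length(missing_markers))
    stop("marker column(s) missing: ", paste(missing_markers, collapse = ", "),
         call. = FALSE)
  for (m in markers) {
    df[[m]] <- as.numeric(df[[m]])
    if (any(df[[m]] < 0, na.rm = TRUE))
      stop(sprintf("negative intensity in marker '%s'", m), call. = FALSE)
  }
  validate_cell_table(df)
  new_cell_table(df, unit = unit, markers = markers)
}

#' Write a cell table to delimited text
#'
#' Inverse of [read_cell_table()] under the identity schema: all canonical
#' columns, marker intensities and passthrough columns are written as CSV.
#'
#' @param table A [cell_table].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_cell_table <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert cell coordinates from pixels to microns
#'
#' Multiplies centroid coordinates by the pixel size and flips the unit flag
#' to microns. Idempotent: a table already in microns is returned unchanged,
#' so accidental double conversion is impossible.
#'
#' @param table A [cell_table].
#' @param pixel_size_um Physical size of one pixel in microns (> 0). There
#'   is no universal default: this depends on the microscope objective and
#'   must be supplied from the imaging metadata.
#' @return The table with `x`, `y` in microns.
#' @export
pixels_to_microns <- function(table, pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number", call. = FALSE)
  if (identical(coord_unit(table), "um")) return(table)
  table$x <- table$x * pixel_size_um
  table$y <- table$y * pixel_size_um
  attr(table, "unit") <- "um"
  table
}

#' QC filter configuration
#'
#' Thresholds for excluding poorly aligned, poorly segmented, or
#' artificially generated cells. Defaults follow common practice for
#' iteratively stained immunofluorescence: nuclear alignment score at least
#' 0.85, at least 10 pixels in each subcellular compartment, and at most 2
#' nuclei per cell. All boundaries are inclusive for retention.
#'
#' @param min_alignment Minimum nuclear alignment score in \[0,1\].
#' @param min_pixels_per_compartment Minimum pixel count required in each of
#'   the nucleus, membrane and cytoplasm compartments.
#' @param max_nuclei Maximum number of nuclei per cell.
#' @param pixel_size_um Optional pixel size used by [pixels_to_microns()].
#' @param min_round_alignment Optional extra threshold on an all-rounds
#'   alignment column (`qc_round_alignment`); `NULL` disables it (default).
#' @param on_missing What to do with cells whose QC fields are missing:
#'   `"reject"` (default) or `"pass"`.
#' @return A `qc_config` object.
#' @export
qc_config <- function(min_alignment = 0.85, min_pixels_per_compartment = 10L,
                      max_nuclei = 2L, pixel_size_um = NULL,
                      min_round_alignment = NULL,
                      on_missing = c("reject", "pass")) {
  on_missing <- match.arg(on_missing)
  stopifnot(min_alignment >= 0, min_alignment <= 1,
            min_pixels_per_compartment >= 0, max_nuclei >= 1)
  if (!is.null(pixel_size_um)) stopifnot(pixel_size_um > 0)
  structure(list(min_alignment = min_alignment,
                 min_pixels_per_compartment = as.integer(min_pixels_per_compartment),
                 max_nuclei = as.integer(max_nuclei),
                 pixel_size_um = pixel_size_um,
                 min_round_alignment = min_round_alignment,
                 on_missing = on_missing),
            class = "qc_config")
}

#' Apply per-cell QC filtering
#'
#' Retains cells passing every QC rule: alignment score >= `min_alignment`,
#' every compartment pixel count >= `min_pixels_per_compartment`, and
#' `n_nuclei` <= `max_nuclei`. Filtering is per-cell independent. Cells with
#' missing QC fields are rejected by default (see [qc_config()]).
#'
#' @param table A [cell_table].
#' @param cfg A [qc_config()].
#' @return A list with elements `cells` (the filtered [cell_table]) and
#'   `report` (a `qc_report`: per-rule exclusion counts, which may overlap,
#'   and the unique number excluded).
#' @export
apply_qc <- function(table, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  n <- nrow(table)
  get <- function(col) if (col %in% names(table)) table[[col]] else rep(NA_real_, n)

  align <- get("qc_alignment")
  nnuc  <- get("n_nuclei")
  pxs   <- cbind(get("px_nucleus"), get("px_membrane"), get("px_cytoplasm"))

  fail_align <- !is.na(align) & align < cfg$min_alignment
  fail_px    <- apply(pxs, 1L, function(p) any(!is.na(p) & p < cfg$min_pixels_per_compartment))
  fail_nuc   <- !is.na(nnuc) & nnuc > cfg$max_nuclei
  fail_round <- rep(FALSE, n)
  if (!is.null(cfg$min_round_alignment)) {
    ra <- get("qc_round_alignment")
    fail_round <- !is.na(ra) & ra < cfg$min_round_alignment
  }
  any_missing <- is.na(align) | is.na(nnuc) | apply(pxs, 1L, anyNA)
  fail_missing <- if (cfg$on_missing == "reject") any_missing else rep(FALSE, n)

  excluded <- fail_align | fail_px | fail_nuc | fail_round | fail_missing
  report <- structure(list(
    n_input = n,
    n_retained = sum(!excluded),
    n_excluded = sum(excluded),
    by_rule = c(alignment = sum(fail_align),
                compartment_pixels = sum(fail_px),
                n_nuclei = sum(fail_nuc),
                round_alignment = sum(fail_round),
                missing_qc = sum(fail_missing)),
    empty_result = all(excluded) && n > 0L
  ), class = "qc_report")
  list(cells = table[!excluded, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d cells in, %d retained, %d excluded\n",
              x$n_input, x$n_retained, x$n_excluded))
  for (r in names(x$by_rule))
    cat(sprintf("  %-20s %d\n", r, x$by_rule[[r]]))
  if (x$empty_result) cat("  WARNING: no cells passed QC\n")
  invisible(x)
}

#' Field-of-view windows
#'
#' Rectangular analysis window of one FOV. By default the tight bounding box
#' of that FOV's cells, optionally expanded by a margin.
#'
#' @param cells A [cell_table] (one or several FOVs).
#' @param fov_id FOV to window; default the single FOV present.
#' @param margin Margin added on every side, in coordinate units.
#' @param bounds Optional explicit `c(x_min, x_max, y_min, y_max)` override.
#' @return An `fov_window` object.
#' @export
fov_window <- function(cells, fov_id = NULL, margin = 0, bounds = NULL) {
  if (is.null(fov_id)) {
    ids <- unique(cells$fov_id)
    if (length(ids) != 1L)
      stop("multiple FOVs present; supply fov_id", call. = FALSE)
    fov_id <- ids
  }
  sub <- cells[cells$fov_id == fov_id, , drop = FALSE]
  if (is.null(bounds)) {
    if (!nrow(sub)) stop("no cells in FOV ", fov_id, call. = FALSE)
    bounds <- c(min(sub$x) - margin, max(sub$x) + margin,
                min(sub$y) - margin, max(sub$y) + margin)
  }
  stopifnot(bounds[1] < bounds[2], bounds[3] < bounds[4])
  structure(list(fov_id = fov_id, x_min = bounds[1], x_max = bounds[2],
                 y_min = bounds[3], y_max = bounds[4]),
            class = "fov_window")
}

#' @export
print.fov_window <- function(x, ...) {
  cat(sprintf("<fov_window> %s: [%.6g, %.6g] x [%.6g, %.6g]\n",
              x$fov_id, x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}
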