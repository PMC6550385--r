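#' Cell aggregation algorithm configuration
#'
#' The aggregation algorithm works on a quadrat grid: (i) subdivide the FOV
#' window into equal squares, (ii) count cells of each class per square,
#' (iii) take the distribution of counts over all squares, (iv) seed
#' aggregates at squares whose count is strictly above the chosen
#' percentile of that distribution, (v-vi) grow each seed layer by layer,
#' absorbing adjacent squares holding at least `growth_cutoff` cells, until
#' no adjacent square qualifies, and (vii) contain all joint and disjoint
#' squares of each aggregate in a (possibly multi-part) polygon.
#'
#' @param square_size_um Quadrat side length in microns (default 50).
#' @param seed_percentile Percentile of the per-square count distribution
#'   above which squares seed aggregates (default 95; strictly greater
#'   than, quantile by linear interpolation).
#' @param growth_cutoff Minimum cell count for a square to be absorbed
#'   during growth; `"auto"` (default) uses the median of the nonzero
#'   per-square counts of the class.
#' @param connectivity Square adjacency: 8 (default; the full surrounding
#'   layer, edges and corners) or 4 (edges only).
#' @return A `caa_config`.
#' @export
caa_config <- function(square_size_um = 50, seed_percentile = 95,
                       growth_cutoff = "auto", connectivity = 8) {
  stopifnot(square_size_um > 0,
            seed_percentile > 0, seed_percentile < 100,
            connectivity %in% c(4, 8))
  if (!identical(growth_cutoff, "auto"))
    stopifnot(is.numeric(growth_cutoff), growth_cutoff >= 0)
  structure(list(square_size_um = square_size_um,
                 seed_percentile = seed_percentile,
                 growth_cutoff = growth_cutoff,
                 connectivity = as.integer(connectivity)),
            class = "caa_config")
}

#' Quadrat counts of cell classes over an FOV window
#'
#' Subdivides the window into squares of side `cfg$square_size_um` anchored
#' at the window's lower-left corner and counts the cells of each class per
#' square. Binning is half-open (`[x0 + j*s, x0 + (j+1)*s)`), with the last
#' column/row closed so every in-window cell lands in exactly one square.
#'
#' @param cells A [cell_table] (micron coordinates, classes assigned).
#' @param window An [fov_window()] covering the cells.
#' @param cfg A [caa_config()].
#' @param classes Class labels to count; default every label present.
#' @param class_of Per-cell class labels; default [cell_classes()] of the
#'   table.
#' @return A `grid_counts` object: per-class count matrices (rows from the
#'   bottom), grid origin and square size.
#' @export
grid_counts <- function(cells, window, cfg = caa_config(), classes = NULL,
                        class_of = NULL) {
  stopifnot(inherits(window, "fov_window"), inherits(cfg, "caa_config"))
  sub <- cells[cells$fov_id == window$fov_id, , drop = FALSE]
  if (is.null(class_of)) class_of <- cell_classes(sub)
  stopifnot(length(class_of) == nrow(sub))
  if (is.null(classes)) classes <- sort(unique(class_of))
  s <- cfg$square_size_um
  x0 <- window$x_min; y0 <- window$y_min
  n_cols <- max(1L, ceiling((window$x_max - x0) / s - 1e-9))
  n_rows <- max(1L, ceiling((window$y_max - y0) / s - 1e-9))
  bin <- function(v, v0, n) pmin(pmax(floor((v - v0) / s), 0), n - 1L)
  col <- bin(sub$x, x0, n_cols)
  row <- bin(sub$y, y0, n_rows)
  inside <- sub$x >= x0 & sub$x <= window$x_max &
            sub$y >= y0 & sub$y <= window$y_max
  counts <- lapply(classes, function(cl) {
    sel <- inside & class_of == cl
    m <- matrix(0L, nrow = n_rows, ncol = n_cols)
    if (any(sel)) {
      tab <- table(factor(row[sel], levels = 0:(n_rows - 1L)),
                   factor(col[sel], levels = 0:(n_cols - 1L)))
      m <- matrix(as.integer(tab), nrow = n_rows, ncol = n_cols)
    }
    m
  })
  names(counts) <- classes
  structure(list(fov_id = window$fov_id, origin = c(x0, y0),
                 square_size_um = s, n_rows = n_rows, n_cols = n_cols,
                 counts = counts),
            class = "grid_counts")
}

#' @export
print.grid_counts <- function(x, ...) {
  cat(sprintf("<grid_counts> %s: %d x %d squares of %.6g um, classes: %s\n",
              x$fov_id, x$n_rows, x$n_cols, x$square_size_um,
              paste(names(x$counts), collapse = ", ")))
  invisible(x)
}

grid_class_matrix <- function(grid, class) {
  m <- grid$counts[[class]]
  if (is.null(m))
    stop("class '", class, "' not counted on this grid", call. = FALSE)
  m
}

#' Seed squares of an aggregate
#'
#' Squares whose count is strictly greater than the `seed_percentile`
#' quantile (linear interpolation, zeros included) of the per-square count
#' distribution of the class.
#'
#' @param grid A [grid_counts()] result.
#' @param class Class label.
#' @param cfg A [caa_config()].
#' @return Data frame of seed squares with columns `row`, `col` (0-based).
#' @export
seed_squares <- function(grid, class, cfg = caa_config()) {
  m <- grid_class_matrix(grid, class)
  q <- stats::quantile(as.numeric(m), probs = cfg$seed_percentile / 100,
                       type = 7, names = FALSE)
  idx <- which(m > q, arr.ind = TRUE)
  data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L)
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = rep(-1:1, each = 3L), dc = rep(-1:1, 3L))[-5L, , drop = FALSE]
}

resolve_cutoff <- function(m, cfg) {
  if (identical(cfg$growth_cutoff, "auto")) {
    nz <- m[m > 0]
    if (!length(nz)) return(NULL)
    stats::median(nz)
  } else cfg$growth_cutoff
}

#' Grow aggregates from seed squares
#'
#' Layer-wise region growing: starting from each seed square, adjacent
#' squares (8- or 4-connectivity) holding at least `growth_cutoff` cells
#' are absorbed, one layer at a time, until no adjacent square qualifies.
#' Growing aggregates that come to share squares are merged, so the result
#' is independent of seed processing order. Seeds are always retained even
#' when their own count is below the cutoff.
#'
#' @param grid A [grid_counts()] result.
#' @param class Class label.
#' @param cfg A [caa_config()].
#' @param seeds Optional seed data frame (default [seed_squares()]).
#' @return List of `aggregate` objects; each carries the class, member
#'   squares, the region geometry ([square_region]) and its exact area.
#' @export
grow_aggregates <- function(grid, class, cfg = caa_config(), seeds = NULL) {
  m <- grid_class_matrix(grid, class)
  if (is.null(seeds)) seeds <- seed_squares(grid, class, cfg)
  if (!nrow(seeds)) return(list())
  cutoff <- resolve_cutoff(m, cfg)
  if (is.null(cutoff)) return(list())

  nr <- grid$n_rows; nc <- grid$n_cols
  qualified <- m >= cutoff
  offs <- neighbor_offsets(cfg$connectivity)

  # growth only ever absorbs squares holding >= cutoff cells, so each
  # seed's aggregate is its seed square plus every connected component of
  # qualified squares it touches; aggregates sharing squares merge
  comp <- matrix(0L, nr, nc)
  n_comp <- 0L
  for (start in which(qualified)) {
    if (comp[start] != 0L) next
    n_comp <- n_comp + 1L
    queue <- start
    comp[start] <- n_comp
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        idx <- (cc - 1L) * nr + rr
        if (qualified[idx] && comp[idx] == 0L) {
          comp[idx] <- n_comp
          queue <- c(queue, idx)
        }
      }
    }
  }
  # components reached by each seed (its own, or adjacent ones if the seed
  # square itself is below the cutoff)
  seed_comps <- lapply(seq_len(nrow(seeds)), function(i) {
    r <- seeds$row[i] + 1L; c <- seeds$col[i] + 1L
    if (qualified[r, c]) return(comp[r, c])
    touched <- integer()
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      if (qualified[rr, cc]) touched <- c(touched, comp[rr, cc])
    }
    unique(touched)
  })
  # union-find over seeds: seeds sharing any component share squares
  parent <- seq_len(nrow(seeds))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(seeds))) for (j in seq_len(i - 1L)) {
    if (length(intersect(seed_comps[[i]], seed_comps[[j]])))
      parent[find(i)] <- find(j)
  }
  groups <- split(seq_len(nrow(seeds)),
                  vapply(seq_len(nrow(seeds)), find, integer(1)))
  lapply(unname(groups), function(g) {
    comp_ids <- unique(unlist(seed_comps[g]))
    member <- comp %in% comp_ids & comp > 0L
    sq <- which(matrix(member, nr, nc), arr.ind = TRUE)
    rows <- c(sq[, 1] - 1L, seeds$row[g])
    cols <- c(sq[, 2] - 1L, seeds$col[g])
    keep <- !duplicated(cbind(rows, cols))
    region <- square_region(rows[keep], cols[keep],
                            origin = grid$origin,
                            square_size = grid$square_size_um)
    structure(list(class = class, fov_id = grid$fov_id,
                   squares = data.frame(row = as.integer(rows[keep]),
                                        col = as.integer(cols[keep]),
                                        row.names = NULL),
                   region = region,
                   area_um2 = region_area(region),
                   growth_cutoff = cutoff),
              class = "aggregate")
  })
}

#' @export
print.aggregate <- function(x, ...) {
  cat(sprintf("<aggregate> %s (%s): %d square(s), %.6g um^2\n",
              x$class, x$fov_id, n_squares(x$region), x$area_um2))
  invisible(x)
}

#' Fill polygon outlines of aggregates
#'
#' Computes each aggregate's polygon (boundary rings with holes, multi-part
#' allowed) and its WKT string from its member squares; areas stay exactly
#' `n_squares * square_size^2`.
#'
#' @param aggs List of aggregates from [grow_aggregates()].
#' @return The list with `polygon` (see [region_polygons()]) and `wkt`
#'   elements filled in.
#' @export
aggregates_to_polygons <- function(aggs) {
  lapply(aggs, function(a) {
    a$polygon <- region_polygons(a$region)
    a$wkt <- region_to_wkt(a$region)
    a
  })
}

#' Per-class FOV aggregate: union of all grown components
#'
#' @param aggs List of aggregates of one class on one grid.
#' @param grid The [grid_counts()] the aggregates came from (used when
#'   `aggs` is empty to produce an empty region on the right grid).
#' @return A `square_region` containing all member squares.
#' @export
class_region <- function(aggs, grid = NULL) {
  if (!length(aggs)) {
    if (is.null(grid)) stop("empty aggregate list needs the grid", call. = FALSE)
    return(square_region(integer(), integer(), grid$origin, grid$square_size_um))
  }
  out <- aggs[[1]]$region
  for (a in aggs[-1]) out <- region_union(out, a$region)
  out
}

#' Infiltration area: intersection of tumor and T-cell aggregates
#'
#' The T-cell infiltration area (IA) of an FOV is the intersection of the
#' union of tumor aggregates with the union of CD3+ aggregates on the same
#' grid. The infiltration fraction is the IA area divided by the total
#' tumor aggregate area (`NA` when no tumor aggregate exists).
#'
#' @param tumor_aggs Aggregates of the tumor class (one FOV).
#' @param cd3_aggs Aggregates of the CD3+ class (same FOV and grid).
#' @param grid The shared [grid_counts()].
#' @return An `infiltration_area`: IA region/polygon/WKT, its area, the
#'   tumor area, and the infiltration fraction.
#' @export
infiltration_areas <- function(tumor_aggs, cd3_aggs, grid) {
  fovs <- unique(c(vapply(tumor_aggs, `[[`, character(1), "fov_id"),
                   vapply(cd3_aggs, `[[`, character(1), "fov_id"),
                   grid$fov_id))
  if (length(fovs) > 1L)
    stop("aggregates come from different FOVs: ",
         paste(fovs, collapse = ", "), call. = FALSE)
  tumor_region <- class_region(tumor_aggs, grid)
  cd3_region <- class_region(cd3_aggs, grid)
  ia_region <- region_intersect(tumor_region, cd3_region)
  tumor_area <- region_area(tumor_region)
  ia_area <- region_area(ia_region)
  structure(list(fov_id = grid$fov_id,
                 region = ia_region,
                 polygon = region_polygons(ia_region),
                 wkt = region_to_wkt(ia_region),
                 area_um2 = ia_area,
                 tumor_area_um2 = tumor_area,
                 cd3_area_um2 = region_area(cd3_region),
                 infiltration_fraction =
                   if (tumor_area > 0) ia_area / tumor_area else NA_real_),
            class = "infiltration_area")
}

#' @export
print.infiltration_area <- function(x, ...) {
  cat(sprintf("<infiltration_area> %s: %.6g um^2 (tumor %.6g), fraction %s\n",
              x$fov_id, x$area_um2, x$tumor_area_um2,
              format(x$infiltration_fraction, digits = 4)))
  invisible(x)
}

#' Cells whose centroid lies in a region
#'
#' Boundary-inclusive: a centroid exactly on a region edge counts as
#' inside, so `cells_in_region` and its complement partition the table.
#'
#' @param cells A [cell_table].
#' @param region A `square_region` (e.g. an aggregate's or IA's `region`).
#' @param invert Return the cells outside instead.
#' @return The subset [cell_table].
#' @export
cells_in_region <- function(cells, region, invert = FALSE) {
  inside <- points_in_region(cells$x, cells$y, region)
  cells[if (invert) !inside else inside, , drop = FALSE]
}

#' Per-FOV aggregate/IA summary table
#'
#' @param aggs_by_class Named list (class -> list of aggregates) for one
#'   FOV.
#' @param ia Optional [infiltration_areas()] result for the FOV.
#' @return Data frame with one row per class (plus `"IA"`): fov_id, class,
#'   n_squares, area_um2, wkt, infiltration_fraction (IA row only).
#' @export
aggregate_summary <- function(aggs_by_class, ia = NULL) {
  rows <- lapply(names(aggs_by_class), function(cl) {
    aggs <- aggs_by_class[[cl]]
    if (!length(aggs)) return(NULL)
    region <- class_region(aggs)
    data.frame(fov_id = aggs[[1]]$fov_id, class = cl,
               n_squares = n_squares(region),
               area_um2 = region_area(region),
               wkt = region_to_wkt(region),
               infiltration_fraction = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(ia)) {
    out <- rbind(out, data.frame(
      fov_id = ia$fov_id, class = "IA",
      n_squares = n_squares(ia$region),
      area_um2 = ia$area_um2, wkt = ia$wkt,
      infiltration_fraction = ia$infiltration_fraction,
      stringsAsFactors = FALSE))
  }
  out
}
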