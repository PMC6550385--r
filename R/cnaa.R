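#' Cell neighborhood analysis configuration
#'
#' The neighborhood analysis visits every cell of the chosen center
#' classes, draws a circular neighborhood of radius `radius_um` around it,
#' counts the cells of each counted class inside (the center itself
#' excluded, boundary inclusive), and measures the nearest-neighbor
#' distance (NND) from the center to each requested target class within
#' the neighborhood. Scanning neighborhood sizes from 2 to 50 microns on
#' tumor-lymphocyte data identified 12 microns as the informative default
#' radius.
#'
#' @param radius_um Neighborhood radius in microns (default 12).
#' @param center_classes Labels whose cells anchor neighborhoods.
#' @param counted_classes Labels counted inside neighborhoods; default all
#'   labels present in the table.
#' @param nnd_pairs List of `c(center_class, target_class)` pairs for which
#'   NND is recorded; default every (center, counted) combination.
#' @param bounded If `TRUE` (default) NND is missing when no target lies
#'   within the radius; if `FALSE` the global nearest neighbor distance is
#'   reported as a diagnostic.
#' @return An `nbhd_config`.
#' @export
nbhd_config <- function(radius_um = 12, center_classes = "CD3",
                        counted_classes = NULL, nnd_pairs = NULL,
                        bounded = TRUE) {
  stopifnot(radius_um > 0)
  structure(list(radius_um = radius_um,
                 center_classes = center_classes,
                 counted_classes = counted_classes,
                 nnd_pairs = nnd_pairs,
                 bounded = isTRUE(bounded)),
            class = "nbhd_config")
}

# fixed-radius neighbor search by grid bucketing: returns, for each query
# point, the indices of data points within radius (inclusive)
radius_neighbors <- function(qx, qy, px, py, radius) {
  nq <- length(qx)
  if (!length(px)) return(rep(list(integer()), nq))
  s <- radius
  x0 <- min(c(qx, px)); y0 <- min(c(qy, py))
  bx <- floor((px - x0) / s); by <- floor((py - y0) / s)
  bucket <- split(seq_along(px), paste(bx, by))
  qbx <- floor((qx - x0) / s); qby <- floor((qy - y0) / s)
  r2 <- radius^2
  out <- vector("list", nq)
  for (i in seq_len(nq)) {
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(qbx[i] + dx, qby[i] + dy)
      b <- bucket[[key]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    if (length(cand)) {
      d2 <- (px[cand] - qx[i])^2 + (py[cand] - qy[i])^2
      cand <- cand[d2 <= r2]
    }
    out[[i]] <- cand
  }
  out
}

#' Per-cell neighborhood composition and nearest-neighbor distances
#'
#' One record per center-class cell: counts of every counted class within
#' the circular neighborhood (Euclidean distance at most the radius,
#' center excluded) and the NND from the center to each target class of
#' the configured pairs (`NA` when no target lies within the radius).
#'
#' @param cells A [cell_table] in microns with phenotypes assigned (and
#'   HLA-1 status called if tumor subclasses are wanted).
#' @param cfg An [nbhd_config()].
#' @param class_of Per-cell class labels; default [cell_classes()].
#' @return A `nbhd_records` data frame: `cell_id`, `fov_id`, `sample_id`,
#'   `class`, `x`, `y`, `region` (`NA` until [tag_regions()]), one
#'   `n_<class>` column per counted class and one `nnd_<target>` column
#'   per NND target.
#' @export
neighborhoods <- function(cells, cfg = nbhd_config(), class_of = NULL) {
  stopifnot(inherits(cfg, "nbhd_config"))
  if (is.null(class_of)) class_of <- cell_classes(cells)
  stopifnot(length(class_of) == nrow(cells))
  counted <- cfg$counted_classes
  if (is.null(counted)) counted <- sort(unique(class_of))
  pairs <- cfg$nnd_pairs
  if (is.null(pairs))
    pairs <- unlist(lapply(cfg$center_classes, function(cc)
      lapply(counted, function(tc) c(cc, tc))), recursive = FALSE)
  targets_of <- function(center_class)
    unique(vapply(Filter(function(p) p[1] == center_class, pairs),
                  `[`, character(1), 2L))

  res <- list()
  for (f in unique(cells$fov_id)) {
    in_f <- cells$fov_id == f
    sub <- cells[in_f, , drop = FALSE]
    cls <- class_of[in_f]
    centers <- which(cls %in% cfg$center_classes)
    if (!length(centers)) next
    nbrs <- radius_neighbors(sub$x[centers], sub$y[centers],
                             sub$x, sub$y, cfg$radius_um)
    rec <- data.frame(cell_id = sub$cell_id[centers],
                      fov_id = sub$fov_id[centers],
                      sample_id = sub$sample_id[centers],
                      class = cls[centers],
                      x = sub$x[centers], y = sub$y[centers],
                      region = NA_character_,
                      stringsAsFactors = FALSE)
    for (cl in counted) rec[[paste0("n_", cl)]] <- 0L
    all_targets <- unique(vapply(pairs, `[`, character(1), 2L))
    for (tc in all_targets) rec[[paste0("nnd_", tc)]] <- NA_real_
    for (i in seq_along(centers)) {
      ci <- centers[i]
      nb <- setdiff(nbrs[[i]], ci)
      nb_cls <- cls[nb]
      for (cl in counted)
        rec[[paste0("n_", cl)]][i] <- sum(nb_cls == cl)
      for (tc in targets_of(cls[ci])) {
        tsel <- nb[nb_cls == tc]
        if (length(tsel)) {
          d <- sqrt((sub$x[tsel] - sub$x[ci])^2 + (sub$y[tsel] - sub$y[ci])^2)
          rec[[paste0("nnd_", tc)]][i] <- min(d)
        } else if (!cfg$bounded) {
          tall <- which(cls == tc & seq_along(cls) != ci)
          if (length(tall)) {
            d <- sqrt((sub$x[tall] - sub$x[ci])^2 + (sub$y[tall] - sub$y[ci])^2)
            rec[[paste0("nnd_", tc)]][i] <- min(d)
          }
        }
      }
    }
    res[[length(res) + 1L]] <- rec
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(cell_id = character(), fov_id = character(),
               sample_id = character(), class = character(),
               x = numeric(), y = numeric(), region = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, radius_um = cfg$radius_um,
            class = c("nbhd_records", "data.frame"))
}

#' Tag neighborhood records by region (inside/outside infiltration areas)
#'
#' Sets each record's `region` to `"inside_IA"` or `"outside_IA"` by a
#' boundary-inclusive point-in-region test of the center cell against the
#' FOV's infiltration area.
#'
#' @param records A [neighborhoods()] result.
#' @param ias Named list of [infiltration_areas()] results, one per FOV
#'   (names = FOV ids), or a single `infiltration_area`.
#' @return The records with `region` filled for the covered FOVs.
#' @export
tag_regions <- function(records, ias) {
  if (inherits(ias, "infiltration_area"))
    ias <- stats::setNames(list(ias), ias$fov_id)
  for (f in names(ias)) {
    ia <- ias[[f]]
    if (!identical(as.character(ia$fov_id), f))
      stop("FOV mismatch: list name '", f, "' vs infiltration area '",
           ia$fov_id, "'", call. = FALSE)
    sel <- records$fov_id == f
    if (!any(sel)) next
    inside <- points_in_region(records$x[sel], records$y[sel], ia$region)
    records$region[sel] <- ifelse(inside, "inside_IA", "outside_IA")
  }
  records
}

#' Summarize nearest-neighbor distances
#'
#' Two-stage average matching the usual per-field reporting: the per-cell
#' NNDs are first averaged within each FOV, then averaged (unweighted)
#' across FOVs. The per-FOV table and a cell-weighted overall mean are
#' also returned, since both weightings are found in practice.
#'
#' @param records A (typically region-tagged) [neighborhoods()] result.
#' @param targets Target classes to summarize; default every `nnd_`
#'   column.
#' @param by Extra grouping columns among `sample_id`, `region`, `class`
#'   (default `"region"` when tagged).
#' @return List with `per_fov` (one row per FOV x group x target: n cells
#'   with an NND, FOV mean) and `overall` (per group x target: number of
#'   contributing FOVs, FOV-weighted mean, cell-weighted mean).
#' @export
summarize_nnd <- function(records, targets = NULL, by = NULL) {
  nnd_cols <- grep("^nnd_", names(records), value = TRUE)
  if (is.null(targets)) targets <- sub("^nnd_", "", nnd_cols)
  if (is.null(by)) by <- if (any(!is.na(records$region))) "region" else character()
  groups_of <- function(df) {
    if (!length(by)) rep("all", nrow(df)) else
      do.call(paste, c(lapply(by, function(b) df[[b]]), sep = "|"))
  }
  per_fov <- list(); overall <- list()
  grp <- groups_of(records)
  for (tc in targets) {
    col <- paste0("nnd_", tc)
    v <- records[[col]]
    for (g in unique(grp)) {
      sel_g <- grp == g
      fovs <- unique(records$fov_id[sel_g])
      fov_means <- c(); fov_ns <- c()
      for (f in fovs) {
        sel <- sel_g & records$fov_id == f
        vv <- v[sel]
        n_ok <- sum(!is.na(vv))
        per_fov[[length(per_fov) + 1L]] <- data.frame(
          group = g, fov_id = f, target = tc, n = n_ok,
          mean_nnd = if (n_ok) mean(vv, na.rm = TRUE) else NA_real_,
          stringsAsFactors = FALSE)
        if (n_ok) { fov_means <- c(fov_means, mean(vv, na.rm = TRUE))
                    fov_ns <- c(fov_ns, n_ok) }
      }
      all_v <- v[sel_g]
      overall[[length(overall) + 1L]] <- data.frame(
        group = g, target = tc,
        n_fovs = length(fov_means),
        n_cells = sum(!is.na(all_v)),
        mean_nnd_fov_weighted = if (length(fov_means)) mean(fov_means) else NA_real_,
        mean_nnd_cell_weighted = if (any(!is.na(all_v)))
          mean(all_v, na.rm = TRUE) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(per_fov = do.call(rbind, per_fov), overall = do.call(rbind, overall))
}

#' Per-neighborhood composition ratios
#'
#' For each group of neighborhood records (default: FOV x region), sums the
#' per-neighborhood class counts and forms ratios of each class's total to
#' the total tumor-cell count in the neighborhoods, the per-tumor-cell
#' composition of the average neighborhood.
#'
#' @param records A [neighborhoods()] result.
#' @param tumor_classes Labels summed as the tumor denominator.
#' @param by Grouping columns (default `c("fov_id", "region")` when tagged,
#'   else `"fov_id"`).
#' @return Data frame of groups x classes with summed counts and ratios
#'   (ratio `NA` when the tumor denominator is 0).
#' @export
neighborhood_composition <- function(records,
                                     tumor_classes = c("Tumor_HLA1pos", "Tumor_HLA1neg"),
                                     by = NULL) {
  count_cols <- grep("^n_", names(records), value = TRUE)
  classes <- sub("^n_", "", count_cols)
  if (is.null(by))
    by <- if (any(!is.na(records$region))) c("fov_id", "region") else "fov_id"
  key <- do.call(paste, c(lapply(by, function(b) records[[b]]), sep = "|"))
  out <- list()
  for (g in unique(key)) {
    sel <- key == g
    sums <- vapply(count_cols, function(cc) sum(records[[cc]][sel]), numeric(1))
    names(sums) <- classes
    denom <- sum(sums[intersect(tumor_classes, classes)])
    keyvals <- strsplit(g, "|", fixed = TRUE)[[1]]
    row <- as.data.frame(stats::setNames(as.list(keyvals), by),
                         stringsAsFactors = FALSE)
    row$n_neighborhoods <- sum(sel)
    for (cl in classes) {
      row[[paste0("count_", cl)]] <- sums[[cl]]
      row[[paste0("ratio_", cl, "_per_tumor")]] <-
        if (denom > 0) sums[[cl]] / denom else NA_real_
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
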