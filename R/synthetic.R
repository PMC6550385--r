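#' Synthetic FOV configuration
#'
#' Describes one simulated field of view: clustered tumor nests with a
#' mixed HLA-1 positive/negative tumor population, plus immune cells of
#' the CD3 / CD8+PD1+ / CD20 / CD4+FOXP3+ classes, in a rectangular window
#' in microns. T cells (CD3 and CD8PD1) can be attracted toward HLA-1+
#' tumor cells: with mixture weight `attraction / (1 + attraction)` a T
#' cell is placed at a Gaussian displacement (scale `attraction_sigma_um`)
#' from a random HLA-1+ tumor cell, otherwise uniformly in the window;
#' `attraction = 0` gives complete spatial randomness. Marker intensities
#' follow a lognormal positive-vs-background model with wide separation,
#' so rule-based phenotyping recovers the true labels with a small, known
#' error rate. A `qc_noise` fraction of cells receives failing QC values
#' so QC filtering is exercised end to end.
#'
#' Default geometry and abundances describe a realistic 20x-objective
#' melanoma lymph-node FOV: a 600x600 micron window, two tumor nests of
#' ~120 micron radius with 400 cells each, a 60% HLA-1+ tumor fraction,
#' and a few hundred immune cells per class.
#'
#' @param window_um Window extents `c(width, height)` in microns.
#' @param n_clusters Number of circular tumor nests.
#' @param cluster_radius_um Nest radius (recycled over nests).
#' @param cells_per_cluster Tumor cells per nest (recycled).
#' @param hla1pos_fraction Fraction of each nest's tumor cells that are
#'   truly HLA-1 positive (recycled; in \[0,1\]).
#' @param n_immune Named counts of immune cells per class.
#' @param attraction Nonnegative T-cell attraction strength (see above).
#' @param attraction_sigma_um Displacement kernel scale in microns.
#' @param qc_noise Fraction of cells given failing QC values.
#' @param intensity_pos,intensity_neg Lognormal `c(meanlog, sdlog)` of
#'   positive-marker and background intensities.
#' @param cluster_centers Optional matrix of nest centers; default drawn
#'   uniformly with the nest fully inside the window.
#' @param fov_id,sample_id Identifiers stamped on the cells.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(window_um = c(600, 600),
                             n_clusters = 2L,
                             cluster_radius_um = 120,
                             cells_per_cluster = 400L,
                             hla1pos_fraction = 0.6,
                             n_immune = c(CD3 = 200L, CD8PD1 = 80L,
                                          CD20 = 100L, CD4FOXP3 = 60L),
                             attraction = 0,
                             attraction_sigma_um = 15,
                             qc_noise = 0.05,
                             intensity_pos = c(meanlog = log(500), sdlog = 0.5),
                             intensity_neg = c(meanlog = log(8), sdlog = 0.5),
                             cluster_centers = NULL,
                             fov_id = "FOV1", sample_id = "S1") {
  stopifnot(all(window_um > 0), n_clusters >= 0,
            all(hla1pos_fraction >= 0), all(hla1pos_fraction <= 1),
            all(cells_per_cluster >= 0), attraction >= 0,
            attraction_sigma_um > 0, qc_noise >= 0, qc_noise <= 1)
  if (n_clusters > 0 && any(2 * cluster_radius_um > min(window_um)))
    stop("cluster diameter exceeds the window", call. = FALSE)
  structure(list(window_um = window_um, n_clusters = as.integer(n_clusters),
                 cluster_radius_um = rep_len(cluster_radius_um, max(1L, n_clusters)),
                 cells_per_cluster = rep_len(as.integer(cells_per_cluster),
                                             max(1L, n_clusters)),
                 hla1pos_fraction = rep_len(hla1pos_fraction, max(1L, n_clusters)),
                 n_immune = n_immune, attraction = attraction,
                 attraction_sigma_um = attraction_sigma_um,
                 qc_noise = qc_noise,
                 intensity_pos = intensity_pos, intensity_neg = intensity_neg,
                 cluster_centers = cluster_centers,
                 fov_id = fov_id, sample_id = sample_id),
            class = "synthetic_config")
}

SYN_MARKERS <- c("S100", "HLA1", "CD3", "CD8", "PD1", "CD20", "CD4", "FOXP3")

rlnorm2 <- function(n, par) stats::rlnorm(n, meanlog = par[[1]], sdlog = par[[2]])

# markers truly expressed by each synthetic class (drives intensity draws)
syn_positive_markers <- function(class, hla_pos) {
  switch(class,
    Tumor = c("S100", if (hla_pos) "HLA1"),
    CD3 = c("CD3", "CD4", "HLA1"),
    CD8PD1 = c("CD3", "CD8", "PD1", "HLA1"),
    CD20 = c("CD20", "HLA1"),
    CD4FOXP3 = c("CD3", "CD4", "FOXP3", "HLA1"),
    character())
}

#' Generate one synthetic FOV with ground truth
#'
#' Places tumor cells uniformly within circular nests (HLA-1 status i.i.d.
#' per nest fraction), immune cells uniformly or attracted to HLA-1+ tumor
#' cells (T-cell classes only), draws marker intensities from the
#' lognormal positive/background model, and attaches passing QC values to
#' all cells except a designated `qc_noise` fraction, which get exactly
#' one failing QC value each. Fully reproducible from the seed.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @return List with `cells` (a [cell_table] in microns), and `truth`
#'   (ground truth: per-cell true class and HLA status, nest centers and
#'   radii, the attraction used, the planted-square helper
#'   [planted_squares()] inputs, and the indices of QC-failing cells).
#' @export
generate_fov <- function(cfg = synthetic_config(), seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  W <- cfg$window_um[1]; H <- cfg$window_um[2]
  # tumor nests
  centers <- cfg$cluster_centers
  if (cfg$n_clusters > 0 && is.null(centers)) {
    r <- cfg$cluster_radius_um
    centers <- cbind(stats::runif(cfg$n_clusters, r, W - r),
                     stats::runif(cfg$n_clusters, r, H - r))
  }
  xs <- ys <- numeric(0); true_class <- character(0); true_hla <- logical(0)
  cluster_id <- integer(0)
  if (cfg$n_clusters > 0) {
    for (k in seq_len(cfg$n_clusters)) {
      n <- cfg$cells_per_cluster[k]
      if (!n) next
      rad <- cfg$cluster_radius_um[k] * sqrt(stats::runif(n))
      ang <- stats::runif(n, 0, 2 * pi)
      xs <- c(xs, pmin(pmax(centers[k, 1] + rad * cos(ang), 0), W))
      ys <- c(ys, pmin(pmax(centers[k, 2] + rad * sin(ang), 0), H))
      true_class <- c(true_class, rep("Tumor", n))
      true_hla <- c(true_hla, stats::runif(n) < cfg$hla1pos_fraction[k])
      cluster_id <- c(cluster_id, rep(k, n))
    }
  }
  hla_pos_idx <- which(true_class == "Tumor" & true_hla)
  # immune cells
  w_attr <- cfg$attraction / (1 + cfg$attraction)
  for (cl in names(cfg$n_immune)) {
    n <- cfg$n_immune[[cl]]
    if (!n) next
    t_cell <- cl %in% c("CD3", "CD8PD1")
    attracted <- t_cell & length(hla_pos_idx) > 0 &
      stats::runif(n) < w_attr
    x <- stats::runif(n, 0, W); y <- stats::runif(n, 0, H)
    na <- sum(attracted)
    if (na) {
      anchor <- sample(hla_pos_idx, na, replace = TRUE)
      x[attracted] <- pmin(pmax(xs[anchor] +
        stats::rnorm(na, 0, cfg$attraction_sigma_um), 0), W)
      y[attracted] <- pmin(pmax(ys[anchor] +
        stats::rnorm(na, 0, cfg$attraction_sigma_um), 0), H)
    }
    xs <- c(xs, x); ys <- c(ys, y)
    true_class <- c(true_class, rep(cl, n))
    true_hla <- c(true_hla, rep(NA, n))
    cluster_id <- c(cluster_id, rep(0L, n))
  }

  n_cells <- length(xs)
  df <- data.frame(cell_id = sprintf("%s_c%05d", cfg$fov_id, seq_len(n_cells)),
                   fov_id = cfg$fov_id, sample_id = cfg$sample_id,
                   x = xs, y = ys, stringsAsFactors = FALSE)
  # marker intensities: background everywhere, then redraw the truly
  # expressed markers per class from the positive distribution
  for (m in SYN_MARKERS) df[[m]] <- rlnorm2(n_cells, cfg$intensity_neg)
  for (cl in unique(true_class)) {
    idx <- which(true_class == cl)
    pos <- syn_positive_markers(cl, hla_pos = FALSE)
    for (m in pos) df[[m]][idx] <- rlnorm2(length(idx), cfg$intensity_pos)
    if (cl == "Tumor") {
      idx_hla <- which(true_class == "Tumor" & true_hla)
      df$HLA1[idx_hla] <- rlnorm2(length(idx_hla), cfg$intensity_pos)
    }
  }
  # QC values: all passing, then a designated fraction made failing
  df$qc_alignment <- stats::runif(n_cells, 0.85, 1)
  df$px_nucleus <- 10L + stats::rpois(n_cells, 40)
  df$px_membrane <- 10L + stats::rpois(n_cells, 60)
  df$px_cytoplasm <- 10L + stats::rpois(n_cells, 80)
  df$n_nuclei <- 1L + stats::rbinom(n_cells, 1L, 0.2)
  n_fail <- round(cfg$qc_noise * n_cells)
  fail_idx <- if (n_fail) sort(sample.int(n_cells, n_fail)) else integer()
  if (n_fail) {
    mode <- sample(3L, n_fail, replace = TRUE)
    df$qc_alignment[fail_idx[mode == 1L]] <-
      stats::runif(sum(mode == 1L), 0, 0.849)
    df$px_nucleus[fail_idx[mode == 2L]] <-
      sample(0:9, sum(mode == 2L), replace = TRUE)
    df$n_nuclei[fail_idx[mode == 3L]] <-
      sample(3:5, sum(mode == 3L), replace = TRUE)
  }

  cells <- new_cell_table(df, unit = "um", markers = SYN_MARKERS)
  truth <- list(true_class = true_class,
                true_hla = ifelse(is.na(true_hla), NA_character_,
                                  ifelse(true_hla, "HLA1pos", "HLA1neg")),
                cluster_id = cluster_id,
                cluster_centers = centers,
                cluster_radius_um = if (cfg$n_clusters > 0) cfg$cluster_radius_um else numeric(),
                attraction = cfg$attraction,
                qc_fail_idx = fail_idx,
                window_um = cfg$window_um,
                seed = seed)
  list(cells = cells, truth = truth)
}

#' Ground-truth grid squares covered by planted tumor nests
#'
#' The squares (on a grid anchored at the window origin) whose center lies
#' inside at least one planted nest disc: the reference square set against
#' which aggregate recovery is scored (e.g. by Jaccard index).
#'
#' @param truth The `truth` element of [generate_fov()].
#' @param square_size_um Grid square size.
#' @return Data frame of `row`, `col` (0-based) ground-truth squares.
#' @export
planted_squares <- function(truth, square_size_um = 50) {
  W <- truth$window_um[1]; H <- truth$window_um[2]
  n_cols <- max(1L, ceiling(W / square_size_um - 1e-9))
  n_rows <- max(1L, ceiling(H / square_size_um - 1e-9))
  grid <- expand.grid(row = 0:(n_rows - 1L), col = 0:(n_cols - 1L))
  cx <- (grid$col + 0.5) * square_size_um
  cy <- (grid$row + 0.5) * square_size_um
  centers <- truth$cluster_centers
  if (is.null(centers) || !nrow(centers))
    return(grid[0, , drop = FALSE])
  covered <- rep(FALSE, nrow(grid))
  for (k in seq_len(nrow(centers))) {
    covered <- covered |
      (cx - centers[k, 1])^2 + (cy - centers[k, 2])^2 <=
        truth$cluster_radius_um[k]^2
  }
  grid[covered, , drop = FALSE]
}

#' Jaccard index of two square sets
#' @param a,b Data frames with `row`, `col` columns.
#' @return Intersection over union (1 when both empty).
#' @export
square_jaccard <- function(a, b) {
  ka <- paste(a$row, a$col); kb <- paste(b$row, b$col)
  u <- union(ka, kb)
  if (!length(u)) return(1)
  length(intersect(ka, kb)) / length(u)
}

#' Generate a multi-sample synthetic cohort
#'
#' Builds brisk samples (strong T-cell attraction, T-cell-rich) and
#' non-brisk samples (weak attraction, T-cell-poor) of several FOVs each,
#' mirroring densely vs sparsely infiltrated tumors. Per-FOV seeds are
#' derived deterministically from `seed`.
#'
#' @param n_brisk,n_nonbrisk Number of samples per group.
#' @param fovs_per_sample FOVs per sample.
#' @param seed Master seed.
#' @param brisk_config,nonbrisk_config Template [synthetic_config()]s; the
#'   defaults differ in attraction (6 vs 0.5) and CD3 abundance (400 vs
#'   120 cells).
#' @return List with `cells` (row-bound [cell_table] of the cohort),
#'   `truths` (per-FOV ground truth, named by FOV id), and `design` (data
#'   frame: sample_id, fov_id, group).
#' @export
generate_cohort <- function(n_brisk = 2L, n_nonbrisk = 2L,
                            fovs_per_sample = 10L, seed = 1L,
                            brisk_config = NULL, nonbrisk_config = NULL) {
  if (is.null(brisk_config))
    brisk_config <- synthetic_config(attraction = 6,
                                     n_immune = c(CD3 = 400L, CD8PD1 = 120L,
                                                  CD20 = 80L, CD4FOXP3 = 50L))
  if (is.null(nonbrisk_config))
    nonbrisk_config <- synthetic_config(attraction = 0.5,
                                        n_immune = c(CD3 = 120L, CD8PD1 = 40L,
                                                     CD20 = 120L, CD4FOXP3 = 80L))
  cells_list <- list(); truths <- list(); design <- list()
  samples <- c(sprintf("brisk%d", seq_len(n_brisk)),
               sprintf("nonbrisk%d", seq_len(n_nonbrisk)))
  groups <- rep(c("brisk", "nonbrisk"), c(n_brisk, n_nonbrisk))
  fov_counter <- 0L
  for (si in seq_along(samples)) {
    template <- if (groups[si] == "brisk") brisk_config else nonbrisk_config
    for (fi in seq_len(fovs_per_sample)) {
      fov_counter <- fov_counter + 1L
      cfg <- template
      cfg$fov_id <- sprintf("%s_FOV%02d", samples[si], fi)
      cfg$sample_id <- samples[si]
      fov_seed <- (seed * 10007L + fov_counter * 97L) %% 2147483647L
      out <- generate_fov(cfg, seed = fov_seed)
      cells_list[[length(cells_list) + 1L]] <- as.data.frame(out$cells)
      truths[[cfg$fov_id]] <- out$truth
      design[[length(design) + 1L]] <- data.frame(
        sample_id = samples[si], fov_id = cfg$fov_id, group = groups[si],
        stringsAsFactors = FALSE)
    }
  }
  list(cells = new_cell_table(do.call(rbind, cells_list),
                              unit = "um", markers = SYN_MARKERS),
       truths = truths,
       design = do.call(rbind, design))
}

#' Write a synthetic FOV to disk (CSV + ground-truth JSON sidecar)
#'
#' @param fov A [generate_fov()] result.
#' @param csv_path Output CSV path; the sidecar is written next to it with
#'   a `.truth.json` suffix.
#' @return `csv_path`, invisibly.
#' @export
write_synthetic_fov <- function(fov, csv_path) {
  write_cell_table(fov$cells, csv_path)
  truth <- fov$truth
  truth$cluster_centers <- if (!is.null(truth$cluster_centers))
    apply(truth$cluster_centers, 1L, function(r) as.list(r), simplify = FALSE)
  jsonlite::write_json(truth, sub("\\.csv$", ".truth.json", csv_path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csv_path)
}
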