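#' Per-FOV cell-count ratio metrics
#'
#' Counts the cells of each class per FOV (optionally restricted to a
#' region such as an infiltration area) and forms the standard ratio panel:
#' HLA-1+ tumor cells / all tumor cells, CD3+ / tumor, CD8+PD1+ / tumor,
#' CD20+ / all immune cells, CD4+FOXP3+ / all immune cells. Denominators
#' are configurable per ratio; a ratio with a zero denominator is missing
#' (`NA`), never infinite.
#'
#' @param cells A phenotyped, HLA-called [cell_table].
#' @param regions Optional named list (FOV id -> `square_region`)
#'   restricting the counts to that region per FOV.
#' @param ratios Named list defining the ratio panel: each element is
#'   `list(num = <classes>, den = <classes>)`; class sets are summed.
#'   `NULL` uses the default panel above. The special class name
#'   `"Tumor"` expands to both HLA-1 classes, `"Immune"` to the four
#'   immune labels.
#' @param class_of Optional per-cell class label override.
#' @return A `ratio_table` data frame: one row per FOV with `sample_id`,
#'   per-class counts (`count_*`) and the ratio columns.
#' @export
fov_ratios <- function(cells, regions = NULL, ratios = NULL, class_of = NULL) {
  if (is.null(class_of)) class_of <- cell_classes(cells)
  expand <- function(cls) {
    out <- character()
    for (cl in cls) out <- c(out, switch(cl,
      Tumor = c("Tumor", "Tumor_HLA1pos", "Tumor_HLA1neg"),
      Immune = c("CD3", "CD8PD1", "CD20", "CD4FOXP3"),
      cl))
    out
  }
  if (is.null(ratios)) ratios <- list(
    hla1pos_per_tumor = list(num = "Tumor_HLA1pos", den = "Tumor"),
    cd3_per_tumor     = list(num = "CD3",           den = "Tumor"),
    cd8pd1_per_tumor  = list(num = "CD8PD1",        den = "Tumor"),
    cd20_per_immune   = list(num = "CD20",          den = "Immune"),
    cd4foxp3_per_immune = list(num = "CD4FOXP3",    den = "Immune"))
  present <- unique(class_of)
  for (rn in names(ratios)) {
    den <- expand(ratios[[rn]]$den)
    if (!length(intersect(den, c(present, "Tumor", "Tumor_HLA1pos",
                                 "Tumor_HLA1neg", "CD3", "CD8PD1", "CD20",
                                 "CD4FOXP3"))))
      stop("unknown denominator class in ratio '", rn, "'", call. = FALSE)
  }

  fovs <- unique(cells$fov_id)
  classes <- sort(unique(class_of))
  rows <- lapply(fovs, function(f) {
    sel <- cells$fov_id == f
    if (!is.null(regions) && !is.null(regions[[as.character(f)]]))
      sel <- sel & points_in_region(cells$x, cells$y, regions[[as.character(f)]])
    cls <- class_of[sel]
    counts <- vapply(classes, function(cl) sum(cls == cl), numeric(1))
    total <- function(set) sum(counts[intersect(expand(set), classes)])
    row <- data.frame(fov_id = f,
                      sample_id = cells$sample_id[cells$fov_id == f][1],
                      stringsAsFactors = FALSE)
    for (cl in classes) row[[paste0("count_", cl)]] <- counts[[cl]]
    for (rn in names(ratios)) {
      num <- total(ratios[[rn]]$num); den <- total(ratios[[rn]]$den)
      row[[rn]] <- if (den > 0) num / den else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  structure(out, ratio_cols = names(ratios),
            class = c("ratio_table", "data.frame"))
}

#' Pairwise Pearson correlogram of ratio metrics across FOVs
#'
#' For every pair of ratio columns, computes Pearson's r over
#' complete-case FOV rows with a two-sided p-value. Pairs with fewer
#' complete rows than `min_n` are flagged `insufficient_data` (the
#' question-mark cells of a correlogram); pairs with p above `alpha` are
#' flagged `not_significant` (the crossed-out cells); the rest are
#' `significant`.
#'
#' @param ratio_table A [fov_ratios()] result (or any data frame).
#' @param columns Ratio columns to correlate; default the table's ratio
#'   panel.
#' @param alpha Significance cutoff (default 0.05).
#' @param min_n Minimum complete-case rows for a usable estimate (default
#'   3).
#' @return A `correlogram` object: symmetric matrices `r`, `p`, `n` and a
#'   `flag` character matrix.
#' @export
correlogram <- function(ratio_table, columns = NULL, alpha = 0.05, min_n = 3L) {
  if (is.null(columns)) columns <- attr(ratio_table, "ratio_cols", exact = TRUE)
  if (is.null(columns))
    columns <- names(ratio_table)[vapply(ratio_table, is.numeric, logical(1))]
  if (length(columns) < 2L) stop("need at least two ratio columns", call. = FALSE)
  k <- length(columns)
  r <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  p <- r; n <- r
  flag <- matrix("insufficient_data", k, k, dimnames = list(columns, columns))
  for (i in seq_len(k)) for (j in i:k) {
    xi <- ratio_table[[columns[i]]]; xj <- ratio_table[[columns[j]]]
    ok <- !is.na(xi) & !is.na(xj)
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) >= max(min_n, 3L) &&
        stats::sd(xi[ok]) > 0 && stats::sd(xj[ok]) > 0) {
      if (i == j) {
        r[i, j] <- 1; p[i, j] <- 0
      } else {
        ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
      fl <- if (p[i, j] <= alpha) "significant" else "not_significant"
      flag[i, j] <- flag[j, i] <- fl
    }
  }
  structure(list(r = r, p = p, n = n, flag = flag,
                 alpha = alpha, min_n = min_n),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("<correlogram>\n")
  print(round(x$r, 3))
  cat("flags:\n"); print(x$flag)
  invisible(x)
}

#' Correlogram as a long-format data frame
#' @param cg A [correlogram()] result.
#' @return Data frame with columns `var1`, `var2`, `r`, `p`, `n`, `flag`.
#' @export
correlogram_table <- function(cg) {
  cols <- colnames(cg$r)
  out <- expand.grid(var1 = cols, var2 = cols, stringsAsFactors = FALSE)
  out$r <- as.vector(cg$r); out$p <- as.vector(cg$p)
  out$n <- as.vector(cg$n); out$flag <- as.vector(cg$flag)
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean;
#' missing when fewer than two non-missing values or a zero mean.
#'
#' @param values Numeric vector.
#' @return CV, or `NA` when undefined.
#' @export
coefficient_of_variation <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  stats::sd(v) / m
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' Tests association between a binary outcome and a two-level group across
#' strata. Degenerate strata (with an empty group or outcome margin) are
#' dropped with a warning. Continuity correction is off by default.
#'
#' @param outcome Logical/binary outcome per unit (e.g. FOV infiltration
#'   fraction above the cohort median).
#' @param group Two-level group label per unit (e.g. brisk / non-brisk).
#' @param stratum Stratum label per unit (e.g. sample id).
#' @param correct Continuity correction (default `FALSE`, pinned).
#' @return List with `statistic` (CMH chi-square, 1 df), `p_value`,
#'   `n_strata` used.
#' @export
cmh_test <- function(outcome, group, stratum, correct = FALSE) {
  outcome <- as.logical(outcome)
  group <- as.factor(as.character(group))
  stratum <- as.factor(as.character(stratum))
  if (nlevels(group) != 2L)
    stop("group must have exactly two levels", call. = FALSE)
  keep_strata <- character()
  for (s in levels(stratum)) {
    sel <- stratum == s
    tab <- table(factor(outcome[sel], levels = c(FALSE, TRUE)),
                 factor(group[sel], levels = levels(group)))
    # a stratum contributes only if no margin is empty: both groups and
    # both outcome levels must be represented
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      keep_strata <- c(keep_strata, s)
  }
  dropped <- setdiff(levels(stratum), keep_strata)
  if (length(dropped))
    warning("dropping degenerate stratum(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!length(keep_strata))
    stop("no stratum with both groups and both outcomes represented",
         call. = FALSE)
  # CMH chi-square over the 2x2xK array: sum of per-stratum deviations of
  # the (TRUE, group1) cell from its hypergeometric expectation, squared
  # over the summed hypergeometric variance, 1 df
  dev <- 0; varsum <- 0
  for (s in keep_strata) {
    sel <- stratum == s
    tab <- table(factor(outcome[sel], levels = c(TRUE, FALSE)),
                 factor(group[sel], levels = levels(group)))
    n <- sum(tab)
    a <- tab[1, 1]
    e <- sum(tab[1, ]) * sum(tab[, 1]) / n
    v <- prod(rowSums(tab)) * prod(colSums(tab)) / (n^2 * (n - 1))
    dev <- dev + (a - e)
    varsum <- varsum + v
  }
  cc <- if (correct) 0.5 else 0
  statistic <- (abs(dev) - cc)^2 / varsum
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       n_strata = length(keep_strata),
       method = "Cochran-Mantel-Haenszel chi-square (1 df)")
}

#' Welch unequal-variance t test
#'
#' Welch's t statistic with Satterthwaite degrees of freedom and two-sided
#' p-value, as used to compare marker expression levels between groups of
#' cells. When both groups are constant and equal, the p-value is 1 by
#' convention; when both are constant but different, it is 0.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `t`, `df`, `p_value`, and the group means.
#' @export
welch_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two observations", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p_value = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Export a ratio table as a heat-map matrix (CSV + optional figure)
#'
#' Writes the FOV x metric matrix as CSV and, when a figure path is given,
#' renders a heat map with missing values shown in a distinct color (never
#' as zero). Purely presentational.
#'
#' @param ratio_table A [fov_ratios()] result.
#' @param csv_path Output CSV path.
#' @param image_path Optional PNG path.
#' @param columns Metric columns; default the ratio panel.
#' @return The matrix written, invisibly.
#' @export
export_heatmap <- function(ratio_table, csv_path, image_path = NULL,
                           columns = NULL) {
  if (is.null(columns)) columns <- attr(ratio_table, "ratio_cols", exact = TRUE)
  m <- as.matrix(as.data.frame(ratio_table)[, columns, drop = FALSE])
  rownames(m) <- as.character(ratio_table$fov_id)
  utils::write.csv(as.data.frame(m), csv_path, row.names = TRUE)
  if (!is.null(image_path)) {
    grDevices::png(image_path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       na_col = "grey50",
                       main = "Per-FOV ratio metrics")
  }
  invisible(m)
}

#' Read back a heat-map CSV
#' @param csv_path Path written by [export_heatmap()].
#' @return Numeric matrix with FOV row names.
#' @export
read_heatmap_csv <- function(csv_path) {
  df <- utils::read.csv(csv_path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Summary statistics of per-FOV supplementary-style tables
#'
#' Computes the headline summaries reported for infiltration-area and
#' distance analyses from a per-FOV CSV: the mean and coefficient of
#' variation of a per-FOV metric by sample group, e.g. mean infiltration
#' fraction and its CV per brisk/non-brisk group, or mean NND by region.
#'
#' @param df Data frame with one row per FOV.
#' @param value_col Name of the per-FOV metric column.
#' @param group_col Optional grouping column; `NULL` summarizes all rows.
#' @return Data frame with `group`, `n`, `mean`, `cv`.
#' @export
summarize_per_fov <- function(df, value_col, group_col = NULL) {
  groups <- if (is.null(group_col)) rep("all", nrow(df)) else df[[group_col]]
  out <- lapply(unique(groups), function(g) {
    v <- df[[value_col]][groups == g]
    data.frame(group = g, n = sum(!is.na(v)),
               mean = mean(v, na.rm = TRUE),
               cv = coefficient_of_variation(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
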