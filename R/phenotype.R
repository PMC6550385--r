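#' Marker-rule phenotype definitions
#'
#' A phenotype rule assigns a class label to cells whose marker intensities
#' exceed the required thresholds and stay at or below the excluded ones.
#' Positivity is strict: intensity must be greater than the threshold.
#'
#' @param label Class label (e.g. `"Tumor"`, `"CD3"`, `"CD20"`, `"CD8PD1"`,
#'   `"CD4FOXP3"`).
#' @param required Named numeric vector `c(marker = threshold, ...)`; the
#'   cell must be above every one.
#' @param excluded Named numeric vector; the cell must not be above any.
#' @param priority Integer; when a cell matches several non-conflicting
#'   rules the highest priority wins (e.g. CD8+PD1+ over plain CD3+).
#' @return A `phenotype_rule`.
#' @export
phenotype_rule <- function(label, required, excluded = numeric(), priority = 0L) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(required), length(required) >= 1L,
            !is.null(names(required)),
            all(required >= 0), all(excluded >= 0))
  if (length(excluded) && is.null(names(excluded)))
    stop("excluded markers must be named", call. = FALSE)
  if (length(intersect(names(required), names(excluded))))
    stop("required and excluded marker sets must be disjoint", call. = FALSE)
  structure(list(label = label, required = required, excluded = excluded,
                 priority = as.integer(priority)),
            class = "phenotype_rule")
}

#' Default melanoma TME phenotype rule set
#'
#' Tumor cells by the S100 tumor-mask marker; T cells by CD3 with CD20
#' exclusion (and vice versa for B cells); cytotoxic PD1+ T cells by
#' CD8 and PD1 co-positivity; regulatory T cells by CD4 and FOXP3
#' co-expression. Thresholds are in the intensity units of the table and
#' must be tuned to the staining batch; the defaults match the package's
#' synthetic intensity model.
#'
#' @param threshold Default positivity threshold applied to every marker.
#' @param tumor_marker Name of the tumor mask marker column.
#' @return List of [phenotype_rule()] objects.
#' @export
default_phenotype_rules <- function(threshold = 150, tumor_marker = "S100") {
  thr <- threshold
  list(
    phenotype_rule("Tumor", required = stats::setNames(thr, tumor_marker), priority = 10L),
    phenotype_rule("CD8PD1", required = c(CD3 = thr, CD8 = thr, PD1 = thr),
                   excluded = c(CD20 = thr), priority = 3L),
    phenotype_rule("CD4FOXP3", required = c(CD4 = thr, FOXP3 = thr),
                   excluded = c(CD20 = thr), priority = 3L),
    phenotype_rule("CD3", required = c(CD3 = thr),
                   excluded = c(CD20 = thr), priority = 1L),
    phenotype_rule("CD20", required = c(CD20 = thr),
                   excluded = c(CD3 = thr), priority = 1L)
  )
}

rule_raw_match <- function(table, rule) {
  ok <- rep(TRUE, nrow(table))
  for (m in names(rule$required)) ok <- ok & table[[m]] > rule$required[[m]]
  ok
}

rule_excl_hit <- function(table, rule) {
  hit <- rep(FALSE, nrow(table))
  for (m in names(rule$excluded)) hit <- hit | table[[m]] > rule$excluded[[m]]
  hit
}

#' Assign rule-based phenotypes
#'
#' Evaluates every rule on every cell. A cell that is positive for the
#' required markers of two rules that declare each other's markers excluded
#' (e.g. CD3 and CD20, which are mutually exclusive on T and B cells) is
#' labelled `"ambiguous"` and is excluded from downstream counts. Among
#' non-conflicting matches the highest-priority rule wins. Cells matching
#' nothing are `"unclassified"`. The tumor label is driven by the tumor
#' mask marker and can co-occur with nothing: a rule whose required set is
#' the tumor marker must be present.
#'
#' @param table A [cell_table] with marker intensity columns.
#' @param rules List of [phenotype_rule()] objects.
#' @param tumor_mask_marker Marker that defines the tumor mask (default
#'   `"S100"`); a rule keyed on it must exist.
#' @return The table with a `phenotype` column.
#' @export
assign_phenotypes <- function(table, rules = default_phenotype_rules(),
                              tumor_mask_marker = "S100") {
  all_markers <- unique(unlist(lapply(rules, function(r)
    c(names(r$required), names(r$excluded)))))
  missing <- setdiff(all_markers, names(table))
  if (length(missing))
    stop("rule references unknown marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tumor_rules <- vapply(rules, function(r)
    identical(names(r$required), tumor_mask_marker), logical(1))
  if (!any(tumor_rules))
    stop("no rule keyed on tumor mask marker '", tumor_mask_marker, "'",
         call. = FALSE)

  n <- nrow(table)
  raw <- vapply(rules, function(r) rule_raw_match(table, r), logical(n))
  if (n == 1L) raw <- matrix(raw, nrow = 1L)
  labels <- vapply(rules, `[[`, character(1), "label")
  prios  <- vapply(rules, `[[`, integer(1), "priority")

  # conflict: two raw-matched rules where one's required marker is excluded
  # by the other (mutual-exclusivity violations such as CD3+CD20+)
  conflict <- rep(FALSE, n)
  nr <- length(rules)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (i == j) next
    if (length(intersect(names(rules[[i]]$required),
                         names(rules[[j]]$excluded)))) {
      conflict <- conflict | (raw[, i] & raw[, j])
    }
  }

  # highest-priority raw match wins among non-conflicting cells; ties broken
  # by rule order
  phenotype <- rep("unclassified", n)
  ord <- order(prios, decreasing = TRUE)
  for (k in ord) {
    unset <- phenotype == "unclassified"
    phenotype[unset & raw[, k]] <- labels[k]
  }
  phenotype[conflict] <- "ambiguous"
  table$phenotype <- phenotype
  table
}

#' HLA-1 calling configuration
#'
#' The tumor HLA-1 positivity threshold is anchored on CD3+ cells, which
#' express HLA-1 ubiquitously and therefore serve as an internal control:
#' the threshold is `fraction` times a pooled statistic of the CD3+ cells'
#' HLA-1 intensity.
#'
#' @param fraction Fraction of the pooled CD3+ HLA-1 intensity (default
#'   0.10).
#' @param pooling_statistic `"median"` (default) or `"mean"` over CD3+
#'   cells.
#' @param pooling_scope `"all_ROIs"` (default; one threshold over the whole
#'   table) or `"per_FOV"`.
#' @param mode `"fraction_of_statistic"` (default: threshold =
#'   `fraction * statistic`) or `"percentile"` (threshold = the
#'   `100*fraction` percentile of the CD3+ HLA-1 distribution) — the two
#'   readings of "a signal greater than the 10% of the CD3+ intensity".
#' @param cd3_labels Phenotype labels treated as CD3+ internal-control
#'   cells.
#' @param hla_marker Name of the HLA-1 intensity column.
#' @return An `hla_call_config`.
#' @export
hla_call_config <- function(fraction = 0.10,
                            pooling_statistic = c("median", "mean"),
                            pooling_scope = c("all_ROIs", "per_FOV"),
                            mode = c("fraction_of_statistic", "percentile"),
                            cd3_labels = c("CD3", "CD8PD1"),
                            hla_marker = "HLA1") {
  stopifnot(fraction > 0, fraction <= 1)
  structure(list(fraction = fraction,
                 pooling_statistic = match.arg(pooling_statistic),
                 pooling_scope = match.arg(pooling_scope),
                 mode = match.arg(mode),
                 cd3_labels = cd3_labels,
                 hla_marker = hla_marker),
            class = "hla_call_config")
}

#' Call tumor HLA-1 status against the CD3+ internal control
#'
#' Computes the positivity threshold from CD3+ cells' HLA-1 intensity
#' (default: 10% of their median, pooled over all regions) and labels each
#' tumor cell `HLA1pos` when its HLA-1 intensity is strictly greater than
#' the threshold, `HLA1neg` otherwise. The threshold(s) used are recorded
#' in the `hla_threshold` attribute of the result.
#'
#' @param table A phenotyped [cell_table].
#' @param cfg An [hla_call_config()].
#' @return The table with an `hla_status` column (`NA` for non-tumor
#'   cells).
#' @export
call_hla1_status <- function(table, cfg = hla_call_config()) {
  stopifnot(inherits(cfg, "hla_call_config"))
  if (!"phenotype" %in% names(table))
    stop("phenotypes must be assigned before HLA-1 calling", call. = FALSE)
  if (!cfg$hla_marker %in% names(table))
    stop("HLA-1 marker column '", cfg$hla_marker, "' not found", call. = FALSE)

  hla <- table[[cfg$hla_marker]]
  is_cd3 <- table$phenotype %in% cfg$cd3_labels
  is_tumor <- table$phenotype == "Tumor"
  stat_fun <- switch(cfg$pooling_statistic,
                     median = stats::median, mean = mean)
  thr_of <- function(values) {
    if (!length(values))
      stop("internal control unavailable: no CD3+ cells in scope",
           call. = FALSE)
    if (cfg$mode == "percentile")
      unname(stats::quantile(values, probs = cfg$fraction, type = 7))
    else
      cfg$fraction * stat_fun(values)
  }

  status <- rep(NA_character_, nrow(table))
  if (cfg$pooling_scope == "all_ROIs") {
    thr <- thr_of(hla[is_cd3])
    status[is_tumor] <- ifelse(hla[is_tumor] > thr, "HLA1pos", "HLA1neg")
    thresholds <- c(all_ROIs = thr)
  } else {
    fovs <- unique(table$fov_id)
    thresholds <- stats::setNames(numeric(length(fovs)), fovs)
    for (f in fovs) {
      in_f <- table$fov_id == f
      thr <- thr_of(hla[is_cd3 & in_f])
      thresholds[[as.character(f)]] <- thr
      sel <- is_tumor & in_f
      status[sel] <- ifelse(hla[sel] > thr, "HLA1pos", "HLA1neg")
    }
  }
  table$hla_status <- status
  attr(table, "hla_threshold") <- thresholds
  table
}

#' Effective cell class labels for spatial analysis
#'
#' Collapses `phenotype` and `hla_status` into one label vector: tumor
#' cells become `Tumor_HLA1pos` / `Tumor_HLA1neg` when HLA-1 status has
#' been called, other cells keep their phenotype.
#'
#' @param table A phenotyped [cell_table].
#' @return Character vector of per-cell class labels.
#' @export
cell_classes <- function(table) {
  cls <- table$phenotype
  if ("hla_status" %in% names(table)) {
    called <- !is.na(table$hla_status)
    cls[called] <- paste0("Tumor_", table$hla_status[called])
  }
  cls
}

#' Read phenotype rules from a YAML or JSON file
#'
#' File format: a list of entries `{label, required: {marker: threshold},
#' excluded: {marker: threshold}, priority}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` rules file.
#' @return List of [phenotype_rule()] objects.
#' @export
read_phenotype_rules <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(e) {
    phenotype_rule(
      label = e$label,
      required = unlist(e$required),
      excluded = if (is.null(e$excluded)) numeric() else unlist(e$excluded),
      priority = if (is.null(e$priority)) 0L else e$priority
    )
  })
}
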