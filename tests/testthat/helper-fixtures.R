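# Shared fixtures and independent brute-force oracles for the test suite.

# --- tiny cell-table CSV ----------------------------------------------------

write_tiny_csv <- function(path, drop = NULL, qc_alignment = c(0.9, 0.95, 1)) {
  df <- data.frame(
    cell_id = c("c1", "c2", "c3"),
    fov_id = "F1", sample_id = "S1",
    x = c(10, 20, 30), y = c(5, 15, 25),
    S100 = c(500, 10, 12), CD3 = c(8, 400, 9), CD20 = c(7, 6, 300),
    qc_alignment = qc_alignment,
    px_nucleus = c(20L, 30L, 40L), px_membrane = c(25L, 35L, 45L),
    px_cytoplasm = c(30L, 40L, 50L), n_nuclei = c(1L, 1L, 2L),
    stringsAsFactors = FALSE)
  if (!is.null(drop)) df <- df[, setdiff(names(df), drop), drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# in-memory cell table built directly (bypasses file IO)
make_cells <- function(x, y, class, fov_id = "F1", sample_id = "S1",
                       hla = NULL) {
  n <- length(x)
  df <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    fov_id = fov_id, sample_id = sample_id,
    x = x, y = y, phenotype = class, stringsAsFactors = FALSE)
  if (!is.null(hla)) df$hla_status <- hla
  tmespat:::new_cell_table(df, unit = "um", markers = character())
}

# --- CAA oracle: literal layer-wise growth simulation -----------------------
# Independent of the package implementation: expands each seed one layer at
# a time (adding adjacent squares holding >= cutoff cells), then merges
# aggregates that share squares. Returns a canonical sorted list of
# "row:col" key sets (0-based).

oracle_grow <- function(counts, seeds, cutoff, connectivity = 8) {
  nr <- nrow(counts); nc <- ncol(counts)
  offs <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  grow_one <- function(seed_rc) {
    members <- list(seed_rc)
    keys <- paste(seed_rc[1], seed_rc[2])
    repeat {
      added <- FALSE
      for (m in members) {
        for (o in offs) {
          rr <- m[1] + o[1]; cc <- m[2] + o[2]
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          k <- paste(rr, cc)
          if (k %in% keys) next
          if (counts[rr, cc] >= cutoff) {
            members[[length(members) + 1]] <- c(rr, cc)
            keys <- c(keys, k)
            added <- TRUE
          }
        }
      }
      if (!added) break
    }
    keys
  }
  aggs <- lapply(seq_len(nrow(seeds)), function(i)
    grow_one(c(seeds$row[i] + 1, seeds$col[i] + 1)))
  # merge aggregates sharing any square
  changed <- TRUE
  while (changed && length(aggs) > 1) {
    changed <- FALSE
    for (i in seq_along(aggs)) {
      for (j in seq_along(aggs)) {
        if (j <= i) next
        if (length(intersect(aggs[[i]], aggs[[j]]))) {
          aggs[[i]] <- union(aggs[[i]], aggs[[j]])
          aggs[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  canonical_sets(aggs)
}

canonical_sets <- function(key_sets) {
  out <- lapply(key_sets, function(k) sort(unique(k)))
  out[order(vapply(out, `[`, character(1), 1))]
}

aggs_to_sets <- function(aggs) {
  canonical_sets(lapply(aggs, function(a)
    paste(a$squares$row + 1, a$squares$col + 1)))
}

# --- CNAA oracle: O(n^2) all-pairs distances --------------------------------

oracle_neighborhood <- function(x, y, class, centers_idx, radius,
                                counted, targets) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  res <- list()
  for (i in centers_idx) {
    nb <- which(d[i, ] <= radius & seq_along(x) != i)
    counts <- vapply(counted, function(cl) sum(class[nb] == cl), numeric(1))
    nnd <- vapply(targets, function(tc) {
      sel <- nb[class[nb] == tc]
      if (length(sel)) min(d[i, sel]) else NA_real_
    }, numeric(1))
    res[[length(res) + 1]] <- list(counts = counts, nnd = nnd)
  }
  res
}

# --- quantile oracle: sort-and-interpolate by hand --------------------------

oracle_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# --- 2x2 CMH closed form (single stratum) -----------------------------------

oracle_cmh_2x2 <- function(tab) {
  n <- sum(tab)
  num <- (tab[1, 1] - sum(tab[1, ]) * sum(tab[, 1]) / n)^2
  den <- prod(rowSums(tab)) * prod(colSums(tab)) / (n^2 * (n - 1))
  num / den
}

# phenotyped + HLA-called synthetic FOV, shared across tests
phenotyped_fov <- function(seed = 1, ...) {
  fov <- generate_fov(synthetic_config(...), seed = seed)
  cells <- apply_qc(fov$cells)$cells
  cells <- call_hla1_status(assign_phenotypes(cells))
  list(cells = cells, truth = fov$truth)
}
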