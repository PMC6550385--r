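test_that("neighborhood counts and NND follow the radius convention", {
  # center at origin; targets at 5, 8, exactly R, and R + epsilon
  cells <- make_cells(x = c(0, 5, 8, 12, 12.001),
                      y = c(0, 0, 0, 0, 0),
                      class = c("CD3", "T", "T", "T", "T"))
  rec <- neighborhoods(cells, nbhd_config(radius_um = 12,
                                          center_classes = "CD3",
                                          counted_classes = "T",
                                          nnd_pairs = list(c("CD3", "T"))))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n_T, 3L)           # distance exactly R counts (<=)
  expect_equal(rec$nnd_T, 5)          # minimum distance

  # isolated center: zero counts, missing NND
  lone <- make_cells(x = c(0, 100), y = c(0, 0), class = c("CD3", "T"))
  rec2 <- neighborhoods(lone, nbhd_config(radius_um = 12,
                                          center_classes = "CD3",
                                          counted_classes = "T",
                                          nnd_pairs = list(c("CD3", "T"))))
  expect_equal(rec2$n_T, 0L)
  expect_true(is.na(rec2$nnd_T))

  # unbounded diagnostic mode reports the global nearest neighbor instead
  rec3 <- neighborhoods(lone, nbhd_config(radius_um = 12,
                                          center_classes = "CD3",
                                          counted_classes = "T",
                                          nnd_pairs = list(c("CD3", "T")),
                                          bounded = FALSE))
  expect_equal(rec3$nnd_T, 100)
})

test_that("accelerated search matches the all-pairs oracle exactly", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(100:250, 1)
    x <- runif(n, 0, 300); y <- runif(n, 0, 300)
    cls <- sample(c("A", "B", "C"), n, replace = TRUE)
    cells <- make_cells(x, y, cls)
    R <- runif(1, 8, 40)
    rec <- neighborhoods(cells, nbhd_config(
      radius_um = R, center_classes = "A",
      counted_classes = c("A", "B", "C"),
      nnd_pairs = list(c("A", "B"), c("A", "C"))))
    centers <- which(cls == "A")
    want <- oracle_neighborhood(x, y, cls, centers, R,
                                counted = c("A", "B", "C"),
                                targets = c("B", "C"))
    for (k in seq_along(centers)) {
      expect_identical(c(rec$n_A[k], rec$n_B[k], rec$n_C[k]),
                       as.integer(want[[k]]$counts))
      expect_identical(c(rec$nnd_B[k], rec$nnd_C[k]), unname(want[[k]]$nnd))
    }
  }
})

test_that("counts are monotone in radius and reach n-1 at large R", {
  set.seed(9)
  n <- 80
  cells <- make_cells(runif(n, 0, 100), runif(n, 0, 100),
                      sample(c("A", "B"), n, replace = TRUE))
  radii <- c(5, 15, 40, 1e6)
  totals <- sapply(radii, function(R) {
    rec <- neighborhoods(cells, nbhd_config(radius_um = R, center_classes = "A",
                                            counted_classes = c("A", "B")))
    rec$n_A + rec$n_B
  })
  for (k in 2:length(radii)) expect_true(all(totals[, k] >= totals[, k - 1]))
  expect_true(all(totals[, length(radii)] == n - 1L))
})

test_that("NND is asymmetric between classes by construction", {
  # two A cells flank one B cell: NND(A->B) exists for both A's, but the
  # B-centered distance to its nearest A differs from each A's to B
  cells <- make_cells(x = c(0, 3, 10), y = c(0, 0, 0),
                      class = c("A", "B", "A"))
  rec_ab <- neighborhoods(cells, nbhd_config(radius_um = 12, center_classes = "A",
                                             counted_classes = "B",
                                             nnd_pairs = list(c("A", "B"))))
  rec_ba <- neighborhoods(cells, nbhd_config(radius_um = 12, center_classes = "B",
                                             counted_classes = "A",
                                             nnd_pairs = list(c("B", "A"))))
  expect_equal(sort(rec_ab$nnd_B), c(3, 7))
  expect_equal(rec_ba$nnd_A, 3)
  expect_false(isTRUE(all.equal(mean(rec_ab$nnd_B), mean(rec_ba$nnd_A))))
})

test_that("tag_regions splits records by the infiltration area polygon", {
  reg <- tmespat:::square_region(c(0, 0), c(0, 1), c(0, 0), 10)
  ia <- structure(list(fov_id = "F1", region = reg,
                       area_um2 = region_area(reg), tumor_area_um2 = 100,
                       infiltration_fraction = 1), class = "infiltration_area")
  cells <- make_cells(x = c(5, 15, 50), y = c(5, 5, 50),
                      class = c("CD3", "CD3", "CD3"))
  rec <- neighborhoods(cells, nbhd_config(center_classes = "CD3",
                                          counted_classes = "CD3"))
  rec <- tag_regions(rec, ia)
  expect_equal(rec$region, c("inside_IA", "inside_IA", "outside_IA"))
  # partition: inside + outside = all centers
  expect_equal(sum(rec$region == "inside_IA") + sum(rec$region == "outside_IA"),
               nrow(rec))
  # empty IA -> everything outside
  empty <- structure(list(fov_id = "F1",
                          region = tmespat:::square_region(integer(), integer(),
                                                           c(0, 0), 10),
                          area_um2 = 0, tumor_area_um2 = 0,
                          infiltration_fraction = NA_real_),
                     class = "infiltration_area")
  rec2 <- tag_regions(rec, empty)
  expect_true(all(rec2$region == "outside_IA"))
  # FOV mismatch errors
  expect_error(tag_regions(rec, stats::setNames(list(ia), "F9")), "mismatch")
})

test_that("summarize_nnd uses two-stage FOV-then-cohort averaging", {
  rec <- data.frame(cell_id = sprintf("c%d", 1:6),
                    fov_id = c("F1", "F1", "F2", "F2", "F2", "F3"),
                    sample_id = "S1", class = "CD3",
                    x = 0, y = 0, region = NA_character_,
                    nnd_T = c(10, 14, 10, 14, 18, NA),
                    stringsAsFactors = FALSE)
  out <- summarize_nnd(rec, targets = "T", by = character())
  # FOV means: F1 = 12, F2 = 14; F3 has no data and is excluded but flagged
  expect_equal(sort(out$per_fov$mean_nnd[out$per_fov$n > 0]), c(12, 14))
  expect_equal(out$per_fov$n[out$per_fov$fov_id == "F3"], 0)
  expect_equal(out$overall$n_fovs, 2)
  expect_equal(out$overall$mean_nnd_fov_weighted, 13)       # unweighted across FOVs
  expect_equal(out$overall$mean_nnd_cell_weighted, mean(c(10, 14, 10, 14, 18)))
})

test_that("neighborhood composition ratios are per tumor cell", {
  rec <- data.frame(cell_id = c("a", "b"), fov_id = "F1", sample_id = "S1",
                    class = "CD3", x = 0, y = 0, region = "inside_IA",
                    n_Tumor_HLA1pos = c(3L, 1L), n_Tumor_HLA1neg = c(1L, 1L),
                    n_CD20 = c(2L, 4L), stringsAsFactors = FALSE)
  comp <- neighborhood_composition(rec)
  expect_equal(comp$count_CD20, 6)
  expect_equal(comp$ratio_CD20_per_tumor, 1)               # 6 / (4 + 2)
  expect_equal(comp$ratio_Tumor_HLA1pos_per_tumor, 4 / 6)
})
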