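grid_from_matrix <- function(m, s = 10, class = "T") {
  # build a grid_counts object directly from a count matrix (rows = bottom-up)
  structure(list(fov_id = "F1", origin = c(0, 0), square_size_um = s,
                 n_rows = nrow(m), n_cols = ncol(m),
                 counts = stats::setNames(list(m), class)),
            class = "grid_counts")
}

test_that("grid_counts bins cells half-open with closed last edges", {
  # 100x100 window, squares of 50 -> 2x2 grid
  cells <- make_cells(x = c(10, 50, 99, 100, 0),
                      y = c(10, 10, 99, 100, 0), class = "T")
  w <- fov_window(cells, bounds = c(0, 100, 0, 100))
  g <- grid_counts(cells, w, caa_config(square_size_um = 50), classes = "T",
                   class_of = rep("T", 5))
  expect_equal(dim(g$counts$T), c(2, 2))
  expect_equal(sum(g$counts$T), 5)           # every cell in exactly one square
  # x = 50 on the interior edge goes to the right square (half-open)
  expect_equal(g$counts$T[1, 2], 1)
  # x = 100 on the closed outer edge stays in the last column
  expect_equal(g$counts$T[2, 2], 2)
  expect_equal(g$counts$T[1, 1], 2)

  # 5 cells of one class in one square
  cells5 <- make_cells(x = rep(10, 5), y = rep(10, 5), class = "T")
  g5 <- grid_counts(cells5, w, caa_config(square_size_um = 50), classes = "T",
                    class_of = rep("T", 5))
  expect_equal(g5$counts$T[1, 1], 5)
  expect_equal(sum(g5$counts$T), 5)
  # empty class -> zero matrix, no error
  g0 <- grid_counts(cells5, w, caa_config(square_size_um = 50), classes = "B",
                    class_of = rep("T", 5))
  expect_equal(sum(g0$counts$B), 0)
})

test_that("seed_squares takes counts strictly above the interpolated quantile", {
  # 99 zeros and one 10: P95 (linear interpolation) = 0, one seed
  m <- matrix(0, 10, 10); m[4, 7] <- 10
  g <- grid_from_matrix(m)
  s <- seed_squares(g, "T", caa_config(seed_percentile = 95))
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$row, s$col), c(3, 6))

  # all equal -> nothing strictly above its own quantile
  g_eq <- grid_from_matrix(matrix(4, 5, 5))
  expect_equal(nrow(seed_squares(g_eq, "T", caa_config())), 0L)

  # counts 1..100: hand-interpolated P95 over the sorted counts
  m2 <- matrix(1:100, 10, 10)
  expect_equal(oracle_quantile(1:100, 0.95), 95.05)
  s2 <- seed_squares(grid_from_matrix(m2), "T", caa_config())
  expect_setequal(m2[cbind(s2$row + 1, s2$col + 1)], 96:100)

  # quantile rule matches the hand oracle on random count vectors
  set.seed(11)
  for (i in 1:20) {
    v <- rpois(36, 3)
    m3 <- matrix(v, 6, 6)
    p <- sample(c(50, 80, 95), 1)
    s3 <- seed_squares(grid_from_matrix(m3), "T",
                       caa_config(seed_percentile = p))
    expect_setequal(paste(s3$row, s3$col),
                    {
                      q <- oracle_quantile(v, p / 100)
                      idx <- which(m3 > q, arr.ind = TRUE)
                      paste(idx[, 1] - 1, idx[, 2] - 1)
                    })
  }
})

test_that("grow_aggregates follows layer-wise growth semantics", {
  cfg <- caa_config(growth_cutoff = 3)
  # seed whose neighbors are all below cutoff -> aggregate is the seed alone
  m <- matrix(1, 5, 5); m[3, 3] <- 50
  aggs <- grow_aggregates(grid_from_matrix(m), "T", cfg)
  expect_length(aggs, 1L)
  expect_equal(aggs[[1]]$squares, data.frame(row = 2L, col = 2L))

  # straight chain of qualifying squares touching the seed is absorbed whole
  m2 <- matrix(0, 5, 7)
  m2[3, 2:6] <- c(3, 3, 50, 3, 3)
  aggs2 <- grow_aggregates(grid_from_matrix(m2), "T", cfg)
  expect_length(aggs2, 1L)
  expect_setequal(paste(aggs2[[1]]$squares$row, aggs2[[1]]$squares$col),
                  paste(2, 1:5))

  # two seeds inside one qualifying component merge into one aggregate
  m3 <- matrix(0, 5, 7)
  m3[2, 2:6] <- c(50, 4, 4, 4, 50)
  aggs3 <- grow_aggregates(grid_from_matrix(m3), "T", cfg)
  expect_length(aggs3, 1L)
  expect_equal(nrow(aggs3[[1]]$squares), 5L)
})

test_that("growth matches the layer-wise oracle on random grids (both connectivities)", {
  set.seed(101)
  for (i in 1:60) {
    m <- matrix(rpois(100, 1.2), 10, 10)
    conn <- sample(c(4, 8), 1)
    cutoff <- sample(1:4, 1)
    cfg <- caa_config(growth_cutoff = cutoff, connectivity = conn)
    g <- grid_from_matrix(m)
    seeds <- seed_squares(g, "T", cfg)
    if (!nrow(seeds)) next
    got <- aggs_to_sets(grow_aggregates(g, "T", cfg))
    want <- oracle_grow(m, seeds, cutoff, conn)
    expect_identical(got, want)
  }
})

test_that("lowering the growth cutoff never shrinks an aggregate", {
  set.seed(7)
  m <- matrix(rpois(100, 2), 10, 10)
  g <- grid_from_matrix(m)
  hi <- grow_aggregates(g, "T", caa_config(growth_cutoff = 4))
  lo <- grow_aggregates(g, "T", caa_config(growth_cutoff = 2))
  hi_sq <- unlist(aggs_to_sets(hi))
  lo_sq <- unlist(aggs_to_sets(lo))
  expect_true(all(hi_sq %in% lo_sq))
})

test_that("polygons conserve area and rasterize back to their squares", {
  cfg <- caa_config(growth_cutoff = 1, square_size_um = 10)
  # one square
  m <- matrix(0, 3, 3); m[2, 2] <- 5
  a <- aggregates_to_polygons(grow_aggregates(grid_from_matrix(m), "T",
                                              caa_config(growth_cutoff = 6)))
  expect_equal(a[[1]]$area_um2, 100)
  expect_match(a[[1]]$wkt, "^POLYGON")

  # two diagonal squares: multi-part, area additive
  r2 <- tmespat:::square_region(c(0, 1), c(0, 1), c(0, 0), 10)
  expect_equal(region_area(r2), 200)
  expect_length(region_polygons(r2), 2L)
  expect_match(region_to_wkt(r2), "^MULTIPOLYGON")

  # 3x3 ring: one part with one interior hole
  ring <- expand.grid(row = 0:2, col = 0:2)
  ring <- ring[!(ring$row == 1 & ring$col == 1), ]
  rr <- tmespat:::square_region(ring$row, ring$col, c(0, 0), 10)
  parts <- region_polygons(rr)
  expect_length(parts, 1L)
  expect_length(parts[[1]], 2L)          # outer ring + hole
  expect_equal(region_area(rr), 800)

  # rasterization round-trip: square centers classify exactly as membership
  set.seed(3)
  for (i in 1:10) {
    sq <- unique(data.frame(row = sample(0:5, 12, TRUE),
                            col = sample(0:5, 12, TRUE)))
    reg <- tmespat:::square_region(sq$row, sq$col, c(0, 0), 10)
    all_sq <- expand.grid(row = 0:5, col = 0:5)
    centers_in <- points_in_region((all_sq$col + 0.5) * 10,
                                   (all_sq$row + 0.5) * 10, reg)
    expect_identical(centers_in,
                     paste(all_sq$row, all_sq$col) %in% paste(sq$row, sq$col))
    expect_equal(region_area(reg), nrow(sq) * 100)
  }
})

test_that("infiltration areas are grid-exact intersections", {
  s <- 10
  tum <- tmespat:::square_region(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0, 0), s)
  mk_agg <- function(region, class) {
    structure(list(class = class, fov_id = "F1",
                   squares = data.frame(row = region$rows, col = region$cols),
                   region = region, area_um2 = region_area(region)),
              class = "aggregate")
  }
  grid <- grid_from_matrix(matrix(0, 2, 2), s = s)

  # identical polygons -> fraction 1
  ia <- infiltration_areas(list(mk_agg(tum, "Tumor")), list(mk_agg(tum, "CD3")), grid)
  expect_equal(ia$infiltration_fraction, 1)

  # disjoint -> empty IA, fraction 0
  cd3 <- tmespat:::square_region(5, 5, c(0, 0), s)
  ia0 <- infiltration_areas(list(mk_agg(tum, "Tumor")), list(mk_agg(cd3, "CD3")), grid)
  expect_equal(ia0$area_um2, 0)
  expect_equal(ia0$infiltration_fraction, 0)

  # half overlap -> fraction 0.5 exactly
  half <- tmespat:::square_region(c(0, 0), c(0, 1), c(0, 0), s)
  ia5 <- infiltration_areas(list(mk_agg(tum, "Tumor")), list(mk_agg(half, "CD3")), grid)
  expect_equal(ia5$infiltration_fraction, 0.5)
  expect_lte(ia5$area_um2, min(region_area(tum), region_area(half)))

  # no tumor aggregate -> fraction is missing, not infinite
  ia_na <- infiltration_areas(list(), list(mk_agg(cd3, "CD3")), grid)
  expect_true(is.na(ia_na$infiltration_fraction))

  # FOV mismatch is an error
  bad <- mk_agg(tum, "Tumor"); bad$fov_id <- "F2"
  expect_error(infiltration_areas(list(bad), list(mk_agg(tum, "CD3")), grid),
               "different FOVs")
})

test_that("cells_in_region is boundary-inclusive and partitions the table", {
  reg <- tmespat:::square_region(c(0, 0), c(0, 1), c(0, 0), 10)  # [0,20]x[0,10]
  cells <- make_cells(x = c(5, 10, 20, 25, 0), y = c(5, 10, 5, 5, 0), class = "T")
  inside <- cells_in_region(cells, reg)
  outside <- cells_in_region(cells, reg, invert = TRUE)
  # centroid, edge point, and corner point are all inside
  expect_setequal(inside$cell_id, c("c001", "c002", "c003", "c005"))
  expect_equal(nrow(inside) + nrow(outside), nrow(cells))
  expect_length(intersect(inside$cell_id, outside$cell_id), 0L)
})

test_that("geojson export writes valid multipolygon features", {
  reg <- tmespat:::square_region(c(0, 1), c(0, 0), c(0, 0), 50)
  path <- tempfile(fileext = ".geojson")
  regions_to_geojson(list(IA_F1 = reg), path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(gj$features[[1]]$properties$area_um2, 5000)
  expect_equal(gj$features[[1]]$geometry$type, "MultiPolygon")
})
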