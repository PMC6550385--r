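ratio_fixture <- function() {
  # two FOVs with known composition
  cls <- c(rep("Tumor_HLA1pos", 4), rep("Tumor_HLA1neg", 6),
           rep("CD3", 5), rep("CD20", 2), rep("CD8PD1", 1), rep("CD4FOXP3", 2))
  n <- length(cls)
  make_cells(seq_len(n), seq_len(n), cls)
}

test_that("fov_ratios computes the ratio panel with missing-on-zero denominators", {
  rt <- fov_ratios(ratio_fixture())
  expect_equal(rt$hla1pos_per_tumor, 0.4)       # 4 HLA1+ of 10 tumor cells
  expect_equal(rt$cd3_per_tumor, 0.5)
  expect_equal(rt$cd20_per_immune, 0.2)         # 2 of 10 immune cells

  # FOV with no tumor cells: tumor-denominated ratios missing, never Inf
  imm <- make_cells(1:3, 1:3, c("CD3", "CD20", "CD3"), fov_id = "F9")
  rt2 <- fov_ratios(imm)
  expect_true(is.na(rt2$cd3_per_tumor))
  expect_false(any(is.infinite(unlist(rt2[sapply(rt2, is.numeric)]))))
  expect_error(fov_ratios(imm, ratios = list(bad = list(num = "CD3", den = "Stroma"))),
               "denominator")
})

test_that("region restriction never increases counts", {
  cells <- ratio_fixture()
  reg <- tmespat:::square_region(0, 0, c(0, 0), 8)   # covers cells with x,y <= 8
  rt_all <- fov_ratios(cells)
  rt_ia <- fov_ratios(cells, regions = list(F1 = reg))
  count_cols <- grep("^count_", names(rt_all), value = TRUE)
  for (cc in count_cols) expect_lte(rt_ia[[cc]], rt_all[[cc]])
})

test_that("correlogram flags significance and insufficient data", {
  set.seed(1)
  df <- data.frame(fov_id = sprintf("F%d", 1:10),
                   a = 1:10, b = 2 * (1:10) + rnorm(10, 0, 1e-4),
                   c = rnorm(10),
                   d = c(rnorm(2), rep(NA, 8)))
  cg <- correlogram(df, columns = c("a", "b", "c", "d"), min_n = 3)
  # perfect linearity: r = 1 to machine precision, significant
  expect_equal(cg$r["a", "b"], 1, tolerance = 1e-6)
  expect_equal(cg$flag["a", "b"], "significant")
  expect_equal(unname(diag(cg$r)[1:3]), rep(1, 3))
  # symmetric with exhaustive, mutually exclusive flags
  expect_identical(cg$r, t(cg$r))
  expect_true(all(cg$flag %in% c("significant", "not_significant",
                                 "insufficient_data")))
  # only 2 complete rows for d -> insufficient
  expect_equal(cg$flag["a", "d"], "insufficient_data")
  expect_true(is.na(cg$r["a", "d"]))
  # r on {(1,2),(2,4),(3,6)} is exactly 1
  ex <- correlogram(data.frame(u = c(1, 2, 3), v = c(2, 4, 6)),
                    columns = c("u", "v"))
  expect_equal(ex$r["u", "v"], 1)
})

test_that("coefficient of variation is sd/mean with scale invariance", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)  # sd 1, mean 2
  expect_equal(coefficient_of_variation(rep(4, 5)), 0)
  x <- c(2, 5, 9, 4)
  expect_equal(coefficient_of_variation(7 * x), coefficient_of_variation(x))
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))   # zero mean
  expect_true(is.na(coefficient_of_variation(3)))          # n < 2
})

test_that("cmh_test matches the closed-form 2x2 chi-square for one stratum", {
  outcome <- rep(c(TRUE, FALSE), c(12, 28))
  group <- rep(c("g1", "g2", "g1", "g2"), c(8, 4, 10, 18))
  res <- cmh_test(outcome, group, stratum = rep("s1", 40))
  tab <- table(factor(outcome, c(FALSE, TRUE)), group)
  expect_equal(res$statistic, oracle_cmh_2x2(tab), tolerance = 1e-12)

  # identical group proportions in every stratum -> statistic ~ 0, p ~ 1
  o2 <- rep(c(TRUE, FALSE), 20)
  g2 <- rep(c("a", "b"), each = 2, times = 10)
  s2 <- rep(c("s1", "s2"), each = 20)
  null_res <- cmh_test(o2, g2, s2)
  expect_lt(null_res$statistic, 1e-10)
  expect_gt(null_res$p_value, 0.99)
})

test_that("cmh_test matches the reference implementation on random stratified tables", {
  set.seed(77)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    n <- 30 * k
    o <- runif(n) > runif(1, 0.3, 0.7)
    g <- sample(c("g1", "g2"), n, replace = TRUE)
    s <- sample(sprintf("s%d", 1:k), n, replace = TRUE)
    arr <- table(factor(o, c(FALSE, TRUE)), factor(g), factor(s))
    ok <- all(apply(arr, 3, function(t2) all(rowSums(t2) > 0) && all(colSums(t2) > 0)))
    if (!ok) next
    ref <- stats::mantelhaen.test(arr, correct = FALSE)
    got <- cmh_test(o, g, s)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("cmh_test is stratum-order invariant and drops degenerate strata", {
  set.seed(33)
  o <- runif(60) > 0.5
  g <- sample(c("x", "y"), 60, replace = TRUE)
  s <- sample(c("s1", "s2", "s3"), 60, replace = TRUE)
  a <- cmh_test(o, g, s)
  perm <- sample(60)
  b <- cmh_test(o[perm], g[perm], s[perm])
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  # stratum with only one group present is dropped with a warning
  o3 <- c(o, runif(5) > 0.5)
  g3 <- c(g, rep("x", 5))
  s3 <- c(s, rep("only_x", 5))
  expect_warning(res <- cmh_test(o3, g3, s3), "degenerate")
  expect_equal(res$n_strata, a$n_strata)
})

test_that("welch_compare reproduces the textbook formula and conventions", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  res <- welch_compare(a, b)
  # hand computation: t = (mean_a - mean_b)/sqrt(va/3 + vb/3), Satterthwaite df
  va <- var(a) / 3; vb <- var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  # identical constant groups -> t = 0, p = 1
  same <- welch_compare(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
  # clear separation -> tiny p
  sep <- welch_compare(c(1, 2, 3), c(101, 102, 103))
  expect_lt(sep$p_value, 1e-6)
})

test_that("heat-map export round-trips and keeps missing values missing", {
  rt <- fov_ratios(rbind(as.data.frame(ratio_fixture()),
                         as.data.frame(make_cells(1:3, 1:3, c("CD3", "CD20", "CD3"),
                                                  fov_id = "F9"))) |>
                     (\(d) tmespat:::new_cell_table(d, unit = "um"))())
  csv <- tempfile(fileext = ".csv")
  m <- export_heatmap(rt, csv)
  expect_equal(dim(m), c(2L, 5L))
  back <- read_heatmap_csv(csv)
  expect_equal(unname(back), unname(m))
  expect_true(anyNA(back["F9", ]))     # missing stays NA, not zero
})

test_that("per-FOV summary computes group means and CVs", {
  df <- data.frame(frac = c(0.2, 0.4, 0.6, 0.1, 0.1, 0.4),
                   grp = rep(c("brisk", "nonbrisk"), each = 3))
  s <- summarize_per_fov(df, "frac", "grp")
  expect_equal(s$mean[s$group == "brisk"], 0.4)
  expect_equal(s$cv[s$group == "brisk"], sd(c(0.2, 0.4, 0.6)) / 0.4)
  expect_equal(s$n, c(3, 3))
})
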