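test_that("trait formulas match direct evaluation", {
  expect_equal(cell_hydraulic_diameter(25 * pi), 10)
  expect_equal(cell_hydraulic_diameter(100 * pi), 20)
  expect_equal(cell_hydraulic_diameter(500), 2 * sqrt(500 / pi))

  expect_equal(mean_hydraulic_diameter(c(10, 10, 10)), 10)
  expect_equal(mean_hydraulic_diameter(c(10, 20)), 3300000 / 170000)

  expect_equal(cell_cwt(3, 5), 4)
  expect_equal(cell_cwt(2.2, 2.2), 2.2)
  expect_equal(cell_cwt(0, 0), 0)

  expect_equal(anatomical_density(30, 70), 0.3)
  expect_equal(anatomical_density(5, 0), 1)
  expect_equal(anatomical_density(0, 5), 0)
  expect_error(anatomical_density(0, 0), "both")
  expect_error(cell_hydraulic_diameter(-1), "> 0")
})

test_that("hydraulic mean dominates the arithmetic mean (power-mean inequality)", {
  set.seed(42)
  for (i in 1:200) {
    d <- rlnorm(sample(2:50, 1), meanlog = 3, sdlog = 0.5)
    expect_gte(mean_hydraulic_diameter(d), mean(d))
  }
})

test_that("anatomical density is bounded and monotone in wall area", {
  set.seed(1)
  cwa <- runif(100, 0, 1000); la <- runif(100, 1, 1000)
  ad <- anatomical_density(cwa, la)
  expect_true(all(ad >= 0 & ad <= 1))
  expect_true(all(diff(anatomical_density(seq(0, 500, 10), 300)) > 0))
})

test_that("sector assignment follows the floor convention", {
  expect_equal(assign_sectors(0), 1L)
  expect_equal(assign_sectors(0.999), 100L)
  expect_equal(assign_sectors(0.5), 51L)
  expect_error(assign_sectors(1), "\\[0, 1\\)")
  expect_error(assign_sectors(-0.01), "\\[0, 1\\)")
})

test_that("Mork's index classifies with the latewood-at-1 boundary and is scale invariant", {
  expect_equal(mork_index(2, 8), 1)      # boundary -> LW under m >= 1
  expect_equal(mork_index(1, 8), 0.5)    # EW
  expect_equal(mork_index(0, 8), 0)      # zero-wall limit -> EW
  set.seed(2)
  cwt <- runif(50, 0.5, 6); ld <- runif(50, 2, 40); k <- runif(50, 0.1, 10)
  expect_equal(mork_index(cwt, ld) >= 1, mork_index(k * cwt, k * ld) >= 1)
  expect_warning(mork_index(2, 0), "wall-only")
})

test_that("sector-majority classification matches the per-cell vote", {
  cells <- tibble::tibble(
    tree_id = "t1", year = 2000L,
    rel_pos = c(0.101, 0.102, 0.103, 0.901, 0.902, 0.903),
    lumen_area_um2 = pi / 4 * c(20, 20, 20, 8, 8, 8)^2,
    cwt_rad_um = c(1, 1, 6, 3, 3, 1),   # sector 11: 2 EW vs 1 LW; sector 91: 2 LW
    cwt_tan_um = 1,
    cwa_um2 = 100,
    lumen_diam_rad_um = c(20, 20, 20, 8, 8, 8)
  )
  out <- classify_cells(cells)
  expect_equal(unique(out$part[out$sector == 11]), "EW")
  expect_equal(unique(out$part[out$sector == 91]), "LW")
  out_cell <- classify_cells(cells, level = "cell")
  expect_equal(out_cell$part, c("EW", "EW", "LW", "LW", "LW", "EW"))
})

test_that("Tukey outlier fences match the brute-force oracle", {
  res <- filter_outliers(c(1:10, 1000))
  expect_false(res$keep[11])
  expect_true(all(res$keep[1:10]))
  expect_equal(res$n_removed, 1L)

  expect_equal(filter_outliers(rep(5, 8))$n_removed, 0L)
  expect_equal(filter_outliers(c(5, 6, 7, 8))$n_removed, 0L)

  set.seed(3)
  for (i in 1:1000) {
    x <- switch(sample(3, 1),
                rnorm(sample(4:60, 1)),
                rlnorm(sample(4:60, 1), sdlog = 1.5),
                rt(sample(4:60, 1), df = 2))
    expect_identical(filter_outliers(x)$keep, tukey_keep_oracle(x))
  }
})

test_that("literal fence mode applies the printed rule only when sane", {
  x <- c(10, 12, 14, 16, 40)   # 1.5*Q1 = 18 > median 14 -> fallback
  expect_warning(res <- filter_outliers(x, mode = "literal"), "Tukey")
  x2 <- c(1, 2, 3, 4, 5, 50)      # 1.5*Q1 < median: literal fences apply
  res2 <- filter_outliers(x2, mode = "literal")
  q <- quantile(x2, c(0.25, 0.75), names = FALSE)
  expect_equal(res2$lower, 1.5 * q[1])
  expect_equal(res2$upper, 1.5 * q[2])
  expect_false(res2$keep[6])      # far right tail removed
  expect_warning(filter_outliers(c(1, 2, 3)), "fewer than 4")
})

test_that("annual aggregation reproduces known medians and splits widths exactly", {
  # 70 earlywood sectors, 30 latewood sectors, constant traits per part
  mk <- function(pos, ld, cwt) tibble::tibble(
    tree_id = "t1", year = 2001L, rel_pos = pos,
    lumen_area_um2 = pi / 4 * ld^2, cwt_rad_um = cwt, cwt_tan_um = cwt,
    cwa_um2 = 200, lumen_diam_rad_um = ld)
  cells <- dplyr::bind_rows(
    mk((0:69 + 0.5) / 100, ld = 20, cwt = 1),   # m = 0.2 -> EW
    mk((70:99 + 0.5) / 100, ld = 8, cwt = 3))   # m = 1.5 -> LW
  cells <- classify_cells(cells)
  rings <- tibble::tibble(tree_id = "t1", year = 2001L, ring_width_mm = 2.0)
  ann <- aggregate_annual(cells, rings)
  expect_equal(ann$width[ann$part == "EW"], 1.4)
  expect_equal(ann$width[ann$part == "LW"], 0.6)
  expect_equal(sum(ann$width), 2.0)
  expect_equal(ann$cwt[ann$part == "EW"], 1)
  expect_equal(ann$dh[ann$part == "EW"], 20)
  expect_equal(ann$ad[ann$part == "LW"],
               anatomical_density(200, pi / 4 * 64))
  expect_equal(ann$n_cells, c(70L, 30L))
})

test_that("part width split sums to ring width on generated data", {
  cfg <- tiny_config(seed = 9)
  d <- generate_cells(cfg, generate_climate(cfg))
  ann <- aggregate_annual(classify_cells(d$cells), d$rings)
  tot <- tapply(ann$width, paste(ann$tree_id, ann$year), sum)
  rw <- d$rings$ring_width_mm[order(paste(d$rings$tree_id, d$rings$year))]
  expect_equal(as.numeric(tot[sort(names(tot))]), unname(rw),
               tolerance = 1e-12)
})

test_that("the median makes annual records robust to a single extreme cell", {
  mk <- function(cwt) tibble::tibble(
    tree_id = "t1", year = 2001L,
    rel_pos = (seq_along(cwt) - 0.5) / 100,
    lumen_area_um2 = 300, cwt_rad_um = cwt, cwt_tan_um = cwt,
    cwa_um2 = 150, lumen_diam_rad_um = 10)
  rings <- tibble::tibble(tree_id = "t1", year = 2001L, ring_width_mm = 1)
  base <- aggregate_annual(classify_cells(mk(rep(1, 11))), rings)
  spiked <- aggregate_annual(classify_cells(mk(c(rep(1, 10), 2.4))), rings)
  expect_equal(spiked$cwt[spiked$part == "EW"],
               base$cwt[base$part == "EW"])
})

test_that("sector profiles record gaps, constants and monotone gradients", {
  cells <- tibble::tibble(
    tree_id = "t1", year = 2000L,
    rel_pos = runif(200, 0, 0.5),
    lumen_area_um2 = 400, cwt_rad_um = 2, cwt_tan_um = 2, cwa_um2 = 180,
    lumen_diam_rad_um = 20)
  cells <- classify_cells(cells)
  prof <- build_sector_profiles(cells)
  cwt <- prof[prof$trait == "CWT", ]
  expect_equal(nrow(cwt), 100L)
  expect_true(all(is.na(cwt$value[cwt$sector > 50])))
  expect_true(all(cwt$value[!is.na(cwt$value)] == 2))

  set.seed(4)
  pos <- runif(5000)
  grad <- tibble::tibble(
    tree_id = "t1", year = 2000L, rel_pos = pos,
    lumen_area_um2 = 100 + 400 * pos + rnorm(5000, 0, 10),
    cwt_rad_um = 2, cwt_tan_um = 2, cwa_um2 = 100,
    lumen_diam_rad_um = 15)
  pr <- build_sector_profiles(classify_cells(grad))
  dh <- pr[pr$trait == "DH" & !is.na(pr$value), ]
  expect_gt(cor(dh$sector, dh$value, method = "spearman"), 0.95)
})
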