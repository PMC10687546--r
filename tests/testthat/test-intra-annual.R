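mk_profiles <- function(values, tree = "t1", year = 2000L, trait = "AD",
                        group = NULL) {
  out <- tibble::tibble(tree_id = tree, year = year, trait = trait,
                        sector = seq_along(values), value = values)
  if (!is.null(group)) out$group <- group
  out
}

test_that("min-max normalization maps the ring onto [0, 1] and is affine invariant", {
  out <- minmax_normalize(mk_profiles(c(2, 4, 6)))
  expect_equal(out$value, c(0, 0.5, 1))

  set.seed(1)
  v <- runif(100)
  n1 <- minmax_normalize(mk_profiles(v))$value
  expect_equal(min(n1), 0); expect_equal(max(n1), 1)
  n2 <- minmax_normalize(mk_profiles(3.7 * v + 11))$value
  expect_equal(n1, n2, tolerance = 1e-12)

  v_na <- c(1, NA, 3)
  out_na <- minmax_normalize(mk_profiles(v_na))
  expect_true(is.na(out_na$value[2]))

  expect_message(empty <- minmax_normalize(mk_profiles(rep(5, 10))),
                 "excluded")
  expect_equal(nrow(empty), 0L)
})

test_that("group mean profiles average rings with a consistent band", {
  rings <- dplyr::bind_rows(lapply(1:5, function(i)
    mk_profiles(seq(0, 1, length.out = 100), tree = paste0("t", i))))
  gp <- group_mean_profile(rings)
  expect_equal(gp$mean, seq(0, 1, length.out = 100))
  expect_true(all(gp$hi - gp$lo < 1e-10))
  expect_equal(gp$n_rings, rep(5L, 100))
  expect_true(all(gp$lo <= gp$mean + 1e-9 & gp$mean <= gp$hi + 1e-9))

  set.seed(2)
  noisy <- dplyr::bind_rows(lapply(1:30, function(i)
    mk_profiles(pmin(1, pmax(0, seq(0, 1, length.out = 100) +
                               rnorm(100, 0, 0.1))),
                tree = paste0("t", i))))
  gp2 <- group_mean_profile(noisy)
  expect_true(all(gp2$mean >= 0 & gp2$mean <= 1))
  rmse <- sqrt(mean((gp2$smooth - seq(0, 1, length.out = 100))^2))
  expect_lt(rmse, 0.05)
})

test_that("the KS statistic equals the brute-force ECDF supremum", {
  same <- ks_two_sample(1:20, 1:20)
  expect_equal(same$d_stat, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_two_sample(1:10, 101:110)$d_stat, 1)
  expect_equal(ks_two_sample(1:5, 3:7)$d_stat, 0.4)
  expect_error(ks_two_sample(1:3, 1:10), "at least 5")

  set.seed(3)
  for (i in 1:100) {
    a <- sample(0:8, sample(5:40, 1), replace = TRUE) +
      (if (runif(1) < 0.5) 0 else rnorm(1))
    b <- sample(0:8, sample(5:40, 1), replace = TRUE)
    expect_equal(ks_two_sample(a, b)$d_stat, ks_d_brute(a, b))
  }
})

test_that("ring-permutation KS is calibrated under clustering and detects shifts", {
  set.seed(4)
  mk_ring <- function(id, shift = 0) {
    u <- rnorm(1, 0, 0.3)   # shared ring effect -> strong clustering
    tibble::tibble(ring = id, value = rnorm(30, u + shift, 0.2))
  }
  null_dat <- dplyr::bind_rows(
    lapply(1:12, function(i) dplyr::mutate(mk_ring(paste0("a", i)), g = "a")),
    lapply(1:12, function(i) dplyr::mutate(mk_ring(paste0("b", i)), g = "b")))
  p_null <- ks_permutation(null_dat$value, null_dat$ring, null_dat$g,
                           n_perm = 199, seed = 1)$p_value
  expect_gt(p_null, 0.01)

  shift_dat <- dplyr::bind_rows(
    lapply(1:12, function(i) dplyr::mutate(mk_ring(paste0("a", i)), g = "a")),
    lapply(1:12, function(i) dplyr::mutate(mk_ring(paste0("b", i), shift = 1),
                                           g = "b")))
  p_shift <- ks_permutation(shift_dat$value, shift_dat$ring, shift_dat$g,
                            n_perm = 199, seed = 2)$p_value
  expect_lt(p_shift, 0.05)
})

test_that("the sorted-identity Gini matches the pairwise oracle", {
  expect_equal(gini(rep(7, 9)), 0)
  expect_equal(gini(c(0, 1)), 0.5)
  expect_equal(gini(c(1, 2, 3)), 8 / 36)
  expect_error(gini(c(-1, 2)), ">= 0")
  expect_error(gini(c(0, 0)), "positive sum")

  set.seed(5)
  for (i in 1:300) {
    x <- rlnorm(sample(2:80, 1), 0, runif(1, 0.1, 1.5))
    expect_equal(gini(x), gini_pairwise(x), tolerance = 1e-10)
  }
})

test_that("Gini bootstrap handles degenerate input and symmetric distributions", {
  expect_warning(gb <- gini_bootstrap(rep(2, 15), n_boot = 100, seed = 1),
                 "degenerate")
  expect_equal(gb$gini, c(0, 0))
  expect_equal(gb$ci_low, c(0, 0))
  expect_equal(gb$ci_high, c(0, 0))

  # near-symmetric sampling distribution: BCa ~ percentile
  set.seed(6)
  x <- rnorm(400, 100, 5)
  gb2 <- gini_bootstrap(x, n_boot = 2000, seed = 2)
  expect_lt(abs(gb2$ci_low[1] - gb2$ci_low[2]), 0.01)
  expect_lt(abs(gb2$ci_high[1] - gb2$ci_high[2]), 0.01)
  expect_true(all(gb2$ci_low <= gb2$gini & gb2$gini <= gb2$ci_high))
  expect_identical(tidy(gb2), tibble::as_tibble(gb2))
})

test_that("BCa and percentile intervals agree with an independent bootstrap implementation", {
  set.seed(9)
  x <- rlnorm(80, 0, 0.6)
  gb <- gini_bootstrap(x, n_boot = 4000, seed = 9)
  b <- boot::boot(x, function(d, i) gini(d[i]), R = 4000)
  ci <- boot::boot.ci(b, type = c("perc", "bca"))
  expect_equal(unlist(gb[gb$method == "percentile", c("ci_low", "ci_high")]),
               ci$percent[4:5], tolerance = 0.01, ignore_attr = TRUE)
  # boot's BCa acceleration uses regression empirical influence rather than
  # the jackknife; agreement is expected to Monte Carlo + method tolerance
  expect_lt(max(abs(unlist(gb[gb$method == "bca", c("ci_low", "ci_high")]) -
                      ci$bca[4:5])), 0.02)
})

test_that("phase assembly excludes drought neighbors and edge cases cleanly", {
  yrs <- 1990:2000
  ph <- qwanat:::phase_years(c(1995, 1996, 2000), yrs)
  expect_equal(ph$before, c(1994L, 1999L)) # 1995 precedes 1996 but is a drought
  expect_equal(ph$during, c(1995L, 1996L, 2000L))
  expect_equal(ph$after, 1997L)            # 2001 beyond record, 1996 a drought

  set.seed(7)
  profs <- dplyr::bind_rows(lapply(1990:2000, function(y) dplyr::bind_rows(
    mk_profiles(runif(100), tree = "t1", year = y, group = "pure"),
    mk_profiles(runif(100), tree = "t2", year = y, group = "pure"))))
  expect_message(
    res <- drought_phase_profiles(profs, c(2000L), n_perm = 99, seed = 1),
    "omitted")
  expect_false("after" %in% as.character(res$profiles$phase))
})

test_that("drought vs non-drought Gini table follows the stratification and flags planted variance", {
  set.seed(8)
  dy <- c(1995L, 2005L)
  profs <- dplyr::bind_rows(lapply(1990:2010, function(y) dplyr::bind_rows(
    mk_profiles(runif(100), tree = "t1", year = y, group = "pure"),
    mk_profiles(runif(100), tree = "t1", year = y, group = "mixed"))))
  rwi <- tidyr::expand_grid(tree_id = sprintf("t%d", 1:8), year = 1990:2010) %>%
    dplyr::mutate(group = "mixed",
                  rwi = ifelse(year %in% dy, rlnorm(dplyr::n(), 0, 0.45),
                               rlnorm(dplyr::n(), 0, 0.04)))
  tab <- drought_vs_nondrought_gini(profs, dy, rwi = rwi, n_boot = 500,
                                    seed = 3)
  expect_true(all(c("trait", "group", "drought", "gini", "ci_low", "ci_high")
                  %in% names(tab)))
  expect_equal(unique(tab$trait), c("AD", "RWI"))
  expect_true(all(tab$ci_low <= tab$gini & tab$gini <= tab$ci_high))
  r <- dplyr::filter(tab, trait == "RWI")
  expect_gt(r$gini[r$drought == "yes"], r$gini[r$drought == "no"])
  expect_gt(r$ci_low[r$drought == "yes"], r$ci_high[r$drought == "no"])
})

test_that("ring width indices centre on one per tree", {
  cfg <- tiny_config(seed = 10)
  d <- generate_cells(cfg, generate_climate(cfg))
  rwi <- ring_width_indices(d$rings)
  m <- tapply(rwi$rwi, rwi$tree_id, mean)
  expect_true(all(abs(m - 1) < 0.05))
})
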