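mk_climate <- function(tmean, prec = 50, years = 1:1 + 1999) {
  tidyr::expand_grid(year = years, month = 1:12) %>%
    dplyr::mutate(tmean_c = rep_len(tmean, dplyr::n()),
                  prec_mm = rep_len(prec, dplyr::n()))
}

test_that("Thornthwaite PET obeys the frozen-month rule and day-length seasonality", {
  cl <- thornthwaite_pet(mk_climate(-5), 45)
  expect_true(all(cl$pet_mm == 0))
  expect_equal(sum(thornthwaite_pet(mk_climate(0), 45)$pet_mm), 0)

  warm <- thornthwaite_pet(mk_climate(20), 45)
  expect_gt(warm$pet_mm[warm$month == 7], warm$pet_mm[warm$month == 1])
  # seasonality of the correction factor follows the day-length oracle
  ratio <- warm$pet_mm[warm$month == 7] / warm$pet_mm[warm$month == 1]
  oracle <- day_length_oracle(45, 196) * 31 / (day_length_oracle(45, 15) * 31)
  expect_equal(ratio, oracle, tolerance = 1e-10)

  expect_error(thornthwaite_pet(mk_climate(10), 70), "66.5")
})

test_that("water balance is the elementwise difference and validates its input", {
  cl <- mk_climate(10, prec = 60)
  cl <- thornthwaite_pet(cl, 50)
  cl$pet_mm <- 60
  expect_true(all(water_balance(cl)$d_mm == 0))
  cl$prec_mm <- 0; cl$pet_mm <- 80
  expect_true(all(water_balance(cl)$d_mm == -80))

  set.seed(1)
  cl$prec_mm <- runif(12, 0, 120); cl$pet_mm <- runif(12, 0, 90)
  expect_equal(water_balance(cl)$d_mm, cl$prec_mm - cl$pet_mm)
  expect_error(water_balance(cl[-3, ]), "contiguous")
})

test_that("SPEI standardizes each calendar month on a long stationary record", {
  cfg <- tiny_config(seed = 5,
                     climate = list(trend_c_per_decade = 0),
                     droughts = tibble::tibble(year = integer(),
                                               months = list(),
                                               anomaly_sd = numeric(),
                                               temp_anomaly_c = numeric()))
  bal <- water_balance(thornthwaite_pet(generate_climate(cfg), cfg$latitude))
  s3 <- spei(bal, 3)
  expect_true(all(is.na(s3$value[1:2])))
  st <- s3 %>% dplyr::filter(!is.na(value)) %>%
    dplyr::group_by(month) %>%
    dplyr::summarise(m = mean(value), s = sd(value))
  expect_true(all(abs(st$m) < 0.1))
  expect_true(all(st$s > 0.85 & st$s < 1.15))
})

test_that("SPEI is a monotone transform of the aggregated balance", {
  cfg <- tiny_config(seed = 6)
  bal <- water_balance(thornthwaite_pet(generate_climate(cfg), cfg$latitude))
  s1 <- spei(bal, 1)
  joined <- dplyr::left_join(bal, s1, by = c("year", "month")) %>%
    dplyr::filter(!is.na(value))
  rho <- joined %>% dplyr::group_by(month) %>%
    dplyr::summarise(r = cor(d_mm, value, method = "spearman"))
  expect_true(all(rho$r == 1))
  # the most negative aggregate maps to the most negative index
  s3 <- spei(bal, 3) %>% dplyr::filter(!is.na(value))
  agg <- as.numeric(stats::filter(bal$d_mm, rep(1, 3), sides = 1))
  bal$agg <- agg
  for (m in c(4, 7, 10)) {
    sub <- dplyr::filter(bal, month == m, !is.na(agg))
    v <- dplyr::filter(s3, month == m)
    expect_equal(v$year[which.min(v$value)], sub$year[which.min(sub$agg)])
  }
})

test_that("SPEI is invariant to a constant shift of the balance", {
  cfg <- tiny_config(seed = 7)
  bal <- water_balance(thornthwaite_pet(generate_climate(cfg), cfg$latitude))
  s_a <- spei(bal, 3)
  bal2 <- dplyr::mutate(bal, d_mm = d_mm + 123.4)
  s_b <- spei(bal2, 3)
  expect_lt(max(abs(s_a$value - s_b$value), na.rm = TRUE), 1e-6)
})

test_that("rolling aggregation telescopes exactly", {
  set.seed(8)
  d <- rnorm(240)
  for (k in c(3, 6)) {
    dk <- as.numeric(stats::filter(d, rep(1, k), sides = 1))
    m <- (k + 1):240
    expect_equal(dk[m] - dk[m - 1], d[m] - d[m - k])
  }
})

test_that("degenerate calibration months are refused", {
  cl <- mk_climate(10, prec = 50, years = 1960:2000)
  cl <- thornthwaite_pet(cl, 45)
  bal <- water_balance(cl)   # identical every year -> zero variance
  expect_error(spei(bal, 3), "variance|irregular")
})

test_that("drought years are flagged only inside the March-October window", {
  base <- tidyr::expand_grid(year = 1990:1999, month = 1:12) %>%
    dplyr::mutate(value = 0, scale = 3L)
  expect_length(flag_drought_years(base), 0L)

  one <- base
  one$value[one$year == 1990 & one$month == 6] <- -1.6
  expect_equal(as.integer(flag_drought_years(one)), 1990L)

  feb <- base
  feb$value[feb$year == 1991 & feb$month == 2] <- -2.0
  expect_length(flag_drought_years(feb), 0L)
})

test_that("lowering the drought threshold never adds years", {
  set.seed(9)
  s <- tidyr::expand_grid(year = 1960:2019, month = 1:12) %>%
    dplyr::mutate(value = rnorm(dplyr::n()), scale = 3L)
  thresholds <- c(-0.5, -1, -1.5, -2)
  flagged <- lapply(thresholds, function(th)
    as.integer(flag_drought_years(s, threshold = th)))
  for (i in 2:length(thresholds))
    expect_true(all(flagged[[i]] %in% flagged[[i - 1]]))
})

test_that("climate detrending yields unit-mean, trend-free indices", {
  cl <- mk_climate(10, prec = 50, years = 1960:2019)
  out <- detrend_climate(cl)
  expect_true(all(abs(out$index - 1) < 1e-10))

  set.seed(10)
  cl2 <- tidyr::expand_grid(year = 1960:2019, month = 1:12) %>%
    dplyr::mutate(tmean_c = 10 + 0.05 * (year - 1960) + rnorm(dplyr::n(), 0, 0.8),
                  prec_mm = 50 + 0.4 * (year - 1960) + rnorm(dplyr::n(), 0, 6))
  out2 <- detrend_climate(cl2)
  for (m in c(1, 6, 12)) {
    idx <- dplyr::filter(out2, variable == "prec_mm", month == m)
    fit <- summary(lm(index ~ year, data = idx))
    expect_gt(coef(fit)[2, 4], 0.05)
    expect_lt(abs(mean(idx$index) - 1), 0.02)
  }
})
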