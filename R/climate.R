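#' Thornthwaite monthly potential evapotranspiration
#'
#' The classic temperature-only PET estimate: an annual heat index
#' `I = sum((T/5)^1.514)` over months with `T > 0`, exponent
#' `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`, unadjusted
#' `PET = 16 (10 T / I)^a` mm (with the Willmott quadratic above 26.5 degC),
#' scaled by mean day length (from latitude and mid-month solar declination)
#' and month length.  Months at or below 0 degC evaporate nothing.
#'
#' @param climate Monthly climate tibble with `year`, `month`, `tmean_c`.
#' @param latitude Site latitude, degrees (|lat| <= 66.5: the day-length
#'   formula breaks poleward of the polar circles).
#' @return `climate` with an added `pet_mm` column.
#' @export
thornthwaite_pet <- function(climate, latitude) {
  assert_number(latitude, "latitude")
  if (abs(latitude) > 66.5)
    abort("|latitude| must be <= 66.5 degrees (day-length formula domain)")
  stopifnot(all(c("year", "month", "tmean_c") %in% names(climate)))
  if (any(is.na(climate$tmean_c)))
    abort("`tmean_c` must be present for all months")

  mid_doy <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  mdays <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  decl <- 0.409 * sin(2 * pi * mid_doy / 365 - 1.39)
  phi <- latitude * pi / 180
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  daylen <- 24 * ws / pi

  climate %>%
    group_by(.data$year) %>%
    mutate(.heat = sum((pmax(.data$tmean_c, 0) / 5)^1.514)) %>%
    ungroup() %>%
    mutate(
      .expo = 6.75e-7 * .data$.heat^3 - 7.71e-5 * .data$.heat^2 +
        1.792e-2 * .data$.heat + 0.49239,
      pet_mm = dplyr::case_when(
        .data$tmean_c <= 0 ~ 0,
        .data$tmean_c >= 26.5 ~
          -415.85 + 32.24 * .data$tmean_c - 0.43 * .data$tmean_c^2,
        .data$.heat == 0 ~ 0,
        TRUE ~ 16 * (10 * .data$tmean_c / .data$.heat)^.data$.expo
      ) * (daylen[.data$month] / 12) * (mdays[.data$month] / 30)
    ) %>%
    select(-".heat", -".expo")
}

check_contiguous_months <- function(climate) {
  idx <- climate$year * 12 + climate$month
  if (anyDuplicated(idx)) abort("duplicated year-month rows")
  if (!all(diff(sort(idx)) == 1)) abort("months must be contiguous with no gaps")
  invisible(TRUE)
}

#' Monthly climatic water balance
#'
#' `D = P - PET`, the input to SPEI.  PET must already be present (e.g. from
#' [thornthwaite_pet()]).
#'
#' @param climate Tibble with `year`, `month`, `prec_mm`, `pet_mm`,
#'   contiguous months.
#' @return `climate` with an added `d_mm` column.
#' @export
water_balance <- function(climate) {
  stopifnot(all(c("year", "month", "prec_mm", "pet_mm") %in% names(climate)))
  check_contiguous_months(climate)
  if (any(is.na(climate$prec_mm)) || any(is.na(climate$pet_mm)))
    abort("precipitation and PET must be complete")
  mutate(climate, d_mm = .data$prec_mm - .data$pet_mm)
}

# Unbiased probability-weighted moments (a-type: E[X (1-F)^r]) and the
# 3-parameter log-logistic fit used for SPEI standardization.
fit_loglogistic_pwm <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 4L) abort("need at least 4 values to fit the log-logistic")
  if (sd(x) == 0)
    abort("degenerate distribution: zero variance in calibration values")
  j <- seq_len(n)
  b0 <- mean(x)
  b1 <- mean((n - j) / (n - 1) * x)
  b2 <- mean((n - j) * (n - j - 1) / ((n - 1) * (n - 2)) * x)
  # negative beta (with negative alpha) is the mirrored, upper-bounded
  # branch that PWMs select for left-skewed samples
  beta <- (2 * b1 - b0) / (6 * b1 - b0 - 6 * b2)
  if (!is.finite(beta) || abs(beta) <= 1)
    abort("log-logistic shape fit failed (|beta| <= 1): calibration sample too irregular")
  g12 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (b0 - 2 * b1) * beta / g12
  gam <- b0 - alpha * g12
  if (!is.finite(alpha) || alpha == 0 || sign(alpha) != sign(beta))
    abort("log-logistic scale fit failed: calibration sample too irregular")
  c(alpha = alpha, beta = beta, gamma = gam)
}

ploglogistic <- function(x, par) {
  z <- (x - par[["gamma"]]) / par[["alpha"]]
  # out of support: below the lower bound (alpha > 0) or above the upper
  # bound (mirrored fit, alpha < 0)
  out <- if (par[["alpha"]] > 0) 0 else 1
  p <- ifelse(z > 0, 1 / (1 + z^(-par[["beta"]])), out)
  pmin(pmax(p, 1e-8), 1 - 1e-8)
}

#' Standardized Precipitation Evapotranspiration Index
#'
#' For each month, the water balance is aggregated over the current and
#' previous `scale - 1` months; a 3-parameter log-logistic distribution is
#' fitted per calendar month over the calibration years by unbiased
#' probability-weighted moments; SPEI is the standard-normal quantile of the
#' fitted cumulative probability.  The first `scale - 1` months of the
#' record are undefined.
#'
#' @param balance Tibble with `year`, `month`, `d_mm` (from
#'   [water_balance()]), contiguous months.
#' @param scale Aggregation window in months (3 and 6 are the usual
#'   choices; any `k >= 1` is accepted).
#' @param calibration Optional `c(first, last)` year range for the fit;
#'   default is the full record (at least 30 years recommended).
#' @return A tibble `year`, `month`, `scale`, `value`.
#' @export
spei <- function(balance, scale = 3L, calibration = NULL) {
  stopifnot(all(c("year", "month", "d_mm") %in% names(balance)))
  assert_number(scale, "scale", positive = TRUE)
  scale <- as.integer(scale)
  balance <- arrange(balance, .data$year, .data$month)
  check_contiguous_months(balance)

  dk <- as.numeric(stats::filter(balance$d_mm, rep(1, scale), sides = 1))
  out <- tibble(year = balance$year, month = balance$month,
                scale = scale, agg = dk)

  cal_years <- if (is.null(calibration)) range(out$year)
               else as.integer(calibration)
  n_cal <- cal_years[2] - cal_years[1] + 1L
  if (n_cal < 30L)
    warn(paste0("only ", n_cal, " calibration years; at least 30 recommended"))

  out <- out %>%
    group_by(.data$month) %>%
    mutate(value = {
      cal <- .data$agg[.data$year >= cal_years[1] & .data$year <= cal_years[2] &
                         !is.na(.data$agg)]
      if (length(cal) == 0L) rep(NA_real_, length(.data$agg))
      else {
        par <- fit_loglogistic_pwm(cal)
        qnorm(ploglogistic(.data$agg, par))
      }
    }) %>%
    ungroup()
  select(out, "year", "month", "scale", "value")
}

#' Flag severe drought years from a 3-month SPEI series
#'
#' A year counts as a drought year when the index drops below the threshold
#' in any month of the growing-season window (March-October by default).
#'
#' @param spei_series Tibble `year`, `month`, `value` (and optionally
#'   `scale`) as returned by [spei()]; intended for the 3-month scale.
#' @param threshold Drought threshold (default -1.5, severe drought).
#' @param months Window of months scanned (default `3:10`).
#' @return Sorted integer vector of drought years, with the threshold,
#'   window and scale attached as attributes.
#' @export
flag_drought_years <- function(spei_series, threshold = -1.5, months = 3:10) {
  stopifnot(all(c("year", "month", "value") %in% names(spei_series)))
  if ("scale" %in% names(spei_series) &&
      any(spei_series$scale != 3L, na.rm = TRUE))
    warn("drought years are conventionally flagged on the 3-month scale")
  yrs <- spei_series %>%
    filter(.data$month %in% months, !is.na(.data$value),
           .data$value < threshold) %>%
    pull(.data$year)
  structure(sort(unique(yrs)), threshold = threshold, months = months,
            scale = if ("scale" %in% names(spei_series))
              unique(spei_series$scale) else NA_integer_)
}

#' Detrend monthly climate series like the trait chronologies
#'
#' Each variable's interannual series for each calendar month is detrended
#' with the same spline procedure as the tree-ring series
#' ([detrend_series()], 30-year cutoff): ratio indices for strictly positive
#' series, difference indices (re-centered on the series mean) for series
#' that touch or cross zero, for which a ratio is undefined.
#'
#' @param climate Monthly tibble with `year`, `month` and the variable
#'   columns.
#' @param vars Columns to detrend (default temperature and precipitation).
#' @param cutoff Spline 50% frequency-response cutoff, years.
#' @return A long tibble `variable`, `year`, `month`, `index`.
#' @export
detrend_climate <- function(climate, vars = c("tmean_c", "prec_mm"),
                            cutoff = 30) {
  stopifnot(all(c("year", "month") %in% names(climate)),
            all(vars %in% names(climate)))
  n_years <- dplyr::n_distinct(climate$year)
  if (n_years < 35L)
    warn("fewer than 35 years per calendar month; detrending is poorly constrained")
  climate %>%
    select(all_of(c("year", "month", vars))) %>%
    tidyr::pivot_longer(all_of(vars), names_to = "variable",
                        values_to = "value") %>%
    arrange(.data$variable, .data$month, .data$year) %>%
    group_by(.data$variable, .data$month) %>%
    mutate(index = detrend_series(.data$value, cutoff = cutoff,
                                  method = "auto")) %>%
    ungroup() %>%
    select("variable", "year", "month", "index")
}
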