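#' Cubic smoothing spline with a 50% frequency-response cutoff
#'
#' Discrete penalized-least-squares smoother (second-difference penalty)
#' whose smoothing parameter is set in closed form so that a sinusoid of
#' wavelength `cutoff` years is attenuated to exactly 50% amplitude in the
#' interior of the series -- the standard dendrochronological
#' parameterization of the cubic smoothing spline.  Longer wavelengths pass
#' nearly untouched, shorter ones are removed, and the response is monotone
#' in frequency.
#'
#' @param y Annual series, no missing values.
#' @param cutoff Wavelength (years) attenuated to 50% amplitude (default 30).
#' @return Fitted values, same length as `y`.  Series shorter than 5 return
#'   their mean with a warning.
#' @export
cp_spline <- function(y, cutoff = 30) {
  if (any(is.na(y))) abort("series must not contain missing values")
  assert_number(cutoff, "cutoff", positive = TRUE)
  n <- length(y)
  if (n < 5L) {
    warn("series shorter than 5: returning the series mean as fit")
    return(rep(mean(y), n))
  }
  lambda <- 1 / (2 * sin(pi / cutoff))^4
  D <- diff(diag(n), differences = 2)
  A <- diag(n) + lambda * crossprod(D)
  as.numeric(solve(A, y))
}

#' Ratio detrending of an annual series
#'
#' Index = raw / fitted.  Non-positive fitted values are floored at 5% of
#' the series mean (with a warning) so the ratio stays defined; an all-zero
#' series is refused.
#'
#' @param raw Raw annual values.
#' @param fit Fitted values (e.g. from [cp_spline()]).
#' @return Dimensionless index values with mean near 1.
#' @export
detrend_ratio <- function(raw, fit) {
  if (length(raw) != length(fit)) abort("`raw` and `fit` lengths differ")
  if (all(raw == 0, na.rm = TRUE)) abort("cannot ratio-detrend an all-zero series")
  floor_val <- 0.05 * mean(abs(raw), na.rm = TRUE)
  if (any(fit <= 0, na.rm = TRUE)) {
    warn("non-positive fitted values floored for ratio detrending")
    fit <- pmax(fit, floor_val)
  }
  raw / fit
}

#' Spline-detrend an annual series
#'
#' Fits [cp_spline()] and returns ratio indices (`method = "ratio"`),
#' difference indices re-centered on the series mean
#' (`method = "difference"`), or picks automatically (`"auto"`: ratio when
#' raw values and fit are strictly positive, difference otherwise -- e.g.
#' winter temperatures crossing 0 degC).
#'
#' @param x Annual values (no interior missing values).
#' @param cutoff Spline cutoff in years.
#' @param method `"ratio"`, `"difference"` or `"auto"`.
#' @return Index series, same length as `x`.
#' @export
detrend_series <- function(x, cutoff = 30,
                           method = c("ratio", "difference", "auto")) {
  method <- match.arg(method)
  fit <- cp_spline(x, cutoff)
  if (method == "auto")
    method <- if (all(x > 0) && all(fit > 0)) "ratio" else "difference"
  if (method == "ratio") detrend_ratio(x, fit)
  else x - fit + mean(x)
}

#' Remove serial autocorrelation from an index series
#'
#' Fits an autoregressive model with the order chosen by AIC among
#' `0..min(10, n/4)` (least-squares fit) and returns the residuals
#' re-centered on the series mean, so the prewhitened chronology keeps its
#' interpretable level.  The first `order` values are undefined.  Series
#' that are too short or (near-)constant pass through unchanged (order 0).
#'
#' @param x Annual index values (>= 10 for a fit).
#' @return Residual series, same length as `x`, with the selected order
#'   attached as attribute `"order"`.
#' @export
prewhiten <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x, na.rm = TRUE) < 1e-10) {
    return(structure(x, order = 0L))
  }
  p_max <- min(10L, n %/% 4L)
  fit <- tryCatch(
    ar(x, aic = TRUE, order.max = p_max, method = "ols"),
    error = function(e) NULL)
  if (is.null(fit) || fit$order == 0L) return(structure(x, order = 0L))
  res <- as.numeric(fit$resid) + mean(x)
  structure(res, order = fit$order)
}

#' Tukey biweight robust mean
#'
#' Iteratively reweighted robust location with biweight weights
#' `(1 - u^2)^2`, `u = (x - m) / (9 MAD)` (raw median absolute deviation),
#' iterated to a 1e-8 tolerance.  Zero MAD (e.g. a majority of identical
#' values) returns the median; a single value returns itself.
#'
#' @param x Numeric values (NAs dropped).
#' @return The robust mean (scalar).
#' @export
biweight_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (length(x) == 1L) return(x)
  m <- median(x)
  s <- 9 * mad(x, constant = 1)
  if (s == 0) return(m)
  for (i in 1:100) {
    u <- (x - m) / s
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < 1e-8) return(m_new)
    m <- m_new
  }
  m
}

#' Build a detrended, prewhitened, robust-mean trait chronology
#'
#' Per tree: spline ratio-detrending ([detrend_series()]) of the annual
#' trait series, then AR prewhitening ([prewhiten()]).  Per year: Tukey
#' biweight robust mean across trees, with the number of contributing trees
#' as sample depth.
#'
#' @param annual Annual trait records ([aggregate_annual()]) or any tibble
#'   with `tree_id`, `year` and the trait column; filter to one ring part
#'   (and forest type) first or pass `part`.
#' @param trait Column to build the chronology from (e.g. `"ad"`, `"cwt"`,
#'   `"dh"`, `"width"`).
#' @param part Optional ring part (`"EW"`/`"LW"`) to filter on.
#' @param cutoff Spline cutoff, years.
#' @param prewhiten Prewhiten each tree's index series (default TRUE).
#' @return A `qwa_chronology` tibble: `year`, `index`, `sample_depth`.
#' @export
build_chronology <- function(annual, trait, part = NULL, cutoff = 30,
                             prewhiten = TRUE) {
  stopifnot(all(c("tree_id", "year", trait) %in% names(annual)))
  if (!is.null(part)) annual <- filter(annual, .data$part == !!part)
  pw <- prewhiten

  per_tree <- annual %>%
    select("tree_id", "year", value = all_of(trait)) %>%
    filter(!is.na(.data$value)) %>%
    arrange(.data$tree_id, .data$year) %>%
    group_by(.data$tree_id) %>%
    filter(n() >= 5L) %>%
    mutate(index = {
      if (any(diff(.data$year) != 1L))
        abort("per-tree series must be contiguous in years")
      idx <- detrend_series(.data$value, cutoff = cutoff, method = "ratio")
      if (pw) as.numeric(qwanat::prewhiten(idx)) else idx
    }) %>%
    ungroup()

  chron <- per_tree %>%
    filter(!is.na(.data$index)) %>%
    group_by(.data$year) %>%
    summarise(index = biweight_mean(.data$index),
              sample_depth = dplyr::n_distinct(.data$tree_id),
              .groups = "drop") %>%
    arrange(.data$year)
  structure(chron, class = c("qwa_chronology", class(chron)),
            trait = trait, part = part, cutoff = cutoff, prewhitened = pw)
}

#' @export
glance.qwa_chronology <- function(x, ...) {
  tibble(trait = attr(x, "trait") %||% NA_character_,
         part = attr(x, "part") %||% NA_character_,
         n_years = nrow(x),
         first_year = min(x$year), last_year = max(x$year),
         mean_index = mean(x$index, na.rm = TRUE),
         mean_sample_depth = mean(x$sample_depth),
         cutoff = attr(x, "cutoff") %||% NA_real_)
}

#' @export
autoplot.qwa_chronology <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$index)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Index",
                  title = paste(attr(object, "part"), attr(object, "trait"),
                                "chronology")) +
    ggplot2::theme_minimal()
}

#' Bootstrapped Pearson correlation
#'
#' Pearson r with a case-resampling bootstrap percentile confidence
#' interval; significant when the interval excludes zero.
#'
#' @param x,y Paired numeric vectors.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param alpha Significance level (default 0.05, i.e. a 95% interval).
#' @param seed Optional integer seed for the resampling.
#' @return One-row tibble: `r`, `ci_low`, `ci_high`, `significant`, `n`.
#' @export
boot_cor <- function(x, y, n_boot = 1000L, alpha = 0.05, seed = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 paired observations")
  r <- cor(x, y)
  rb <- with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    xs <- matrix(x[idx], n)
    ys <- matrix(y[idx], n)
    mx <- colMeans(xs); my <- colMeans(ys)
    sxy <- colSums(xs * ys) - n * mx * my
    sxx <- colSums(xs^2) - n * mx^2
    syy <- colSums(ys^2) - n * my^2
    den <- sqrt(sxx * syy)
    ifelse(den > 0, sxy / den, NA_real_)
  })
  ci <- quantile(rb, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
  tibble(r = r, ci_low = ci[1], ci_high = ci[2],
         significant = ci[1] > 0 | ci[2] < 0, n = n)
}

month_window <- function() {
  tibble(
    lag = c(rep(1L, 10L), rep(0L, 10L)),
    month = c(3:12, 1:10),
    label = c(paste0("prev_", tolower(month.abb[3:12])),
              paste0("cur_", tolower(month.abb[1:10])))
  )
}

#' Monthly climate-trait correlations over a 20-month window
#'
#' Correlates a trait chronology with monthly temperature, precipitation
#' and (optionally) the 6-month SPEI from March of the previous year
#' through October of the current year.  Climate variables are first
#' detrended per calendar month exactly like the trait series
#' ([detrend_climate()]); each correlation gets a case-resampling bootstrap
#' percentile interval ([boot_cor()]).
#'
#' @param chronology A [build_chronology()] result (or tibble with `year`,
#'   `index`).
#' @param climate Monthly climate tibble (`year`, `month`, `tmean_c`,
#'   `prec_mm`).
#' @param spei6 Optional [spei()] result at the 6-month scale.
#' @param n_boot,alpha,seed Bootstrap settings (see [boot_cor()]).
#' @param detrend Detrend the climate variables first (default TRUE).
#' @param cutoff Spline cutoff used for climate detrending.
#' @param min_overlap Minimum chronology-climate overlap in years
#'   (default 25); shorter overlaps are refused.
#' @return A `qwa_correlation` tibble: `variable`, `label`, `lag`, `month`,
#'   `r`, `ci_low`, `ci_high`, `significant`, `n`.
#' @export
correlate_monthly <- function(chronology, climate, spei6 = NULL,
                              n_boot = 1000L, alpha = 0.05, seed = NULL,
                              detrend = TRUE, cutoff = 30,
                              min_overlap = 25L) {
  stopifnot(all(c("year", "index") %in% names(chronology)))
  monthly <- if (detrend) {
    detrend_climate(climate, cutoff = cutoff) %>%
      mutate(variable = dplyr::recode(.data$variable,
                                      tmean_c = "temperature",
                                      prec_mm = "precipitation"))
  } else {
    climate %>%
      select("year", "month", temperature = "tmean_c",
             precipitation = "prec_mm") %>%
      tidyr::pivot_longer(c("temperature", "precipitation"),
                          names_to = "variable", values_to = "index")
  }
  if (!is.null(spei6)) {
    sp <- spei6 %>%
      select("year", "month", value = "value") %>%
      mutate(variable = "spei6")
    if (detrend) {
      sp <- sp %>%
        filter(!is.na(.data$value)) %>%
        arrange(.data$month, .data$year) %>%
        group_by(.data$month) %>%
        mutate(index = detrend_series(.data$value, cutoff = cutoff,
                                      method = "difference")) %>%
        ungroup()
    } else sp$index <- sp$value
    monthly <- bind_rows(monthly, select(sp, "variable", "year", "month",
                                         "index"))
  }

  win <- month_window()
  grid <- tidyr::expand_grid(variable = unique(monthly$variable), win)
  seeds <- with_seed(seed, sample.int(2^30, nrow(grid)))
  res <- purrr::pmap(list(grid$variable, grid$lag, grid$month, seeds),
    function(v, lag, m, s) {
      pred <- monthly %>% filter(.data$variable == v, .data$month == m)
      dat <- chronology %>%
        mutate(pred_year = .data$year - lag) %>%
        left_join(pred, by = c(pred_year = "year"))
      ok <- !is.na(dat$index.x) & !is.na(dat$index.y)
      if (sum(ok) < min_overlap)
        abort(paste0("chronology-climate overlap is ", sum(ok),
                     " years; need at least ", min_overlap))
      boot_cor(dat$index.x[ok], dat$index.y[ok], n_boot = n_boot,
               alpha = alpha, seed = s)
    })
  out <- dplyr::bind_cols(select(grid, "variable", "label", "lag", "month"),
                          bind_rows(res))
  structure(out, class = c("qwa_correlation", class(out)),
            alpha = alpha, n_boot = n_boot,
            trait = attr(chronology, "trait"),
            part = attr(chronology, "part"))
}

#' @export
glance.qwa_correlation <- function(x, ...) {
  tibble(n_tests = nrow(x),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         n_boot = attr(x, "n_boot"))
}

#' @export
autoplot.qwa_correlation <- function(object, ...) {
  df <- object %>%
    mutate(label = factor(.data$label, levels = month_window()$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$r,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.3, linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
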