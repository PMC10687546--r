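#' Configuration for the synthetic wood-anatomy dataset generator
#'
#' Bundles every knob of the generator: climate normals and variability,
#' planted drought events, admixture-dependent anatomical drought effects,
#' and the ontogenetic (age-trend and intra-ring gradient) parameters.  The
#' defaults emulate an even-aged Scots pine trial under a warm-summer
#' continental climate: 62 years, nine trees in a pure and nine in a mixed
#' stand, roughly 300 measured tracheids per ring, six planted severe spring
#' droughts, and a 15% earlywood wall-thickening legacy in the pure group
#' the year after each drought (no effect in the mixed group).
#'
#' @param seed Integer root seed; all generator randomness flows from it via
#'   named substreams, so a fixed config is byte-reproducible.
#' @param n_years Number of simulated calendar years (>= 35, so that spline
#'   detrending at a 30-year cutoff and SPEI calibration are meaningful).
#' @param start_year First calendar year.
#' @param trees_per_group Trees per forest type (pure / mixed).
#' @param cells_per_ring Tracheids measured per annual ring.
#' @param latitude Site latitude in degrees (used for potential
#'   evapotranspiration downstream).
#' @param climate List: `tmean_normals` (12 monthly mean temperatures, degC),
#'   `prec_normals` (12 monthly precipitation sums, mm, >= 0), `tmean_sd`
#'   (interannual sd, degC), `prec_cv` (interannual coefficient of variation
#'   of precipitation), `trend_c_per_decade` (linear warming trend).
#' @param droughts Data frame of planted drought events: `year`, `months`
#'   (list-column of month numbers), `anomaly_sd` (precipitation shift in
#'   units of the month's interannual sd; negative = dry), `temp_anomaly_c`
#'   (additive temperature anomaly, degC).
#' @param effects List with elements `pure` and `mixed`, each a named vector
#'   `c(during = , after = )` of multipliers applied to expected earlywood
#'   cell wall thickness (hence anatomical density) in drought years and the
#'   year after.  Must be > 0; 1 means no effect.
#' @param ontogeny List of ring and cell-scale parameters: negative
#'   exponential ring-width age trend (`rw_max_mm`, `rw_floor_mm`,
#'   `rw_tau_years`, `rw_noise_sd`, `rw_climate_sens`), earlywood/latewood
#'   gradient endpoints (`d_ew_um`, `d_lw_um` lumen diameters; `cwt_ew_um`,
#'   `cwt_lw_um` wall thicknesses), logistic transition (`transition_pos`,
#'   `transition_width`), and lognormal cell noise (`lumen_noise_sd`,
#'   `wall_noise_sd`).
#' @return An object of class `qwa_config` (a validated list).
#' @seealso [generate_climate()], [generate_cells()],
#'   [write_synthetic_dataset()]
#' @export
synthetic_config <- function(seed = 1L,
                             n_years = 62L,
                             start_year = 1958L,
                             trees_per_group = 9L,
                             cells_per_ring = 300L,
                             latitude = 51.8,
                             climate = list(),
                             droughts = NULL,
                             effects = list(),
                             ontogeny = list()) {
  assert_number(seed, "seed")
  assert_number(n_years, "n_years", positive = TRUE)
  assert_number(trees_per_group, "trees_per_group", positive = TRUE)
  assert_number(cells_per_ring, "cells_per_ring", positive = TRUE)
  assert_number(latitude, "latitude")

  clim <- utils::modifyList(list(
    tmean_normals = c(-2, -1, 2.6, 8, 13.5, 17, 19, 18, 13.5, 8.5, 3.5, -0.5),
    prec_normals = c(30, 28, 33, 38, 52, 68, 82, 70, 48, 42, 39, 35),
    tmean_sd = 1.5,
    prec_cv = 0.35,
    trend_c_per_decade = 0.3
  ), climate)
  if (length(clim$tmean_normals) != 12L || length(clim$prec_normals) != 12L)
    abort("climate normals must have 12 monthly values")
  if (any(clim$prec_normals < 0)) abort("precipitation normals must be >= 0")
  if (clim$tmean_sd < 0 || clim$prec_cv < 0)
    abort("climate variability parameters must be >= 0")

  if (is.null(droughts)) {
    yrs <- start_year + c(14L, 21L, 29L, 37L, 45L, 53L)
    yrs <- yrs[yrs <= start_year + n_years - 2L]
    droughts <- tibble(
      year = yrs,
      months = rep(list(4:6), length(yrs)),
      anomaly_sd = rep(-2.5, length(yrs)),
      temp_anomaly_c = rep(1.5, length(yrs))
    )
  }
  droughts <- as_tibble(droughts)
  if (nrow(droughts) > 0) {
    stopifnot(all(c("year", "months", "anomaly_sd") %in% names(droughts)))
    if (!"temp_anomaly_c" %in% names(droughts)) droughts$temp_anomaly_c <- 1.5
    if (any(droughts$year < start_year | droughts$year >= start_year + n_years))
      abort("planted drought years must fall within the simulated span")
  }

  eff <- utils::modifyList(list(
    pure = c(during = 1.0, after = 1.15),
    mixed = c(during = 1.0, after = 1.0)
  ), effects)
  for (g in c("pure", "mixed")) {
    if (!all(c("during", "after") %in% names(eff[[g]])))
      abort(paste0("effects$", g, " must name `during` and `after` multipliers"))
    if (any(eff[[g]] <= 0))
      abort("effect multipliers must be > 0")
  }

  ont <- utils::modifyList(list(
    rw_max_mm = 3, rw_floor_mm = 0.8, rw_tau_years = 25,
    rw_noise_sd = 0.15, rw_climate_sens = 0.1,
    d_ew_um = 26, d_lw_um = 11, cwt_ew_um = 3, cwt_lw_um = 5.5,
    transition_pos = 0.75, transition_width = 0.05,
    lumen_noise_sd = 0.25, wall_noise_sd = 0.15
  ), ontogeny)

  structure(list(
    seed = as.integer(seed), n_years = as.integer(n_years),
    start_year = as.integer(start_year),
    trees_per_group = as.integer(trees_per_group),
    cells_per_ring = as.integer(cells_per_ring),
    latitude = latitude, climate = clim, droughts = droughts,
    effects = eff, ontogeny = ont
  ), class = "qwa_config")
}

#' @export
print.qwa_config <- function(x, ...) {
  cat("<qwa_config> seed", x$seed, "|", x$n_years, "years from", x$start_year,
      "|", 2L * x$trees_per_group, "trees |", x$cells_per_ring, "cells/ring |",
      nrow(x$droughts), "planted droughts\n")
  invisible(x)
}

#' Generate a monthly climate table with planted droughts
#'
#' Simulates monthly mean temperature and precipitation from the config's
#' normals, interannual variability and warming trend, then superimposes the
#' planted drought anomalies (precipitation shifted by `anomaly_sd` times the
#' month's interannual sd, truncated at zero; temperature raised by
#' `temp_anomaly_c`).  Deterministic for a fixed config.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `year`, `month`, `tmean_c`, `prec_mm`.
#' @export
generate_climate <- function(config) {
  stopifnot(inherits(config, "qwa_config"))
  if (config$n_years < 35L)
    abort("n_years must be >= 35: the 30-year spline cutoff and SPEI calibration need a long record")
  cl <- config$climate
  years <- config$start_year + seq_len(config$n_years) - 1L
  out <- tidyr::expand_grid(year = years, month = 1:12)
  prec_sd <- cl$prec_cv * cl$prec_normals
  out <- with_seed(substream_seed(config$seed, "climate"), {
    out %>%
      mutate(
        tmean_c = cl$tmean_normals[.data$month] +
          cl$trend_c_per_decade * (.data$year - config$start_year) / 10 +
          rnorm(n(), 0, cl$tmean_sd),
        prec_mm = pmax(0, cl$prec_normals[.data$month] +
                          rnorm(n(), 0, prec_sd[.data$month]))
      )
  })
  if (nrow(config$droughts) > 0) {
    dr <- tidyr::unnest(config$droughts, "months") %>%
      rename(month = "months") %>%
      select("year", "month", "anomaly_sd", "temp_anomaly_c")
    out <- out %>%
      left_join(dr, by = c("year", "month")) %>%
      mutate(
        prec_mm = pmax(0, .data$prec_mm +
                          dplyr::coalesce(.data$anomaly_sd, 0) * prec_sd[.data$month]),
        tmean_c = .data$tmean_c + dplyr::coalesce(.data$temp_anomaly_c, 0)
      ) %>%
      select(-"anomaly_sd", -"temp_anomaly_c")
  }
  out
}

# logistic earlywood -> latewood transition along relative position
ew_lw_gradient <- function(p, ont) {
  1 / (1 + exp(-(p - ont$transition_pos) / ont$transition_width))
}

#' Generate tracheid and ring-width tables with known ground truth
#'
#' Simulates, per tree and year, a ring of tracheids whose expected lumen
#' diameter declines and wall thickness rises along the ring (logistic
#' earlywood-to-latewood gradient with lognormal cell noise), plus a
#' negative-exponential ring-width age trend with mild spring-precipitation
#' sensitivity.  In planted drought years and the year after, expected wall
#' thickness of earlywood-position cells is multiplied by the config's
#' group-specific effect, which raises earlywood anatomical density -- the
#' planted, recoverable signal for the legacy analyses.
#'
#' @param config A [synthetic_config()].
#' @param climate Monthly climate table from [generate_climate()]; must cover
#'   all simulated years.
#' @return A list with tibbles `cells` (`tree_id`, `plot_id`, `group`,
#'   `year`, `rel_pos`, `lumen_area_um2`, `cwt_rad_um`, `cwt_tan_um`,
#'   `cwa_um2`, `lumen_diam_rad_um`) and `rings` (`tree_id`, `plot_id`,
#'   `group`, `year`, `ring_width_mm`).
#' @export
generate_cells <- function(config, climate) {
  stopifnot(inherits(config, "qwa_config"))
  years <- config$start_year + seq_len(config$n_years) - 1L
  if (!all(years %in% climate$year))
    abort("climate table must cover all simulated years")
  ont <- config$ontogeny
  eff <- config$effects
  dy <- config$droughts$year

  ntr <- config$trees_per_group
  trees <- tibble(
    tree_id = c(sprintf("P%02d", seq_len(ntr)), sprintf("M%02d", seq_len(ntr))),
    group = rep(c("pure", "mixed"), each = ntr),
    plot_id = c(sprintf("PP%d", (seq_len(ntr) - 1L) %/% 3L + 1L),
                sprintf("MP%d", (seq_len(ntr) - 1L) %/% 3L + 1L))
  )

  # spring (Apr-Jun) precipitation anomaly as a mild ring-width driver
  spring <- climate %>%
    filter(.data$year %in% years, .data$month %in% 4:6) %>%
    group_by(.data$year) %>%
    summarise(p = sum(.data$prec_mm), .groups = "drop")
  z <- (spring$p - mean(spring$p)) / max(sd(spring$p), 1e-12)
  names(z) <- spring$year

  rings <- tidyr::expand_grid(trees, year = years) %>%
    mutate(age = .data$year - config$start_year + 1L)
  rings <- with_seed(substream_seed(config$seed, "rings"), {
    rings %>%
      mutate(ring_width_mm =
               (ont$rw_floor_mm + ont$rw_max_mm * exp(-.data$age / ont$rw_tau_years)) *
               exp(ont$rw_climate_sens * z[as.character(.data$year)]) *
               exp(rnorm(n(), 0, ont$rw_noise_sd) - ont$rw_noise_sd^2 / 2))
  })

  ncell <- config$cells_per_ring
  cells <- rings %>%
    select("tree_id", "plot_id", "group", "year") %>%
    tidyr::expand_grid(cell = seq_len(ncell))
  cells <- with_seed(substream_seed(config$seed, "cells"), {
    p <- (cells$cell - 1L + runif(nrow(cells))) / ncell
    s <- ew_lw_gradient(p, ont)
    d_exp <- ont$d_ew_um + (ont$d_lw_um - ont$d_ew_um) * s
    cwt_exp <- ont$cwt_ew_um + (ont$cwt_lw_um - ont$cwt_ew_um) * s
    phase <- ifelse(cells$year %in% dy, "during",
                    ifelse(cells$year %in% (dy + 1L), "after", "none"))
    mult <- rep(1, nrow(cells))
    idx <- phase != "none" & p < ont$transition_pos
    lut <- c(pure.during = eff$pure[["during"]], pure.after = eff$pure[["after"]],
             mixed.during = eff$mixed[["during"]], mixed.after = eff$mixed[["after"]])
    mult[idx] <- unname(lut[paste(cells$group[idx], phase[idx], sep = ".")])
    lumen <- (pi / 4) * d_exp^2 *
      exp(rnorm(nrow(cells), 0, ont$lumen_noise_sd) - ont$lumen_noise_sd^2 / 2)
    cwt_rad <- cwt_exp * mult *
      exp(rnorm(nrow(cells), 0, ont$wall_noise_sd) - ont$wall_noise_sd^2 / 2)
    cwt_tan <- cwt_exp * mult *
      exp(rnorm(nrow(cells), 0, ont$wall_noise_sd) - ont$wall_noise_sd^2 / 2)
    l <- sqrt(lumen)                    # square-lumen wall geometry
    cwa <- (l + cwt_rad + cwt_tan)^2 - lumen
    cells %>%
      mutate(rel_pos = p,
             lumen_area_um2 = lumen,
             cwt_rad_um = cwt_rad,
             cwt_tan_um = cwt_tan,
             cwa_um2 = cwa,
             lumen_diam_rad_um = 2 * sqrt(lumen / pi)) %>%
      select(-"cell")
  })
  list(cells = cells,
       rings = select(rings, "tree_id", "plot_id", "group", "year",
                      "ring_width_mm"))
}

#' Write a complete synthetic dataset to disk
#'
#' Generates climate, cells and ring widths for `config` and writes
#' `cells.csv`, `ring_widths.csv`, `climate.csv` and `ground_truth.json`
#' (planted drought years, effect multipliers, seed) into `dir`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated tables.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  climate <- generate_climate(config)
  dat <- generate_cells(config, climate)
  readr::write_csv(dat$cells, file.path(dir, "cells.csv"))
  readr::write_csv(dat$rings, file.path(dir, "ring_widths.csv"))
  readr::write_csv(climate, file.path(dir, "climate.csv"))
  gt <- list(seed = config$seed,
             drought_years = config$droughts$year,
             effects = config$effects,
             latitude = config$latitude)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(dat, list(climate = climate, ground_truth = gt)))
}
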