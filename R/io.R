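#' Read a tracheid cell table
#'
#' Reads the CSV cell-table dialect written by cell-measurement software
#' exports (and by [write_synthetic_dataset()]): one row per tracheid with
#' tree and year identifiers, relative radial position, lumen area and wall
#' geometry.  Rows violating the record invariants (`rel_pos` outside
#' `[0, 1)`, non-positive lumen area, negative wall thickness or wall area,
#' missing required fields) are rejected; the rejected rows, with their line
#' numbers, are attached as attribute `"rejected"` and counted in a message.
#' Unknown columns are dropped with a single warning.
#'
#' @param path CSV file path.
#' @return A tibble of valid cell records.
#' @export
read_cell_table <- function(path) {
  required <- c("tree_id", "year", "rel_pos", "lumen_area_um2",
                "cwt_rad_um", "cwt_tan_um", "cwa_um2")
  optional <- c("plot_id", "group", "lumen_diam_rad_um")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
    df <- select(df, -all_of(extra))
  }
  df <- mutate(df, .line = row_number() + 1L)
  ok <- !is.na(df$tree_id) & !is.na(df$year) &
    !is.na(df$rel_pos) & df$rel_pos >= 0 & df$rel_pos < 1 &
    !is.na(df$lumen_area_um2) & df$lumen_area_um2 > 0 &
    !is.na(df$cwt_rad_um) & df$cwt_rad_um >= 0 &
    !is.na(df$cwt_tan_um) & df$cwt_tan_um >= 0 &
    !is.na(df$cwa_um2) & df$cwa_um2 >= 0
  if (any(!ok))
    inform(paste0(sum(!ok), " malformed row(s) rejected (lines ",
                  paste(head(df$.line[!ok], 10L), collapse = ", "),
                  if (sum(!ok) > 10L) ", ..." else "", ")"))
  if (sum(ok) == 0L) abort("no valid cell records in file")
  out <- select(filter(df, ok), -".line")
  attr(out, "rejected") <- select(filter(df, !ok), line = ".line",
                                  dplyr::everything())
  out
}

#' Read a ring-width table
#'
#' @param path CSV with columns `tree_id`, `year`, `ring_width_mm`.
#' @return A tibble.
#' @export
read_ring_width_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("tree_id", "year", "ring_width_mm"), names(df))
  if (length(missing) > 0)
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")))
  df
}

#' Read a monthly climate table
#'
#' @param path CSV with columns `year`, `month`, `tmean_c`, `prec_mm`.
#' @return A tibble.
#' @export
read_climate_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("year", "month", "tmean_c", "prec_mm"), names(df))
  if (length(missing) > 0)
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")))
  df
}

#' Configuration of a full pipeline run
#'
#' Either synthetic (pass a [synthetic_config()]) or file-based (pass the
#' three input paths).  All analysis knobs of the downstream stages are
#' collected here; seeds recorded in the configuration drive every
#' stochastic stage, so a rerun with the same config reproduces the same
#' outputs.
#'
#' @param synthetic Optional [synthetic_config()]; when given, inputs are
#'   generated rather than read.
#' @param cells_path,rings_path,climate_path Input CSVs (file-based mode).
#' @param latitude Site latitude (defaults to the synthetic config's).
#' @param spline_cutoff Detrending cutoff, years.
#' @param spei_scales Aggregation scales; the first is used for drought
#'   flagging, the last for climate correlations.
#' @param drought_threshold SPEI threshold for drought years.
#' @param drought_months Window of months scanned for drought flagging.
#' @param calendar `"spei"` (flag droughts from the data) or
#'   `"ground_truth"` (synthetic mode only: use the planted years).
#' @param outlier_mode Outlier fence mode, see [filter_outliers()].
#' @param ks_mode Phase-contrast p-value mode, see
#'   [drought_phase_profiles()].
#' @param n_boot Bootstrap replicates for correlations.
#' @param gini_boot Bootstrap replicates for Gini intervals.
#' @param seed Root seed for all stochastic stages.
#' @param out_dir Optional output directory; when given, every stage output
#'   is written as CSV/JSON.
#' @return A `qwa_run_config` list.
#' @export
run_config <- function(synthetic = NULL, cells_path = NULL,
                       rings_path = NULL, climate_path = NULL,
                       latitude = NULL, spline_cutoff = 30,
                       spei_scales = c(3L, 6L), drought_threshold = -1.5,
                       drought_months = 3:10,
                       calendar = c("spei", "ground_truth"),
                       outlier_mode = c("tukey", "literal"),
                       ks_mode = c("permutation", "asymptotic"),
                       n_boot = 1000L, gini_boot = 2000L, seed = 1L,
                       out_dir = NULL) {
  calendar <- match.arg(calendar)
  outlier_mode <- match.arg(outlier_mode)
  ks_mode <- match.arg(ks_mode)
  if (is.null(synthetic)) {
    for (p in c(cells_path, rings_path, climate_path))
      if (!file.exists(p)) abort(paste0("input path does not exist: ", p))
    if (is.null(latitude))
      abort("`latitude` is required in file-based mode")
    if (calendar == "ground_truth")
      abort("`calendar = \"ground_truth\"` requires synthetic mode")
  } else {
    stopifnot(inherits(synthetic, "qwa_config"))
    latitude <- latitude %||% synthetic$latitude
  }
  structure(list(
    synthetic = synthetic, cells_path = cells_path, rings_path = rings_path,
    climate_path = climate_path, latitude = latitude,
    spline_cutoff = spline_cutoff, spei_scales = as.integer(spei_scales),
    drought_threshold = drought_threshold, drought_months = drought_months,
    calendar = calendar, outlier_mode = outlier_mode, ks_mode = ks_mode,
    n_boot = as.integer(n_boot), gini_boot = as.integer(gini_boot),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "qwa_run_config")
}

#' Run the full wood-anatomy analysis pipeline
#'
#' Chains ingest (synthetic or file), anatomy (sectorization, Mork
#' classification, outlier filtering, annual aggregation, sector profiles),
#' climate (PET, water balance, SPEI, drought calendar), per-group trait
#' chronologies with monthly climate correlations, and the intra-annual
#' statistics (normalized profiles, drought-legacy phase contrasts, Gini
#' table).  Every stochastic stage is seeded from the config, so reruns
#' with the same config are reproducible.
#'
#' @param config A [run_config()].
#' @return A list with elements `annual`, `chronologies`, `correlations`,
#'   `profiles`, `legacy`, `gini`, `spei`, `drought_years` and `report`
#'   (record counts per stage, configuration hash, warnings).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qwa_run_config"))
  warnings_log <- character()
  note <- function(...) {
    warnings_log <<- c(warnings_log, paste0(...))
  }

  # --- ingest -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    climate <- generate_climate(config$synthetic)
    dat <- generate_cells(config$synthetic, climate)
    cells <- dat$cells
    rings <- dat$rings
  } else {
    cells <- read_cell_table(config$cells_path)
    rings <- read_ring_width_table(config$rings_path)
    climate <- read_climate_table(config$climate_path)
  }
  n_read <- nrow(cells)

  # --- anatomy ------------------------------------------------------------
  cells <- classify_cells(cells)
  cells <- filter_outlier_cells(cells, mode = config$outlier_mode)
  outlier_log <- attr(cells, "outlier_log")
  n_outliers <- sum(outlier_log$n_removed)
  annual <- aggregate_annual(cells, rings)
  profiles <- build_sector_profiles(cells)
  nprof <- minmax_normalize(profiles)

  # --- climate / drought --------------------------------------------------
  climate <- thornthwaite_pet(climate, config$latitude)
  balance <- water_balance(climate)
  spei_tabs <- purrr::map(config$spei_scales,
                          ~ spei(balance, scale = .x))
  names(spei_tabs) <- paste0("spei", config$spei_scales)
  flagged <- flag_drought_years(spei_tabs[[1]],
                                threshold = config$drought_threshold,
                                months = config$drought_months)
  drought_years <- if (config$calendar == "ground_truth")
    config$synthetic$droughts$year else as.integer(flagged)

  # --- chronologies and climate correlations ------------------------------
  groups <- if ("group" %in% names(annual)) unique(annual$group) else NA
  spei_hi <- spei_tabs[[length(spei_tabs)]]
  combos <- tidyr::expand_grid(group = groups,
                               trait = c("dh", "cwt", "ad"),
                               part = c("EW", "LW"))
  seeds <- with_seed(substream_seed(config$seed, "boot"),
                     sample.int(2^30, nrow(combos)))
  chronologies <- purrr::pmap(combos, function(group, trait, part) {
    a <- if (is.na(group)) annual else filter(annual, .data$group == group)
    build_chronology(a, trait = trait, part = part,
                     cutoff = config$spline_cutoff)
  })
  correlations <- purrr::map2(chronologies, seeds, function(ch, s) {
    correlate_monthly(ch, climate, spei6 = spei_hi, n_boot = config$n_boot,
                      seed = s, cutoff = config$spline_cutoff)
  })
  names(chronologies) <- names(correlations) <-
    paste(combos$group, combos$part, combos$trait, sep = ".")
  correlations_tab <- purrr::imap(correlations, function(x, nm) {
    mutate(as_tibble(x), chronology = nm)
  }) %>% bind_rows()

  # --- intra-annual statistics --------------------------------------------
  legacy <- drought_phase_profiles(nprof, drought_years,
                                   ks = config$ks_mode,
                                   seed = substream_seed(config$seed, "perm"))
  rwi <- ring_width_indices(rings, cutoff = config$spline_cutoff)
  gini_tab <- drought_vs_nondrought_gini(nprof, drought_years, rwi = rwi,
                                         n_boot = config$gini_boot,
                                         seed = substream_seed(config$seed,
                                                               "boot"))

  report <- list(
    package_version = as.character(utils::packageVersion("qwanat")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    n_cells_read = n_read,
    n_cells_outlier_removed = n_outliers,
    n_cells_kept = nrow(cells),
    n_rings = nrow(rings),
    n_trees = dplyr::n_distinct(cells$tree_id),
    years = range(rings$year),
    drought_years_flagged = as.integer(flagged),
    drought_years_used = drought_years,
    calendar = config$calendar,
    warnings = warnings_log
  )

  out <- list(annual = annual, profiles = nprof, chronologies = chronologies,
              correlations = correlations_tab, legacy = legacy,
              gini = gini_tab, spei = bind_rows(spei_tabs),
              drought_years = drought_years, report = report)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(annual, file.path(config$out_dir, "annual_traits.csv"))
    readr::write_csv(correlations_tab,
                     file.path(config$out_dir, "correlations.csv"))
    readr::write_csv(as_tibble(legacy$profiles),
                     file.path(config$out_dir, "phase_profiles.csv"))
    readr::write_csv(legacy$ks, file.path(config$out_dir, "phase_ks.csv"))
    readr::write_csv(gini_tab, file.path(config$out_dir, "gini_table.csv"))
    readr::write_csv(out$spei, file.path(config$out_dir, "spei.csv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Write sector profiles in wide format
#'
#' One row per tree, year and trait with columns `sector_001..sector_N`.
#'
#' @param profiles Long profile tibble.
#' @param path Output CSV path.
#' @return Invisibly, the wide tibble.
#' @export
write_sector_profiles <- function(profiles, path) {
  wide <- profiles %>%
    mutate(sector = sprintf("sector_%03d", .data$sector)) %>%
    tidyr::pivot_wider(names_from = "sector", values_from = "value")
  readr::write_csv(wide, path)
  invisible(wide)
}
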