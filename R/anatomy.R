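#' Per-cell hydraulic diameter
#'
#' Equivalent-circle diameter of a conduit lumen, `d = 2 * sqrt(A / pi)`,
#' the per-cell diameter that feeds the hydraulically weighted ring mean
#' ([mean_hydraulic_diameter()]).
#'
#' @param lumen_area Lumen area, um^2 (> 0; vectorized).
#' @return Diameter in um.
#' @export
cell_hydraulic_diameter <- function(lumen_area) {
  if (any(!is.finite(lumen_area)) || any(lumen_area <= 0))
    abort("`lumen_area` must be > 0")
  2 * sqrt(lumen_area / pi)
}

#' Hydraulically weighted mean conduit diameter (DH)
#'
#' `DH = sum(d^5) / sum(d^4)` over the conduit diameters of a ring (or ring
#' part).  Weighting by the fourth power reflects the Hagen-Poiseuille
#' dependence of conductivity on diameter, so wide conduits dominate.  Always
#' at least the arithmetic mean of `d` (power-mean inequality).
#'
#' @param d Vector of conduit diameters, um (non-empty, all > 0).
#' @return The hydraulic mean diameter, um.
#' @examples
#' mean_hydraulic_diameter(c(10, 20)) # 3.3e6 / 1.7e5 = 19.4118
#' @export
mean_hydraulic_diameter <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(NA_real_)
  if (any(d <= 0)) abort("diameters must be > 0")
  sum(d^5) / sum(d^4)
}

#' Mean cell wall thickness (CWT)
#'
#' Average of the radial and tangential wall thickness of a cell.
#'
#' @param cwt_rad,cwt_tan Radial and tangential single-wall thickness, um
#'   (>= 0; vectorized).
#' @return `(cwt_rad + cwt_tan) / 2`, um.
#' @export
cell_cwt <- function(cwt_rad, cwt_tan) {
  if (any(cwt_rad < 0, na.rm = TRUE) || any(cwt_tan < 0, na.rm = TRUE))
    abort("wall thicknesses must be >= 0")
  (cwt_rad + cwt_tan) / 2
}

#' Anatomical wood density (AD)
#'
#' `AD = CWA / (CWA + LA)`: the wall-area fraction of the cell, a
#' cell-geometry proxy for wood density, in `[0, 1]`.
#'
#' @param cwa Cell wall area, um^2 (>= 0; vectorized).
#' @param lumen_area Lumen area, um^2 (>= 0).
#' @return Dimensionless density in `[0, 1]`; both-zero input is an error.
#' @export
anatomical_density <- function(cwa, lumen_area) {
  if (any(cwa < 0, na.rm = TRUE) || any(lumen_area < 0, na.rm = TRUE))
    abort("areas must be >= 0")
  if (any(cwa + lumen_area == 0, na.rm = TRUE))
    abort("cell wall area and lumen area cannot both be zero")
  cwa / (cwa + lumen_area)
}

#' Assign cells to equal-width tangential sectors
#'
#' Sector `floor(rel_pos * n_sectors) + 1`, mapping relative radial position
#' `[0, 1)` onto `1..n_sectors`.
#'
#' @param rel_pos Relative position within the ring, in `[0, 1)`.
#' @param n_sectors Number of sectors (default 100).
#' @return Integer sector indices.
#' @export
assign_sectors <- function(rel_pos, n_sectors = 100L) {
  if (any(rel_pos < 0 | rel_pos >= 1, na.rm = TRUE))
    abort("`rel_pos` must lie in [0, 1)")
  as.integer(floor(rel_pos * n_sectors)) + 1L
}

#' Mork's index of a tracheid
#'
#' `m = 4 * cwt_rad / lumen_diam_rad` (equivalently twice the double wall
#' over the radial lumen diameter).  A cell or sector is latewood when
#' `m >= 1`.  Scale-invariant: rescaling wall and lumen together leaves the
#' class unchanged.
#'
#' @param cwt_rad Radial single-wall thickness, um (>= 0).
#' @param lumen_diam_rad Radial lumen diameter, um.  Zero (wall-only cell)
#'   yields an infinite index, i.e. latewood, with a warning.
#' @return Numeric index (vectorized).
#' @export
mork_index <- function(cwt_rad, lumen_diam_rad) {
  if (any(cwt_rad < 0, na.rm = TRUE)) abort("`cwt_rad` must be >= 0")
  if (any(lumen_diam_rad == 0 & cwt_rad > 0, na.rm = TRUE))
    warn("zero radial lumen diameter: wall-only cell classified latewood")
  4 * cwt_rad / lumen_diam_rad
}

#' Classify cells into earlywood and latewood
#'
#' Adds `sector`, `mork` and `part` columns to a cell table.  Mork's index is
#' computed from `cwt_rad_um` and the radial lumen diameter
#' (`lumen_diam_rad_um` if present, else the equivalent-circle diameter from
#' lumen area).  By default each sector is assigned as a whole, by the
#' majority class of its cells (ties go to latewood); `level = "cell"`
#' classifies every cell individually.
#'
#' @param cells Cell table with at least `tree_id`, `year`, `rel_pos`,
#'   `lumen_area_um2`, `cwt_rad_um`.
#' @param n_sectors Number of tangential sectors (default 100).
#' @param level `"sector"` (majority vote, default) or `"cell"`.
#' @return `cells` with `sector` and `part` (`"EW"`/`"LW"`) columns.
#' @export
classify_cells <- function(cells, n_sectors = 100L,
                           level = c("sector", "cell")) {
  level <- match.arg(level)
  ld <- if ("lumen_diam_rad_um" %in% names(cells)) cells$lumen_diam_rad_um
        else cell_hydraulic_diameter(cells$lumen_area_um2)
  out <- cells %>%
    mutate(sector = assign_sectors(.data$rel_pos, n_sectors),
           mork = mork_index(.data$cwt_rad_um, ld),
           part = ifelse(.data$mork >= 1, "LW", "EW"))
  if (level == "sector") {
    ids <- vctrs::vec_group_id(out[c("tree_id", "year", "sector")])
    lw_frac <- rowsum((out$part == "LW") + 0, ids)[, 1] / tabulate(ids)
    out$part <- ifelse(lw_frac >= 0.5, "LW", "EW")[ids]
  }
  out
}

# median of `x` within integer groups `ids` (1..k), vectorized via one sort
group_median <- function(ids, x, k = max(ids)) {
  o <- order(ids, x, method = "radix")
  v <- x[o]
  L <- tabulate(ids[o], nbins = k)
  ends <- cumsum(L)
  starts <- ends - L + 1L
  out <- rep(NA_real_, k)
  nz <- L > 0L
  out[nz] <- (v[starts[nz] + (L[nz] - 1L) %/% 2L] +
                v[starts[nz] + L[nz] %/% 2L]) / 2
  out
}

#' Quartile outlier fences for a trait vector
#'
#' Tukey mode keeps values within `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.  Literal
#' mode applies the rule exactly as sometimes printed -- remove values above
#' `1.5 * Q3` or below `1.5 * Q1` -- but only when `1.5 * Q1` lies below the
#' median; otherwise that lower rule would remove the bulk of a right-skewed
#' distribution, and the function falls back to Tukey fences with a warning.
#' Quartiles use linear interpolation (type 7).
#'
#' @param x Numeric vector (>= 4 values for quartile estimation; shorter
#'   vectors pass through unfiltered with a warning).
#' @param mode `"tukey"` (default) or `"literal"`.
#' @return A list: `keep` (logical mask), `lower`, `upper`, `n_removed`.
#' @export
filter_outliers <- function(x, mode = c("tukey", "literal")) {
  mode <- match.arg(mode)
  ok <- !is.na(x)
  if (sum(ok) < 4L) {
    warn("fewer than 4 values: no outlier filtering applied")
    return(list(keep = ok, lower = -Inf, upper = Inf, n_removed = 0L))
  }
  q <- quantile(x[ok], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (mode == "literal" && 1.5 * q[1] < q[2]) {
    lower <- 1.5 * q[1]
    upper <- 1.5 * q[3]
  } else {
    if (mode == "literal")
      warn("literal lower fence 1.5*Q1 not below the median; using Tukey fences")
    iqr <- q[3] - q[1]
    lower <- q[1] - 1.5 * iqr
    upper <- q[3] + 1.5 * iqr
  }
  keep <- ok & x >= lower & x <= upper
  list(keep = keep, lower = lower, upper = upper,
       n_removed = sum(ok) - sum(keep))
}

#' Remove outlier cells within earlywood and latewood of each ring
#'
#' Applies [filter_outliers()] to `trait` separately within the earlywood
#' and latewood cells of every ring and drops the flagged cells.  The
#' removal log (per ring part) is attached as attribute `"outlier_log"`.
#'
#' @param cells Classified cell table (see [classify_cells()]).
#' @param trait Column filtered on; conduit size (`"lumen_area_um2"`,
#'   default) is the usual criterion.
#' @param mode Passed to [filter_outliers()].
#' @return The filtered cell table.
#' @export
filter_outlier_cells <- function(cells, trait = "lumen_area_um2",
                                 mode = c("tukey", "literal")) {
  mode <- match.arg(mode)
  stopifnot(trait %in% names(cells), "part" %in% names(cells))
  out <- cells %>%
    group_by(.data$tree_id, .data$year, .data$part) %>%
    mutate(.keep_cell = suppressWarnings(
      filter_outliers(.data[[trait]], mode)$keep)) %>%
    ungroup()
  log <- out %>%
    group_by(.data$tree_id, .data$year, .data$part) %>%
    summarise(n_cells = n(), n_removed = sum(!.data$.keep_cell),
              .groups = "drop")
  res <- out %>% filter(.data$.keep_cell) %>% select(-".keep_cell")
  attr(res, "outlier_log") <- log
  res
}

#' Annual earlywood/latewood trait records
#'
#' Aggregates a classified (and typically outlier-filtered) cell table into
#' one record per tree, year and ring part: hydraulic mean diameter (DH),
#' median wall thickness (CWT), median anatomical density (AD), cell count,
#' and the part width as the ring width times the part's share of classified
#' sectors.  Medians are preferred to means to blunt skewed cell-level
#' distributions.  A part with no cells yields a record with `n_cells = 0`
#' and missing traits.
#'
#' @param cells Classified cell table (see [classify_cells()]).
#' @param rings Ring-width table (`tree_id`, `year`, `ring_width_mm`).
#' @return A tibble with `tree_id` (plus `group`/`plot_id` if present),
#'   `year`, `part`, `dh`, `cwt`, `ad`, `width`, `n_cells`.
#' @export
aggregate_annual <- function(cells, rings) {
  stopifnot(all(c("sector", "part") %in% names(cells)))
  id_cols <- intersect(c("tree_id", "plot_id", "group"), names(cells))

  sector_share <- cells %>%
    distinct(.data$tree_id, .data$year, .data$sector, .data$part) %>%
    group_by(.data$tree_id, .data$year) %>%
    summarise(frac_ew = mean(.data$part == "EW"), .groups = "drop")

  traits <- cells %>%
    mutate(d_cell = cell_hydraulic_diameter(.data$lumen_area_um2),
           cwt_cell = cell_cwt(.data$cwt_rad_um, .data$cwt_tan_um),
           ad_cell = anatomical_density(.data$cwa_um2, .data$lumen_area_um2)) %>%
    group_by(across(all_of(c(id_cols, "year", "part")))) %>%
    summarise(dh = mean_hydraulic_diameter(.data$d_cell),
              cwt = median(.data$cwt_cell),
              ad = median(.data$ad_cell),
              n_cells = n(), .groups = "drop")

  grid <- traits %>%
    distinct(across(all_of(c(id_cols, "year")))) %>%
    tidyr::expand_grid(part = c("EW", "LW"))
  traits <- grid %>%
    left_join(traits, by = c(id_cols, "year", "part")) %>%
    mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L))

  traits %>%
    left_join(sector_share, by = c("tree_id", "year")) %>%
    left_join(select(rings, "tree_id", "year", "ring_width_mm"),
              by = c("tree_id", "year")) %>%
    mutate(width = .data$ring_width_mm *
             ifelse(.data$part == "EW", .data$frac_ew, 1 - .data$frac_ew)) %>%
    select(all_of(id_cols), "year", "part", "dh", "cwt", "ad", "width",
           "n_cells") %>%
    arrange(.data$tree_id, .data$year, .data$part)
}

#' Intra-annual sector profiles of DH, CWT and AD
#'
#' Per tree, year and trait, the vector of per-sector medians over the
#' ring's cells (hydraulic diameter, wall thickness, anatomical density).
#' Sectors without cells are reported as missing, so every profile has
#' exactly `n_sectors` entries.
#'
#' @param cells Sectorized (and typically filtered) cell table.
#' @param n_sectors Number of sectors (default 100).
#' @return A long tibble: id columns, `year`, `trait` (`"DH"`, `"CWT"`,
#'   `"AD"`), `sector`, `value`.
#' @export
build_sector_profiles <- function(cells, n_sectors = 100L) {
  stopifnot("sector" %in% names(cells))
  id_cols <- intersect(c("tree_id", "plot_id", "group"), names(cells))
  ids <- vctrs::vec_group_id(cells[c(id_cols, "year", "sector")])
  k <- max(ids)
  first <- match(seq_len(k), ids)
  med <- cells[first, c(id_cols, "year", "sector")] %>%
    mutate(DH = group_median(ids, cell_hydraulic_diameter(cells$lumen_area_um2), k),
           CWT = group_median(ids, cell_cwt(cells$cwt_rad_um, cells$cwt_tan_um), k),
           AD = group_median(ids, anatomical_density(cells$cwa_um2,
                                                     cells$lumen_area_um2), k)) %>%
    tidyr::pivot_longer(c("DH", "CWT", "AD"),
                        names_to = "trait", values_to = "value")
  grid <- med %>%
    distinct(across(all_of(c(id_cols, "year", "trait")))) %>%
    tidyr::expand_grid(sector = seq_len(n_sectors))
  grid %>%
    left_join(med, by = c(id_cols, "year", "trait", "sector")) %>%
    arrange(.data$tree_id, .data$year, .data$trait, .data$sector)
}
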