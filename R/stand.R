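#' Quadratic mean diameter of a stand
#'
#' Diameter (cm) of the tree of mean basal area, computed from stem density
#' and stand basal area: `Dq = sqrt(40000 * BA / (pi * N))`.
#'
#' @param stems_per_ha Stem density, trees per hectare (> 0).
#' @param basal_area Stand basal area, m^2 per hectare (> 0).
#' @return Quadratic mean diameter in cm (vectorized).
#' @examples
#' quadratic_mean_dbh(708, 43)
#' @export
quadratic_mean_dbh <- function(stems_per_ha, basal_area) {
  if (any(!is.finite(stems_per_ha)) || any(stems_per_ha <= 0))
    abort("`stems_per_ha` must be > 0")
  if (any(!is.finite(basal_area)) || any(basal_area <= 0))
    abort("`basal_area` must be > 0")
  sqrt(40000 * basal_area / (pi * stems_per_ha))
}

#' Reineke Stand Density Index
#'
#' `SDI = N * (Dq / 25)^1.605`, the stem density the stand would carry at a
#' reference quadratic mean diameter of 25 cm.  A dimensionless measure of
#' stand density / competition.
#'
#' @param stems_per_ha Stem density, trees per hectare (> 0).
#' @param dq Quadratic mean diameter, cm (> 0).
#' @return Stand Density Index (vectorized).
#' @examples
#' reineke_sdi(500, 25) # == 500 at the reference diameter
#' reineke_sdi(708, quadratic_mean_dbh(708, 43))
#' @export
reineke_sdi <- function(stems_per_ha, dq) {
  if (any(!is.finite(stems_per_ha)) || any(stems_per_ha <= 0))
    abort("`stems_per_ha` must be > 0")
  if (any(!is.finite(dq)) || any(dq <= 0))
    abort("`dq` must be > 0")
  stems_per_ha * (dq / 25)^1.605
}

#' Stand description of the two pine-oak admixture trials
#'
#' Plot-level stand characteristics of the two study locations the package's
#' demo analyses emulate: a Continental (Poland) and a Mediterranean (Spain)
#' *Pinus sylvestris* trial, each with three pure-pine and three pine-oak
#' plots.  Stem density and basal area cover all trees (pines plus oaks);
#' DBH columns describe the pines.
#'
#' @return A tibble with one row per plot: `site` ("continental" or
#'   "mediterranean"), `forest_type` ("mixed" or "pure"), `plot`,
#'   `area_ha`, `stems_ha`, `basal_area_m2ha`, `sdi` (Reineke Stand Density
#'   Index), `dbh_mean_cm`, `dbh_sd_cm`.
#' @export
pine_oak_stands <- function() {
  tibble(
    site = rep(c("continental", "mediterranean"), each = 6L),
    forest_type = rep(rep(c("mixed", "pure"), each = 3L), 2L),
    plot = rep(c("MPA", "MPB", "MPC", "PPD", "PPE", "PPF"), 2L),
    area_ha = c(0.2, 0.2, 0.18, 0.12, 0.12, 0.09,
                0.2, 0.2, 0.2, 0.04, 0.04, 0.04),
    stems_ha = c(610, 655, 505, 708, 458, 444,
                 5580, 4635, 4370, 2200, 2350, 2025),
    basal_area_m2ha = c(36, 42, 41, 43, 41, 38,
                        31, 32, 33, 67, 69, 57),
    sdi = c(696, 790, 737, 825, 721, 681,
            935, 932, 938, 1460, 1510, 1269),
    dbh_mean_cm = c(31.4, 29.6, 31.6, 30.6, 33.8, 34.3,
                    11.9, 12.5, 12.5, 19.4, 17.7, 18.2),
    dbh_sd_cm = c(4.28, 6.58, 5.81, 5.56, 5.44, 6.15,
                  4.5, 3.9, 4.7, 5.4, 4.3, 4.3)
  )
}
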