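#' Min-max normalize intra-annual sector profiles
#'
#' Rescales each ring's trait profile so its minimum maps to 0 and its
#' maximum to 1 (`(x - min) / (max - min)`), removing between-tree level
#' differences and axial-widening effects so intra-annual shapes can be
#' averaged and compared.  Missing sectors stay missing.  Rings with fewer
#' than two distinct defined values (zero range) are excluded, with a
#' message reporting how many.
#'
#' @param profiles Long sector-profile tibble from
#'   [build_sector_profiles()]: id columns, `year`, `trait`, `sector`,
#'   `value`.
#' @return The same tibble with `value` replaced by its normalized version.
#' @export
minmax_normalize <- function(profiles) {
  stopifnot(all(c("year", "trait", "sector", "value") %in% names(profiles)))
  id_cols <- intersect(c("tree_id", "plot_id", "group"), names(profiles))
  out <- profiles %>%
    group_by(across(all_of(c(id_cols, "year", "trait")))) %>%
    mutate(.min = min(.data$value, na.rm = TRUE),
           .max = max(.data$value, na.rm = TRUE)) %>%
    ungroup()
  bad <- out %>%
    filter(!is.finite(.data$.min) | .data$.max == .data$.min) %>%
    distinct(across(all_of(c(id_cols, "year", "trait"))))
  if (nrow(bad) > 0)
    inform(paste0(nrow(bad), " constant or empty ring profile(s) excluded ",
                  "from normalization (zero range)"))
  out %>%
    filter(is.finite(.data$.min), .data$.max > .data$.min) %>%
    mutate(value = (.data$value - .data$.min) / (.data$.max - .data$.min)) %>%
    select(-".min", -".max")
}

smooth_profile <- function(sector, y, span) {
  ok <- !is.na(y)
  if (sum(ok) < 10L) return(y)
  fit <- loess(y ~ sector, data = tibble(sector = sector[ok], y = y[ok]),
               span = span, degree = 1, family = "gaussian")
  out <- rep(NA_real_, length(y))
  out[ok] <- predict(fit, tibble(sector = sector[ok]))
  out
}

#' Group-mean intra-annual profile with a 95% band
#'
#' Pointwise mean of the (normalized) profiles across rings, with a 95%
#' confidence band `mean +/- 1.96 SE` computed before smoothing; mean and
#' band are then smoothed with the same loess operator (local linear,
#' default span 0.3) to suppress sector-scale noise while keeping the
#' earlywood-latewood transition.
#'
#' @param profiles Normalized long profile tibble; any of `group`, `trait`,
#'   `phase` columns present are used as strata.
#' @param span Loess span (default 0.3).
#' @return A `qwa_profile` tibble: strata, `sector`, `mean`, `se`,
#'   `smooth`, `lo`, `hi`, `n_rings`.
#' @export
group_mean_profile <- function(profiles, span = 0.3) {
  strata <- intersect(c("group", "trait", "phase"), names(profiles))
  pt <- profiles %>%
    filter(!is.na(.data$value)) %>%
    group_by(across(all_of(c(strata, "sector")))) %>%
    summarise(mean = mean(.data$value),
              se = ifelse(n() > 1, sd(.data$value) / sqrt(n()), 0),
              n = n(), .groups = "drop")
  n_rings <- profiles %>%
    distinct(across(all_of(c(strata, "tree_id", "year")))) %>%
    group_by(across(all_of(strata))) %>%
    summarise(n_rings = n(), .groups = "drop")
  if (nrow(pt) == 0) abort("no defined profile values to average")
  out <- pt %>%
    arrange(across(all_of(c(strata, "sector")))) %>%
    group_by(across(all_of(strata))) %>%
    mutate(smooth = smooth_profile(.data$sector, .data$mean, span),
           lo = smooth_profile(.data$sector, .data$mean - 1.96 * .data$se,
                               span),
           hi = smooth_profile(.data$sector, .data$mean + 1.96 * .data$se,
                               span)) %>%
    ungroup() %>%
    left_join(n_rings, by = strata) %>%
    select(all_of(strata), "sector", "mean", "se", "smooth", "lo", "hi",
           "n_rings")
  structure(out, class = c("qwa_profile", class(out)), span = span)
}

#' @export
autoplot.qwa_profile <- function(object, ...) {
  has_phase <- "phase" %in% names(object)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$sector, y = .data$smooth))
  if (has_phase) {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                        fill = .data$phase), alpha = 0.2) +
      ggplot2::geom_line(ggplot2::aes(colour = .data$phase))
  } else {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           alpha = 0.2) +
      ggplot2::geom_line()
  }
  facets <- intersect(c("trait", "group"), names(object))
  if (length(facets) == 2L)
    p <- p + ggplot2::facet_grid(trait ~ group, scales = "free_y")
  else if (length(facets) == 1L)
    p <- p + ggplot2::facet_wrap(facets, scales = "free_y")
  p + ggplot2::labs(x = "Ring sector (relative position)",
                    y = "Normalized trait value") +
    ggplot2::theme_minimal()
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The supremum distance between the two empirical CDFs, with the p-value
#' from the asymptotic Kolmogorov distribution at the effective sample size
#' `n1 n2 / (n1 + n2)`.
#'
#' @param a,b Numeric samples (>= 5 values each).
#' @return One-row tibble: `d_stat`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 5L || length(b) < 5L)
    abort("need at least 5 values per sample")
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  tibble(d_stat = unname(ht$statistic), p_value = unname(ht$p.value),
         n1 = length(a), n2 = length(b))
}

# D statistic alone, tie-safe, for the permutation test
ks_d <- function(a, b) {
  w <- c(a, b)
  z <- c(rep(1 / length(a), length(a)), rep(-1 / length(b), length(b)))
  o <- order(w)
  cs <- cumsum(z[o])
  # with ties, only evaluate the ECDF difference at the last of tied values
  keep <- c(diff(w[o]) != 0, TRUE)
  max(abs(cs[keep]))
}

#' Cluster-permutation Kolmogorov-Smirnov test for pooled ring values
#'
#' Pooled sector values from the same ring are correlated (each ring is
#' normalized as a unit), which makes the iid KS p-value anticonservative.
#' This test keeps the pooled D statistic but draws its null distribution
#' by permuting whole rings between the two groups, so the p-value is valid
#' under ring exchangeability.
#'
#' @param values Numeric vector of pooled values.
#' @param ring Ring identifier per value (cluster label).
#' @param grp Two-level group label per value.
#' @param n_perm Number of permutations (default 499).
#' @param seed Optional seed.
#' @return One-row tibble: `d_stat`, `p_value`, `n1`, `n2`.
#' @export
ks_permutation <- function(values, ring, grp, n_perm = 499L, seed = NULL) {
  ok <- !is.na(values)
  values <- values[ok]; ring <- ring[ok]; grp <- as.character(grp)[ok]
  lev <- unique(grp)
  if (length(lev) != 2L) abort("`grp` must have exactly two levels")
  by_ring <- split(values, ring)
  ring_grp <- vapply(split(grp, ring), function(g) g[1], character(1))
  if (any(vapply(split(grp, ring), function(g) length(unique(g)), 1L) > 1L))
    abort("each ring must belong to a single group")
  a_rings <- names(ring_grp)[ring_grp == lev[1]]
  d0 <- ks_d(unlist(by_ring[a_rings], use.names = FALSE),
             unlist(by_ring[setdiff(names(by_ring), a_rings)],
                    use.names = FALSE))
  n_a <- length(a_rings)
  all_names <- names(by_ring)
  dp <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pa <- sample(all_names, n_a)
      ks_d(unlist(by_ring[pa], use.names = FALSE),
           unlist(by_ring[setdiff(all_names, pa)], use.names = FALSE))
    }, numeric(1))
  })
  tibble(d_stat = d0, p_value = (1 + sum(dp >= d0)) / (n_perm + 1),
         n1 = sum(grp == lev[1]), n2 = sum(grp == lev[2]))
}

#' Gini coefficient
#'
#' Inequality of a non-negative distribution in `[0, 1]` (0 = perfect
#' equality), `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, computed via the
#' sorted O(n log n) identity.
#'
#' @param x Non-negative values with a positive sum (NAs dropped).
#' @return The Gini coefficient.
#' @examples
#' gini(c(1, 2, 3)) # 8/36
#' @export
gini <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) abort("no values")
  if (any(x < 0)) abort("values must be >= 0")
  s <- sum(x)
  if (s <= 0) abort("values must have a positive sum")
  n <- length(x)
  xs <- sort(x)
  2 * sum(seq_len(n) * xs) / (n * s) - (n + 1) / n
}

# leave-one-out Gini from the sorted sample, closed form
gini_jackknife <- function(xs) {
  n <- length(xs)
  S <- sum(xs)
  W <- sum(seq_len(n) * xs)
  P <- cumsum(xs)
  j <- seq_len(n)
  W1 <- W - j * xs - (S - P)
  2 * W1 / ((n - 1) * (S - xs)) - n / (n - 1)
}

#' Bootstrap confidence intervals for the Gini coefficient
#'
#' Case-resampling bootstrap with both percentile and bias-corrected and
#' accelerated (BCa) intervals: bias correction from the fraction of the
#' bootstrap distribution below the point estimate, acceleration from the
#' jackknife skewness.  A degenerate bootstrap distribution collapses the
#' interval onto the point estimate with a warning.
#'
#' @param x Non-negative values, `n >= 10`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return A `qwa_gini` tibble with one row per interval method:
#'   `method` (`"percentile"`, `"bca"`), `gini`, `ci_low`, `ci_high`, `n`,
#'   `n_boot`.
#' @export
gini_bootstrap <- function(x, n_boot = 2000L, conf = 0.95, seed = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10L) abort("need at least 10 values")
  g0 <- gini(x)
  gb <- with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    m <- matrix(x[idx], n)
    ms <- apply(m, 2, sort)
    cs <- colSums(ms)
    2 * colSums(ms * seq_len(n)) / (n * cs) - (n + 1) / n
  })
  gb <- gb[is.finite(gb)]
  alpha <- 1 - conf
  if (length(unique(gb)) <= 1L) {
    warn("degenerate bootstrap distribution: interval collapsed to the point estimate")
    ci_p <- ci_b <- c(g0, g0)
  } else {
    ci_p <- quantile(gb, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    z0 <- qnorm((sum(gb < g0) + 0.5 * sum(gb == g0)) / length(gb))
    gj <- gini_jackknife(sort(x))
    dj <- mean(gj) - gj
    denom <- sum(dj^2)^1.5
    a <- if (denom > 0) sum(dj^3) / (6 * denom) else 0
    zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
    adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    ci_b <- quantile(gb, adj, names = FALSE)
  }
  out <- tibble(method = c("percentile", "bca"),
                gini = g0,
                ci_low = pmin(c(ci_p[1], ci_b[1]), g0),
                ci_high = pmax(c(ci_p[2], ci_b[2]), g0),
                n = n, n_boot = n_boot)
  structure(out, class = c("qwa_gini", class(out)), conf = conf)
}

#' @export
tidy.qwa_gini <- function(x, ...) as_tibble(x)

#' @export
glance.qwa_gini <- function(x, ...) {
  tibble(gini = x$gini[1], n = x$n[1], n_boot = x$n_boot[1],
         conf = attr(x, "conf"))
}

# phase years around planted/flagged droughts; neighbors that are
# themselves droughts are excluded from before/after
phase_years <- function(drought_years, all_years) {
  dy <- sort(unique(drought_years))
  list(
    before = setdiff(intersect(dy - 1L, all_years), dy),
    during = intersect(dy, all_years),
    after = setdiff(intersect(dy + 1L, all_years), dy)
  )
}

#' Drought-legacy intra-annual profiles and phase contrasts
#'
#' For every drought year, collects each group's normalized ring profiles
#' one year before, during, and one year after the event (neighbor years
#' that are themselves droughts are excluded from the before/after phases),
#' averages them into smoothed phase profiles, and tests every phase pair
#' per group and trait with a Kolmogorov-Smirnov contrast on the pooled
#' normalized sector values.  The default p-value permutes whole rings
#' between phases ([ks_permutation()]), which stays valid although sector
#' values within a ring are correlated; `ks = "asymptotic"` uses the plain
#' pooled test ([ks_two_sample()]).
#'
#' @param profiles Normalized profile tibble ([minmax_normalize()]) with a
#'   `group` column.
#' @param drought_years Integer years (e.g. from [flag_drought_years()] or
#'   the generator's ground truth).
#' @param span Loess span for the phase profiles.
#' @param ks `"permutation"` (default) or `"asymptotic"`.
#' @param n_perm Permutations for the default test.
#' @param seed Optional seed.
#' @param traits Optional subset of traits to test (default: all present).
#' @param pairs Optional subset of phase pairs to test, e.g.
#'   `"before_vs_after"` (default: all).
#' @return A list: `profiles` (a [group_mean_profile()] tibble with a
#'   `phase` column) and `ks` (tibble `group`, `trait`, `pair`, `d_stat`,
#'   `p_value`, `n1`, `n2`, `method`).  Phases without eligible years are
#'   omitted with a message.
#' @export
drought_phase_profiles <- function(profiles, drought_years, span = 0.3,
                                   ks = c("permutation", "asymptotic"),
                                   n_perm = 499L, seed = NULL,
                                   traits = NULL, pairs = NULL) {
  ks <- match.arg(ks)
  stopifnot("group" %in% names(profiles))
  if (length(drought_years) == 0L) abort("empty drought calendar")
  ph <- phase_years(drought_years, unique(profiles$year))
  empty <- names(ph)[lengths(ph) == 0L]
  if (length(empty) > 0)
    inform(paste0("phase(s) without eligible years omitted: ",
                  paste(empty, collapse = ", ")))
  ph <- ph[lengths(ph) > 0L]

  phased <- purrr::imap(ph, function(yrs, nm) {
    profiles %>% filter(.data$year %in% yrs) %>% mutate(phase = nm)
  }) %>% bind_rows() %>%
    mutate(phase = factor(.data$phase, levels = c("before", "during", "after")))

  prof <- group_mean_profile(phased, span = span)

  phase_pairs <- utils::combn(levels(droplevels(phased$phase)), 2L,
                              simplify = FALSE)
  if (!is.null(pairs))
    phase_pairs <- purrr::keep(phase_pairs,
                               ~ paste(.x, collapse = "_vs_") %in% pairs)
  tested <- phased
  if (!is.null(traits)) tested <- filter(tested, .data$trait %in% traits)
  seeds <- with_seed(seed, sample.int(2^30, 64L))
  si <- 0L
  ks_res <- purrr::map(
    split(tested, list(tested$group, tested$trait), drop = TRUE),
    function(df) {
      purrr::map(phase_pairs, function(pr) {
        a <- filter(df, .data$phase == pr[1], !is.na(.data$value))
        b <- filter(df, .data$phase == pr[2], !is.na(.data$value))
        if (nrow(a) < 5L || nrow(b) < 5L) return(NULL)
        si <<- si %% 64L + 1L
        res <- if (ks == "permutation") {
          dd <- bind_rows(a, b)
          ks_permutation(dd$value,
                         paste(dd$tree_id, dd$year, as.character(dd$phase)),
                         as.character(dd$phase),
                         n_perm = n_perm, seed = seeds[si])
        } else {
          ks_two_sample(a$value, b$value)
        }
        res %>% mutate(group = df$group[1], trait = df$trait[1],
                       pair = paste(pr, collapse = "_vs_"), method = ks)
      }) %>% bind_rows()
    }) %>% bind_rows()
  if (nrow(ks_res) > 0)
    ks_res <- select(ks_res, "group", "trait", "pair", "d_stat", "p_value",
                     "n1", "n2", "method")
  list(profiles = prof, ks = ks_res)
}

#' Gini inequality of intra-annual profiles in drought vs non-drought years
#'
#' Pools the normalized sector values of each forest type and trait
#' separately over drought and non-drought years and estimates the Gini
#' coefficient of each stratum with BCa bootstrap intervals
#' ([gini_bootstrap()]).  Ring-width indices, which have no intra-annual
#' profile, can be supplied via `rwi` and enter as a `"RWI"` trait pooled
#' per stratum.
#'
#' @param profiles Normalized profile tibble with a `group` column.
#' @param drought_years Integer drought calendar.
#' @param rwi Optional tibble `tree_id`, `group`, `year`, `rwi` of
#'   detrended ring-width indices (see [ring_width_indices()]).
#' @param n_boot,conf,seed Bootstrap settings.
#' @return A tibble `trait`, `group`, `drought` (`"yes"`/`"no"`), `gini`,
#'   `ci_low`, `ci_high` (BCa), `n_values`, `n_rings`; empty strata are
#'   omitted.
#' @export
drought_vs_nondrought_gini <- function(profiles, drought_years, rwi = NULL,
                                       n_boot = 2000L, conf = 0.95,
                                       seed = NULL) {
  stopifnot("group" %in% names(profiles))
  pool <- profiles %>%
    filter(!is.na(.data$value)) %>%
    mutate(drought = ifelse(.data$year %in% drought_years, "yes", "no")) %>%
    select("trait", "group", "drought", "tree_id", "year", "value")
  if (!is.null(rwi)) {
    pool <- bind_rows(pool, rwi %>%
      filter(!is.na(.data$rwi)) %>%
      mutate(trait = "RWI",
             drought = ifelse(.data$year %in% drought_years, "yes", "no")) %>%
      select("trait", "group", "drought", "tree_id", "year", value = "rwi"))
  }
  strata <- split(pool, list(pool$trait, pool$group, pool$drought),
                  drop = TRUE)
  seeds <- with_seed(seed, sample.int(2^30, length(strata)))
  res <- purrr::imap(strata, function(df, nm) {
    if (nrow(df) < 10L) return(NULL)
    gb <- gini_bootstrap(df$value, n_boot = n_boot, conf = conf,
                         seed = seeds[[match(nm, names(strata))]])
    bca <- filter(gb, .data$method == "bca")
    tibble(trait = df$trait[1], group = df$group[1], drought = df$drought[1],
           gini = bca$gini, ci_low = bca$ci_low, ci_high = bca$ci_high,
           n_values = nrow(df),
           n_rings = dplyr::n_distinct(paste(df$tree_id, df$year)))
  }) %>% bind_rows()
  res %>%
    mutate(trait = factor(.data$trait, levels = c("DH", "CWT", "AD", "RWI"))) %>%
    arrange(.data$trait, .data$group, dplyr::desc(.data$drought == "no")) %>%
    mutate(trait = as.character(.data$trait))
}

#' Detrended ring-width indices per tree
#'
#' Spline ratio-detrending ([detrend_series()]) of each tree's ring-width
#' series; the standard input for ring-width inequality comparisons.
#'
#' @param rings Tibble `tree_id`, `year`, `ring_width_mm` (plus optional id
#'   columns carried through).
#' @param cutoff Spline cutoff, years.
#' @return `rings` with an added `rwi` column.
#' @export
ring_width_indices <- function(rings, cutoff = 30) {
  stopifnot(all(c("tree_id", "year", "ring_width_mm") %in% names(rings)))
  rings %>%
    arrange(.data$tree_id, .data$year) %>%
    group_by(.data$tree_id) %>%
    mutate(rwi = detrend_series(.data$ring_width_mm, cutoff = cutoff,
                                method = "ratio")) %>%
    ungroup()
}
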