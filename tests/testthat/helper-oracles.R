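# Independent brute-force oracles used across the suite.

# O(n^2) pairwise Gini
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# KS D by scanning both ECDFs at every pooled point
ks_d_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  Fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(Fa - Fb))
}

# direct iteration of the published biweight equations (independent of the
# package's implementation details)
biweight_oracle <- function(x, c_tune = 9, tol = 1e-10) {
  m <- median(x)
  s <- c_tune * median(abs(x - median(x)))
  if (s == 0) return(median(x))
  repeat {
    u <- (x - m) / s
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    m2 <- sum(w * x) / sum(w)
    if (abs(m2 - m) < tol) return(m2)
    m <- m2
  }
}

# explicit type-7 quartiles and Tukey fences
tukey_keep_oracle <- function(x) {
  q1 <- quantile(x, 0.25, type = 7, names = FALSE)
  q3 <- quantile(x, 0.75, type = 7, names = FALSE)
  x >= q1 - 1.5 * (q3 - q1) & x <= q3 + 1.5 * (q3 - q1)
}

# day length (hours) from latitude and day of year, standard solar geometry
day_length_oracle <- function(lat_deg, doy) {
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  phi <- lat_deg * pi / 180
  24 / pi * acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
}

# small synthetic config used by several files (fast but non-trivial)
tiny_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_years = 36, trees_per_group = 2,
                   cells_per_ring = 60, ...)
}

# amplitude of a fitted sinusoid of period p over an index window
fitted_amplitude <- function(y, p, idx = seq_along(y)) {
  t <- seq_along(y)
  co <- coef(lm(y[idx] ~ sin(2 * pi * t[idx] / p) + cos(2 * pi * t[idx] / p)))
  sqrt(co[2]^2 + co[3]^2)
}
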