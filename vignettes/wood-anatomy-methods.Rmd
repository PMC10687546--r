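---
title: "Methods: from tracheid tables to climate and drought statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tracheid tables to climate and drought statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own methods: the models and
conventions each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical decisions that were genuinely open.

## 1. Cell-level traits and ring anatomy

A cell record carries a relative radial position in $[0,1)$, lumen area
($\mu m^2$), radial and tangential single-wall thickness ($\mu m$) and
cell wall area ($\mu m^2$). Three traits summarize a ring part:

* **Hydraulic diameter.** Per cell, the equivalent-circle diameter
  $d = 2\sqrt{A/\pi}$. The imaging software that produces cell tables has
  its own (unpublished) diameter definition; the equivalent-circle
  convention is the standard QWA choice and is what we adopt. Per ring
  part, $D_H = \sum d^5/\sum d^4$, the Hagen–Poiseuille-weighted mean; it
  always dominates the arithmetic mean (power-mean inequality), which the
  suite checks property-style.
* **Cell wall thickness**, $(t_r + t_t)/2$.
* **Anatomical density**, $W/(W+A) \in [0,1]$, a geometric proxy for wood
  density.

**Sectors.** Each ring is cut into 100 equal-width tangential sectors by
`floor(rel_pos * 100) + 1`; position 0 falls in sector 1 and 0.999 in
sector 100. Sector profiles are per-sector *medians* (robust to the
right-skewed cell distributions); annual records are medians too, except
$D_H$ which is the weighted ratio over the part's cells.

**Earlywood/latewood.** Mork's index $m = 4 t_r/\ell_r$ with $\ell_r$ the
radial lumen diameter (the supplied column when present, else the
equivalent-circle diameter). The cited index's convention is "latewood iff
$m \ge 1$", so the boundary cell is latewood; a wall-only cell
($\ell_r = 0$) is latewood with a warning. Classification is applied at
the *sector* level by majority vote of the sector's cells (ties to
latewood), because the assignment unit in this tradition is the sector;
per-cell assignment remains available (`level = "cell"`). Part widths are
the ring width times the part's share of classified sectors, so earlywood
and latewood widths sum to the ring width exactly.

**Outlier filtering.** The quartile rule is applied separately within the
earlywood and latewood cells of each ring, on conduit size (lumen area) by
default. The default fences are Tukey's, $[Q_1 - 1.5\,IQR,\; Q_3 +
1.5\,IQR]$ with type-7 quartiles. A "literal" mode implements the rule as
it is sometimes printed — remove values above $1.5\,Q_3$ *or below*
$1.5\,Q_1$ — which on right-skewed data would delete up to a quarter of
genuine observations; that mode therefore only applies when $1.5\,Q_1$
lies below the median and otherwise falls back to Tukey fences with a
warning. We treat the printed lower rule as a near-certain misstatement of
Tukey fences, hence the default. An upstream image-quality prefilter
("cells misclassified due to bad images") cannot be reproduced from a
printed description and is out of scope; only the quartile stage is
implemented.

## 2. Chronologies

Per tree and trait, annual medians are detrended by a cubic smoothing
spline with a 50% frequency-response cutoff at 30 years, as ratio indices
raw/fit. The spline is implemented as the discrete penalized least-squares
smoother with a second-difference penalty,
$(I + \lambda D^\top D)^{-1} y$, whose interior frequency response is
$H(\omega) = 1/(1 + 16\lambda \sin^4(\omega/2))$; solving $H = 1/2$ at
wavelength $p$ gives the closed form $\lambda = (2\sin(\pi/p))^{-4}$. This
is the standard dendrochronological parameterization linking cutoff and
smoothing; the suite verifies 0.50 ± 0.05 amplitude at the cutoff and a
monotone response over a sine sweep. Non-positive fitted values (possible
on series that dip toward zero) are floored at 5% of the series mean with
a warning; an all-zero series is refused.

Index series are then **prewhitened**: an AR model of order selected by
AIC among $0..\min(10, n/4)$, fitted by least squares, with residuals
re-centered on the index mean so chronology units stay interpretable. Two
calibration facts informed the defaults. First, AIC is deliberately
liberal: on pure white noise it keeps order 0 only about 70% of the time
(any fitting method); we keep AIC because it is the convention of the
tooling this pipeline mirrors, and the suite asserts only that order 0 is
the majority choice. Second, the *fitting* method matters for how white
the residuals are at $n \approx 60$: least squares leaves
$|\rho_1| < 0.1$ on AR(1) $\phi = 0.7$ input in ~94% of runs, whereas
Yule–Walker (biased toward zero) manages only ~86%; we therefore fit by
least squares.

The chronology is the per-year **Tukey biweight robust mean** across
trees: weights $(1-u^2)^2$ for $|u|<1$ with $u = (x-m)/(9\,\mathrm{MAD})$
(raw MAD), iterated to $10^{-8}$; zero MAD returns the median. Sample
depth per year is the count of contributing trees.

**Climate correlations.** Monthly temperature, precipitation and 6-month
SPEI are first detrended per calendar month with the *same* spline-ratio
procedure, so chronology and climate carry the same frequency content;
variables that cross zero (winter temperature, any SPEI) are detrended by
difference (raw − fit + mean) instead, since a ratio is undefined there —
Pearson correlation is indifferent to that location/scale choice. The
window is the 20 months from previous-year March to current-year October.
Each correlation gets a case-resampling bootstrap (years with replacement,
default 1000 draws) percentile interval; "significant" means the interval
excludes zero. The number of draws and the percentile flavor are not fixed
by convention anywhere we could anchor to, so both are arguments and are
recorded in the result's attributes. Overlaps shorter than 25 years are
refused rather than silently correlated.

## 3. Climate, SPEI and drought years

Potential evapotranspiration uses **Thornthwaite's** temperature-only
formulation (annual heat index, day-length correction from mid-month solar
declination, zero PET at or below 0 °C, Willmott's quadratic above
26.5 °C). Published analyses of this kind rarely state their PET
method; Thornthwaite is the default wherever only temperature is
available, which is exactly our input contract. The day-length formula is
valid only equatorward of the polar circles, so $|\phi| > 66.5°$ is
refused.

SPEI aggregates the water balance $D = P - PET$ over $k$ months (3 and 6
by default) and fits, per calendar month over the calibration years (the
full record by default — no reference period is prescribed anywhere), a
3-parameter log-logistic distribution by **unbiased probability-weighted
moments**, then maps each value through the fitted CDF to standard-normal
quantiles. Two numerical points are worth recording:

* The PWM weights must be the $E[X(1-F)^r]$ ("a-type") form,
  $(n-j)/(n-1)$ on the ascending order statistics; the $(j-1)/(n-1)$ form
  that is often printed returns a mirrored (negative-scale) fit. We
  verified the convention by recovering known parameters from simulated
  log-logistic samples.
* Left-skewed monthly series legitimately produce the mirrored,
  upper-bounded branch (negative scale *and* shape); it is a proper
  monotone fit and is accepted. Values outside the fitted support are
  clamped to CDF $10^{-8}$ (below a lower bound) or $1-10^{-8}$ (above an
  upper bound). Only $|\beta| \le 1$ or sign-inconsistent fits are
  refused, as is any zero-variance calibration month.

The suite checks the standardization property (per-month mean within
±0.05, sd within [0.9, 1.1] on a 62-year stationary balance), location
equivariance, and rank-preservation against the raw aggregate.

A **drought year** is any year whose 3-month SPEI drops below −1.5 in any
month March–October. Note what standardization implies: about 7% of all
months sit below −1.5 *by construction*, so over six decades a dozen or
more years will be flagged even in an unremarkable climate — the planted
droughts of the generator are always among them (they are the most extreme
by a wide margin), but they are never the *only* ones. Exact recovery of a
planted calendar is therefore a property of the flagging logic (window and
threshold), which the suite tests on constructed index series, not of the
full standardization chain.

## 4. Intra-annual profiles, KS contrasts, Gini

Sector profiles are min–max normalized per ring (min → 0, max → 1;
constant rings are excluded with a logged count). Group profiles are
pointwise means across rings with a 95% band mean ± 1.96 SE computed
*before* smoothing; mean and band are then smoothed by the same loess
operator (local linear, span 0.3 — small enough to keep the
earlywood–latewood transition, large enough to kill sector noise; the span
is an argument and recorded in the result).

**Phase contrasts.** For each drought year $d$, rings at $d-1$, $d$,
$d+1$ form the before/during/after phases; a neighbor year that is itself
a drought is excluded from before/after so consecutive droughts do not
contaminate the contrast. Distributions are compared by the two-sample
Kolmogorov–Smirnov statistic on the pooled normalized sector values of a
phase. The open question here was the pooling unit, and it has a
statistical sting: sector values within a ring are correlated (the ring is
normalized as a unit), and the iid asymptotic KS p-value on pooled values
is badly anticonservative — in our null-generator calibration its
false-positive rate was roughly 27%. The default p-value therefore comes
from a **ring-label permutation** of the pooled D statistic (whole rings
shuffled between phases), which is valid under ring exchangeability and
was calibrated at the nominal 5% in replicate null datasets; the plain
asymptotic pooled test remains available (`ks = "asymptotic"`), and
`ks_two_sample()` itself is the standard iid test with the asymptotic
Kolmogorov p-value at effective sample size $n_1 n_2/(n_1+n_2)$.

**Gini.** Profile inequality per stratum (forest type × trait × drought
vs non-drought) pools the normalized sector values and computes
$G = \sum_{ij}|x_i - x_j| / (2 n^2 \bar x)$ via the sorted
$O(n \log n)$ identity (checked against the $O(n^2)$ oracle). Bootstrap
intervals are percentile and BCa; BCa takes its bias correction from the
bootstrap distribution's fraction below the point estimate and its
acceleration from jackknife skewness, with the leave-one-out Gini computed
in closed form from prefix sums. Ring-width indices have no intra-annual
profile, so their inequality rows are computed on the pooled detrended
ring-width indices of a stratum — that is the only sensible reading of
placing ring width alongside the profile traits in one inequality table.

## 5. The synthetic generator

The generator defines the study conditions the tests run under: 62 years
(1958 onward), nine trees per forest type split over three plots, ~300
cells per ring (150 in the replicate experiments below), a warm-summer
continental climate (monthly normals averaging 8.3 °C and 565 mm a year,
interannual sd 1.5 °C, precipitation CV 0.35, +0.3 °C/decade trend), and
six planted spring droughts (April–June precipitation shifted by −2.5
interannual sd, +1.5 °C) spaced 7–8 years apart. Cells follow a logistic
earlywood→latewood transition at relative position 0.75 (width 0.05):
expected lumen diameter falls 26 → 11 µm, expected wall thickness rises
3 → 5.5 µm, with lognormal cell noise (sd 0.25 and 0.15); wall area uses a
square-lumen geometry $(\sqrt A + t_r + t_t)^2 - A$. Ring width follows a
negative-exponential age trend (standard convention; detrending removes it
anyway) with mild spring-precipitation sensitivity. The planted anatomical
signal multiplies expected earlywood wall thickness in drought years and
the year after, per forest type; the default is the legacy pattern of
interest — ×1.15 the year after a drought in the pure group, nothing in
the mixed group. All randomness flows from one root seed through named
substreams (climate, rings, cells), so a fixed config is byte-reproducible
while components stay independently perturbable.

What it does *not* emulate: cambial phenology (cells appear with ideal
stratified positions, not intra-seasonal timing), image-segmentation
artifacts, missing or wedging rings, age-dependent cell anatomy, the oak
co-occupants, and any spatial structure among trees. Passing tests
therefore demonstrate that the statistical machinery recovers known
effects under clean conditions — not that those effects are identifiable
in any particular real dataset.

**Recovery experiment.** Fifty replicate datasets at the conditions above
(effect ×1.15, six droughts, nine trees per group, 150 cells/ring): the
before-vs-after KS contrast on anatomical density flags the pure group
(p < 0.05, with the mean shift upward) and not the mixed group in >90% of
replicates; fifty null replicates (all multipliers 1) flag either group in
well under 10%. These sizes keep the full suite within a few minutes while
leaving the conclusions unambiguous.

## 6. Degenerate inputs and edge behavior

Empty sectors stay missing through profiles and normalization; a part with
no cells yields an annual record with `n_cells = 0` and missing traits;
series shorter than five years return their mean as the spline fit (with a
warning); prewhitening passes short or constant series through at order 0;
a degenerate bootstrap distribution collapses its interval onto the point
estimate with a warning; drought phases without eligible years are omitted
with a message rather than an error. The cell reader rejects malformed
rows (line numbers logged, attached as an attribute) and refuses files
with missing required columns or no valid rows.

## 7. Known limitations

The stand table ships the published plot-level values of the two trials it
describes; their printed basal areas are rounded, so stand-density indices
recomputed from stems and basal area differ from the printed SDI column by
up to ~2% — group means are taken over the printed per-plot values.
Thornthwaite PET and the full-record SPEI calibration are conventions, not
reconstructions of any particular station processing, so SPEI values are
comparable to published site analyses only qualitatively. The permutation
KS default treats rings as exchangeable units; if rings within a tree were
strongly correlated beyond the ring level, a tree-level permutation would
be the conservative extension.
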