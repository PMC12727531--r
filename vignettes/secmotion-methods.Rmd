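---
title: "Methods: motion-based translation classification and organelle proximity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motion-based translation classification and organelle proximity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secmotion)
```

## The measurement model

A secretome mRNA engaged by ER-bound ribosomes is tethered to the membrane
and explores only a small neighbourhood; the same molecule released from
translation diffuses freely in the cytosol. `secmotion` turns this contrast
into a per-molecule classifier and a set of ensemble statistics.

Each trajectory is a time-ordered sequence of 2D localizations
$(x_i, y_i)$ in micrometres at a fixed frame interval. Its single-lag MSD
is the average squared displacement over all available consecutive-frame
pairs,

$$\mathrm{MSD}_\tau = \frac{1}{n}\sum_{i=1}^{n}
  \big[(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2\big],$$

evaluated at $\tau = 1$ s. A trajectory is *translating* when
$\mathrm{MSD}_\tau$ is strictly below the cut-off (0.055 µm² for mRNA;
0.04 µm² for ribosome tracking), *non-translating* otherwise, and
*unclassified* when it carries fewer than 10 localizations. The
translating fraction of a cell is computed over classified trajectories
only.

The population (ensemble) MSD is the mean squared displacement over all
trajectory pairs at each lag. Its first four lags are fitted by ordinary
least squares with

$$\mathrm{MSD}(\tau) = 2 n D_\mathrm{app}\,\tau + 4\sigma^2,
  \qquad n = 2,$$

so the slope yields the apparent diffusion coefficient and the intercept
the static localization error $\sigma$. Only the leading lags are used
because confinement bends the curve at longer lags; for confined
populations $D_\mathrm{app}$ is reported as an *effective* coefficient,
with no confinement-model correction.

Heterogeneous populations are resolved by fitting the pooled single-lag
displacement magnitudes $r$ with the mixture cumulative distribution

$$\mathrm{CDF}(r) = 1 - \sum_{j=1}^{k} A_j\,
  e^{-r^2 / (4 D_j t)}, \qquad k \le 3,$$

with $A_j \ge 0$, $\sum_j A_j = 1$, $D_j \ge 0$.

## Choices where the procedure was open

Several details of the analysis admit more than one reasonable reading;
the package fixes them as follows.

* **All lag-1 pairs, minimum 10 localizations.** The per-trajectory MSD
  averages every available consecutive-frame pair rather than exactly the
  first nine; using all pairs is the lower-variance estimator consistent
  with the sum above, and the 10-localization minimum keeps the shortest
  classified track at 9 displacements. Frame gaps (missed detections)
  contribute no pairs: they are skipped and counted, never bridged as
  longer lags.
* **Strict cut-off.** A trajectory exactly at the threshold is
  non-translating; classification is monotone in MSD by construction.
* **ECDF, not histograms.** The CDF mixture is fitted to the empirical CDF
  evaluated at the sorted sample (evenly thinned above 2000 points), since
  any binning choice loses information and none is canonical.
* **Nuclear removal is strict.** A single localization inside the nuclear
  mask excludes the whole trajectory; the cytoplasmic label requires all
  points (configurable fraction) inside the cell mask.
* **Junction = skeleton branch point.** ER junctions are detected by Otsu
  binarization, Zhang–Suen thinning, and marking skeleton pixels whose
  crossing number (0→1 transitions around the 8-neighbour cycle) is at
  least 3, then merging branch points within 0.25 µm to their centroid.
  The crossing number, rather than a raw neighbour count, is robust to the
  two-pixel staircases thinning leaves on diagonal lines. This matches the
  biological definition of a three-way tubule junction.
* **Greedy nearest-first matching.** Puncta are associated with
  trajectories per frame under the ≤ 2-pixel radius, assigning pairs in
  order of increasing distance with ties broken by punctum then track id —
  deterministic, one-to-one per frame, and identical to the optimal
  assignment whenever candidates do not conflict.
* **Half-open distance bins.** The proximity profile uses eight 500-nm
  bins centred 0.75–4.25 µm with edges $[c - 0.25, c + 0.25)$; the
  normalized value of the 4.25 µm reference bin is exactly 1 by
  construction, and an empty reference bin is an error, never an
  interpolation. Distances are 2D (image plane).
* **Per-frame minimum lysosome distance.** Distances are computed per
  frame and reduced by minimum per track (configurable), since the
  protocol references "minimum distance" without fixing the reduction.
* **Kinetics.** Time origin sits at the event frame (bleach or
  activation), pre-event samples carry negative times, and FRAP traces are
  normalized to the mean of the 10 pre-bleach frames (idempotent).
  Recruitment normalization uses the mean of all pre-activation frames.
  The saturation plateau is a *fitted* parameter of
  $I(t) = b + p\,(1 - e^{-kt})$, not the maximum observed value, which
  makes the half-time $t_{1/2} = \ln 2 / k$ robust to noise spikes and
  invariant under affine intensity rescaling; the interpolated-crossing
  estimate is reported alongside and flagged when the two disagree by more
  than 20%. A fit whose $t_{1/2}$ exceeds half the observed window is
  rejected as "no plateau" with advice to acquire longer.

## Numerical details

The CDF mixture is non-convex, so the Levenberg–Marquardt fit runs from
eight quantile-derived starts (log-parameterized weights and
diffusivities enforce the simplex and positivity constraints smoothly) and
keeps the lowest residual sum of squares; when the component count is not
fixed, models with 1–3 components compete by BIC on the ECDF residuals.
The model is not identifiable for close diffusivities: fitted components
whose $D$ differ by less than two-fold are merged in the report (flagged),
and components below 2% weight are pruned as fitting noise. Negative
fitted slopes or intercepts in the ensemble MSD line are clamped to zero
and flagged rather than propagated as imaginary $\sigma$.

Coordinates follow the image convention (origin at the image corner,
pixel centres at $(i + 0.5)\,\times$ pixel size, frames 0-based with
$t =$ frame $\times$ frame interval unless explicit times are supplied).
The pixel size of the camera system is a required configuration value with
no default.

## What the synthetic generators emulate

The simulator draws, per time step and Cartesian axis, an independent
zero-mean Gaussian displacement of standard deviation $\sqrt{2 D\,
\Delta t}$ (the 1D Brownian propagator), in 2D for analytic checks or in
3D projected to the image plane to mirror quasi-2D imaging near the
coverslip. Localization error is added as independent per-frame Gaussian
noise per axis — additive, not cumulative, which is exactly what produces
the $4\sigma^2$ intercept. Confinement is modelled as reflection at a
circular boundary around the start position (radial folding handles steps
larger than the boundary); uniform occupancy of a disc of radius $R$
gives a long-time plateau near $R^2$, so a 0.1 µm radius sits far below
the 0.055 µm² cut-off and a free population at $D = 0.1$ µm²/s sits far
above it. Mixtures carry per-trajectory ground-truth labels.

Synthetic ER networks place branch nodes on a jittered grid joined by the
grid's 4-neighbour lattice, with short axis-aligned terminal stubs raising
every node to degree ≥ 3 — polygonal, near-orthogonal tubule meshes like
the peripheral ER. Shallow-angle intersections are avoided by
construction: at grazing angles the skeleton branch point migrates along
the tubule by roughly width$/\tan(\theta/2)$ and the junction is not
resolvable at imaging resolution, a physical limit of any skeleton-based
detector, not of this implementation. Kinetic fixtures are saturating
exponentials with known half-time; the FRAP variant has a 10-frame
pre-bleach plateau and instantaneous bleach.

The generators deliberately omit photophysics (blinking, bleaching),
non-Gaussian camera noise, motion blur, tracking errors (misconnections),
and anomalous subdiffusion. Passing recovery tests therefore demonstrates
that the estimators are correct for their stated models at the simulated
sample sizes — not that real trajectories satisfy those models; on real
data the classification threshold and localization error must be
interpreted against those unmodelled effects.

## Problem sizes and tunables

The recovery checks run at: 500 tracks × 100 steps for the
$D_\mathrm{app}/\sigma$ calibration ($D = 0.01$ µm²/s, $\sigma =
0.02$ µm — the intercept is small relative to the slope, so long tracks
are used for calibration); 1000-track mixtures at confined fractions
0.2/0.5/0.86 for classifier recovery (agreement judged against the 95%
binomial CI of the realized mixture); 5000 displacements for the
three-component CDF fit ($A = 0.3/0.4/0.3$, $D = 0.5/0.05/0.005$ µm²/s);
25-junction networks at 0.2 µm tubule width; 6000 puncta for the profile;
and 50 noisy replicates for kinetic recovery at the 7.9 s and 26 s
half-times used throughout as constructed round-trip rates.

Key tunables, all surfaced in `classification_config()` and the relevant
function arguments rather than hard-coded: MSD cut-offs (0.055 / 0.04
µm²), minimum localizations (10), lag (1 s), match radius (2 pixels),
junction merge radius (0.25 µm), colocalization radius (0.3 µm),
proximity bins (0.75–4.25 µm by 0.5), pre-bleach frames (10), rendering
blur (0.05 µm).

## Known limitations

Per-trajectory MSD at a single lag cannot separate slow free diffusion
from weak confinement near the threshold; the CDF mixture assumes pure
Brownian species at one lag (no state switching within a trajectory — no
HMM segmentation); junction detection inherits skeletonization's
resolution limits on thick or dim tubules; and FRAP fitting reports a
single saturating exponential, not a reaction–diffusion model, matching
how such recovery curves are typically summarized.
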