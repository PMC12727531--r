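# secmotion

Motion-based analysis of secretome mRNA translation on the endoplasmic
reticulum (ER), from single-particle trajectories.

mRNAs encoding secretory and membrane proteins are translated on the ER
surface, where engaged ribosomes anchor them and sharply restrict their
motion; releasing the ribosomes (e.g. with puromycin) frees the mRNA. A
single molecule's mobility therefore reports its translation state.
`secmotion` implements the full quantitative chain used in this kind of
live-cell imaging study:

- **Per-trajectory confinement classification.** For each tracked mRNA the
  lag-time MSD is computed as
  `MSD_tau = sum_i ((x_{i+1} - x_i)^2 + (y_{i+1} - y_i)^2) / n`
  at tau = 1 s, and the molecule is called *translating* when
  `MSD_tau < 0.055 um^2` (a separate 0.04 um^2 cut-off serves ribosome
  tracking). The translating fraction of a cell is the classified-track
  fraction below the cut-off.
- **Ensemble diffusion fitting.** The population MSD is fitted on its first
  four lags with `MSD(tau) = 2 n D_app tau + 4 sigma^2` (n = 2 dimensions),
  yielding the apparent diffusion coefficient `D_app` and the static
  localization error `sigma`.
- **Displacement-CDF mixture fitting.** Pooled single-lag displacements r
  are fitted with the 1-3 component model
  `CDF(r) = 1 - sum_j A_j exp(-r^2 / (4 D_j t))`
  to resolve fast/medium/slow diffusive species and their fractions (e.g.
  freely diffusing, scanning and translating ribosome pools).
- **Spatial statistics at organelles.** ER tubule junction detection
  (Otsu threshold, skeletonization, crossing-number branch points),
  nearest-junction/lysosome distances, a puncta-to-trajectory matcher with
  the <= 2 pixel rule used for SunTag/mRNA correlation, and distance-binned
  intensity profiles (500-nm bins from 0.75 to 4.25 um, normalized to the
  4.25 um bin).
- **Kinetics.** FRAP normalization to the 10-frame pre-bleach level and
  half-saturation times `t_1/2 = ln 2 / k` of optogenetic ER-lysosome
  recruitment traces via saturating-exponential fits.
- **A Monte Carlo simulator** for Brownian and confined motion (per-axis
  Gaussian propagator of SD `sqrt(2 D dt)`, reflecting circular
  confinement, per-frame localization noise), plus synthetic ER networks,
  distance-dependent puncta and kinetic traces — every analysis stage is
  testable against known ground truth without any imaging data.

## Worked example

```r
library(secmotion)

# 500 tracks, 86% confined ("translating-like"), with ground truth
sim <- simulate_translation_mixture(500, 0.86, seed = 7)
msd <- trajectory_msd(sim$tracks, classification_config())
translating_fraction(msd)
#> 0.866
head(msd, 3)
#>   track_id msd_lag1_um2 n_disp           label
#> 1        1  0.531893062     20 non_translating
#> 2        2  0.005186904     20     translating
#> 3        3  0.006069719     20     translating

fit_dapp(ensemble_msd(sim$tracks, 4))
#> Ensemble MSD fit (first 4 lags): D_app = 0.01434 um^2/s, sigma = 0.02742 um

r <- sample_cdf_mixture(5000, c(0.3, 0.4, 0.3), c(0.5, 0.05, 0.005),
                        lag_t = 1, seed = 7)
fit_cdf_mixture(r, 1, n_components = 3)
#> Displacement-CDF mixture fit at lag 1 s:
#>   component 1: A = 0.300, D = 0.5218 um^2/s
#>   component 2: A = 0.413, D = 0.05063 um^2/s
#>   component 3: A = 0.288, D = 0.004586 um^2/s
#>   rss = 0.004464, 3 component(s) fitted

k <- synth_kinetic_trace("recruitment", plateau = 1, rate = log(2) / 7.9,
                         noise_sd = 0.02, seed = 7, n_frames = 120)
fit_half_time(k$trace)
#> Half-saturation fit (exponential_fit): t1/2 = 8.09 s (rate 0.08568 /s, plateau 2.003)
```

The translating fraction recovers the constructed 86% mixture; the
ensemble fit reports the *effective* diffusivity of a mostly confined
population (hence above the per-trajectory expectation); the CDF fit
resolves all three diffusive species and their fractions; and the
half-saturation fit recovers the constructed 7.9 s recruitment half-time
from a noisy trace.

Real data enter through `read_tracks()` (TrackMate-dialect XML or CSV),
`read_image_stack()` (TIFF masks/movies) and plain CSV time series;
`apply_compartment_mask()` restricts analysis to cytosolic trajectories.
The `run_*()` functions (and the thin `inst/cli/secmotion` wrapper with
subcommands `simulate`, `classify`, `cdf-fit`, `junctions`, `proximity`,
`frap`, `recruit`, `report`) orchestrate the same steps over files with a
YAML configuration and per-stage provenance manifests.

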