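---
title: "Steady-state cross-correlation analysis of two-colour localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state cross-correlation analysis of two-colour localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssxcorr)
```

## The problem

Single-molecule localization microscopy (PALM/STORM) reconstructs images
from sparse, stochastically blinking fluorophores.  In fixed samples the
co-distribution of two labelled species is quantified by the pair
cross-correlation of the two localization channels.  In live cells,
however, molecules move between frames, and a correlation computed over
all localizations irrespective of time, `C(r, <tau>)`, washes out any real
structure: localizations recorded seconds apart no longer report the same
configuration.  The steady-state approach restores the information by
correlating only localization pairs recorded *simultaneously* — or at a
controlled time lag — and pooling those pairs over a window during which
the system is assumed stationary.

## The estimator

For channels 1 and 2, distances between channel-1 localizations in frame
*i* and channel-2 localizations in frame *i + tau* are histogrammed into
radial bins of width `dr` to give `M(r)`.  The number of pair comparisons
is

    N = sum_i  n1_i * n2_(i+tau)

with `n_c,i` the per-frame counts; in the time-averaged mode every
cross-channel pair counts and `N = n1 * n2`.  The expected histogram for
uniformly distributed particles is `mu(r) = dA(r) * rho0 * W(r)`, where
`dA = 2 pi r dr` is the annulus area, `rho0 = N / A_ROI` the mean pair
density, and `W(r)` the radially averaged normalized autocorrelation of
the ROI mask, computed with zero-padded FFTs.  `W` corrects for pairs
lost over the ROI boundary: it equals the average fraction of an annulus
of radius `r` around a uniformly drawn interior point that stays inside
the ROI.  The correlation function is then simply

    C(r, tau) = M(r) / mu(r),

the relative probability of finding a cross-channel pair at separation
`r` compared to randomly placed particles.  `C = 1` means no
co-structure; `C > 1` enrichment; `C < 1` depletion.

Since `M` and `N` are independent counting variables with Poisson
statistics (`var(M) = M`, `var(N) = N`), error propagation gives

    sigma_C^2 = C^2 (1/M + 1/N),

which the package validates against scrambled-frame resampling
(`scrambled_resample()`).  In sparse mode `var(M)` is taken as `M + 1` so
empty bins report a finite uncertainty; it switches on automatically when
a window holds fewer than 100 pairs in total.

Under the assumption that the observed organization reflects an
equilibrium process, the correlation maps onto an effective interaction
free energy, the potential of mean force, `PMF(r) = -kT ln C(r)`
(`pmf_from_correlation()`, reported in kT units), and onto the density of
partners at distance `r`, `rho(r) = C(r) * <rho>`, whose excess integral
counts the expected surplus partners within a radius
(`density_from_correlation()`).

## Mobility from the same data

The same machinery applied within one channel gives `G(r, tau)`, the
correlation between localizations of the same fluorophore separated by a
lag.  For a mobile probe its short-range part is dominated by self-pairs
— the same molecule seen twice — so, normalized to unit area
(`pdf_from_G()`), it is the probability density of a displacement `r` in
lag `tau`, without any trajectory linking.  For 2-D Brownian motion this
density is a zero-centred Gaussian whose width is the mean squared
displacement, `MSD = 4 D tau`; a two-population system is a mixture of
two such Gaussians with slow fraction `alpha` (`fit_single()`,
`fit_two()`).  When the slow state reflects transient binding, a step
spanning a lag counts as slow only if the molecule remains bound
throughout, so `alpha(tau) = alpha(0) exp(-tau / tau0)` with `tau0` the
inverse off-rate (`fit_alpha_decay()`, `mobility_analysis()`).

Two estimator details deserve note, both documented design choices:

* **Background subtraction.**  In the edge-corrected normalization,
  uncorrelated pairs of different molecules contribute exactly `G = 1` in
  expectation.  `pdf_from_G()` subtracts that uniform baseline by default
  before normalizing, so the estimator remains unbiased when labelling
  density is not negligible.  At the very low per-frame densities typical
  of live-cell experiments the subtraction changes little
  (`background = "none"` reproduces the raw normalization).
* **Weighting and width bounds.**  The least-squares fits use
  inverse-variance weights from the Poisson pair counts, which are
  statistically efficient when the mixture model is exact — single-lag
  `fit_single()`/`fit_two()` calls use them unmodified, and their
  standard errors are then well calibrated.  In the multi-lag
  `mobility_analysis()` pipeline the two-Gaussian model is only an
  approximation (partially bound steps, residual cross-molecule
  structure), and tail bins with vanishing counting error would amplify
  that mismatch into a degenerate "flat background" optimum; there the
  variance is floored at 0.5% of the peak density (`floor_frac`).  For
  the same reason both mixture widths are bounded above by
  `(0.75 r_max)^2` and interior optima are preferred over bound-hitting
  ones: a Gaussian component much wider than the analysis window is
  indistinguishable from background.  If a fitted width reaches the
  bound, a warning suggests increasing `r_max`; the analysis window
  should cover roughly three standard deviations of the fastest
  population at the largest lag analysed.

## Validation simulators

All tests and the acceptance analysis run on data the package generates
itself:

* `lj_simulate()` — 64 atoms in two dimensions interacting through a
  Lennard-Jones potential at reduced density 0.05 (box side
  `sqrt(64/0.05)`, about 36 sigma), integrated with velocity Verlet at
  `dt = 0.005` under periodic boundaries.  After Gaussian velocity
  initialization and an equilibration phase with periodic rescaling to
  the target temperature (default `T* = 1`), production is plain NVE, and
  positions are saved every 5 steps.  The interaction cutoff is 2.5 sigma
  with the potential shifted to zero at the cutoff, a standard choice
  that keeps the energy bookkeeping consistent at this system size; the
  temperature is configurable and recorded in the output rather than
  asserted.  The atoms are randomly split into two equal colour groups,
  so the cross-colour correlation estimates the fluid's pair correlation
  g(r), and at low density `-kT ln C` reproduces the pair potential up to
  small many-body corrections: the recovered well sits near
  `2^(1/6) ~ 1.12 sigma` with depth close to epsilon.
* `brownian_simulate()` — free diffusion with optional two-state binding:
  channel-2 particles act as binding sites; channel-1 particles bind at
  rate `k_on` when within a capture radius (default 50 nm, echoing the
  analysis threshold) and release at `k_off`, co-moving with the site
  while bound.  Waiting times are exponential to machine accuracy at the
  frame resolution.
* `observe_smlm()` — the stochastic observation process: per-frame
  Bernoulli blinking with probability `p_on`, Gaussian localization
  noise, and spectral bleed-through modelled at the localization level: a
  channel-1 emission spawns, with probability `bleed_prob`, a
  *simultaneous, position-correlated* channel-2 record.  This reproduces
  the characteristic artefact signature — inflation of `C(r -> 0,
  tau = 0)` with `C(r, <tau>)` unaffected — and the package's
  countermeasure, `extrapolate_tau_zero()`, which fits `C` versus `tau`
  per bin over lags free of bleed-through and evaluates at zero lag.

What the simulators deliberately do not emulate: camera-frame spot
fitting and its failure modes, dark-state photophysics beyond Bernoulli
blinking, photobleaching decay, 3-D effects, and spatially varying
labelling efficiency.  Passing tests therefore demonstrate the
correctness and calibration of the estimators under the stated
observation model, not robustness to every artefact of real acquisitions.

## Preprocessing

Stage drift is estimated per 500-frame group from the FFT
cross-correlation of consecutive group reconstructions (50-nm raster by
default), with the peak refined to sub-pixel precision by a separable
quadratic fit in log intensity — exact for a Gaussian peak — and applied
as block-constant shifts; whether to interpolate within groups is left
open, and block-constant is the implemented convention.  Chromatic
registration fits a bivariate polynomial (default degree 2, a standard
choice for chromatic warps that a few tens of fiducial beads can
constrain) by least squares from bead control points, reporting the rms
residual.

## Numerical choices and conventions

* Radial bins are half-open `[c - dr/2, c + dr/2)` with the first centre
  at `dr/2`; `2 pi r dr` is the exact annulus area for centred bins.
  Default `dr = 25 nm` matches the reconstruction pixel.
* Raster pixels are half-open with a y-up row convention; points on a
  right/top edge belong to the next pixel.
* The edge factor is rasterized at `min(dr, 25 nm)` and zero-padded to
  twice the mask extent before the FFT, so no wraparound reaches any
  representable displacement.
* Bins where `mu = 0` (outside the edge-factor support) are reported as
  undefined (`NA`), excluded from averages and fits, never propagated as
  infinities; `C <= 0` bins yield undefined PMF values rather than
  `-Inf`.
* Frame indices are 0-based and lags are integers in frames; conversion
  to seconds happens only at presentation, through the table's
  `frame_interval`.
* The time-averaged image-method curve divides the density-normalized
  FFT image cross-correlation by the mask autocorrelation, which supplies
  the area normalization and edge factor in one step; its agreement with
  the pairwise time-averaged mode (within 5% beyond two pixels) is the
  pinned contract for that code path.
* Inverse-variance weighting is used wherever curves are averaged over
  lags, with the standard error of the weighted mean attached.  The
  time-average in `average_over_tau()` excludes `tau = 0` by caller
  convention, since that is the lag bleed-through contaminates.
* All stochastic components accept explicit seeds and are bit-reproducible
  under them.

## Problem sizes used in the bundled validation

The test-suite and acceptance analyses are sized for a single CPU: the
Lennard-Jones validation uses 40,000 equilibration plus 20,000 production
steps (4,000 snapshots of 64 atoms); the variance validation uses 150
scrambled 20-frame windows at ~30 localizations per channel per frame;
the method-equivalence and null-calibration checks use 10^4-point single
frames; mobility recovery uses on the order of 10^5 displacement steps;
the binding simulation runs 150 molecules over 1,500 frames at 0.03
s/frame.  These sizes give standard errors a few percent or better for
every tested quantity.

## Known limitations

* The displacement-PDF analysis assumes the analysis window contains
  essentially all displacement mass of the fastest population; windows
  that truncate it bias the slow fraction upward (the width bound and its
  warning guard against the degenerate case).
* Cross-molecule structure that is itself clustered (e.g. many labelled
  molecules co-occupying one immobile site) contributes slow pair mass
  that does not decay with the single-molecule off-rate; at high site
  occupancy `tau0` from `alpha(tau)` overestimates the dwell time.
* The analytic variance treats bins and windows as independent; temporal
  correlations longer than a steady-state window (persistent complexes,
  slow photophysics) make it an underestimate, which is precisely why
  `scrambled_resample()` exists.
* Localization noise broadens short-range correlations but preserves the
  integral of `C - 1`; the apparent MSD offset of `4 sigma_loc^2` for
  immobile molecules is reported, not subtracted.
* Block-constant drift correction leaves sub-group drift (< 500 frames)
  uncorrected.
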