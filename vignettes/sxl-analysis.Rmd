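---
title: "Serial X-ray liquidography: models, reduction and kinetic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial X-ray liquidography: models, reduction and kinetic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sxlkit)
```

## The measurement this package models

Serial X-ray liquidography (SXL) is a fixed-target variant of time-resolved
X-ray solution scattering. Instead of re-exposing one capillary of protein
solution over and over, the sample is spread across a chip of 40 × 30
sealed microchambers (a few nanolitres each). The chip is raster-scanned
through the beam in a zigzag: under the *dual-probing* scheme each chamber
receives one X-ray exposure before the optical pump pulse (the laser-off
ground-state reference) and one after it at the programmed pump–probe
delay; under *single-probing* each chamber is exposed once and off/on
partners come from adjacent chambers. Because every chamber is used at most
once per pair, irreversible photoreactions and damage-prone reversible ones
can be probed without the signal decaying under repeated exposure, and the
per-difference-curve sample cost drops by roughly two orders of magnitude
relative to a capillary.

The observable is the difference scattering curve
\(\Delta S(q, t) = S_\mathrm{on}(q, t) - S_\mathrm{off}(q)\)
on a grid of log-spaced delays. Low *q* reports global size and oligomeric
state (dissociation of a homodimer produces a negative low-*q* lobe;
association raises the Guinier region), high *q* local structure.

`sxlkit` implements the full chain — synthetic data generation with known
ground truth, reduction, SVD/kinetic analysis, and budget arithmetic — as
pipe-friendly functions over tibbles and small S3 result objects with
`tidy()`, `glance()` and `autoplot()` methods.

## The synthetic-data generator

No public raw SXL datasets exist, so verifiability rests on a generator
whose truth is exactly known and whose structure mirrors the instrument:

* **Structural models.** Species are homogeneous spheres or rigid
  dimers-of-spheres. The sphere form factor is
  \(P(q) = \left[3\,(\sin qR - qR\cos qR)/(qR)^3\right]^2\) and the dimer
  intensity carries the Debye two-body term
  \(I(q) = 2A\,P(q)\,[1 + \mathrm{sinc}(qd)]\), so a dimer's forward
  intensity is exactly four times a monomer's. This is deliberately not an
  atomistic calculation: spheres suffice to produce the dissociation and
  association difference-signal signatures with closed-form truth.
  The default dimer separation is \(d = 2.2R\) — clearly separated spheres
  with a strong interference term, avoiding the degenerate touching case.
* **SADS bases.** Species-associated difference scattering curves are
  \(\mathrm{SADS}_i(q) = I_i(q) - I_\mathrm{ground}(q)\). By default each
  SADS is expressed in the *gauge fixed by the normalisation window*: the
  component proportional to the ground curve inside 1.4–1.6 Å⁻¹ is
  projected out. After curves are normalised to that window such a
  component is unobservable, so this gauge makes the generated truth
  exactly the quantity the reduction chain can recover — it is the
  synthetic analogue of the solvent-dominated high-*q* region of real data
  being delay-invariant. The projection coefficients are below 1 % here, so
  low-*q* signs and shapes are untouched.
* **Kinetics.** A single sequential chain
  \(I_1 \to I_2 \to \dots \to P\) with first-order rates, excited fraction
  \(\varphi\), and an optional recovery rate back to the ground state.
  Because difference signals determine only the product
  \(\varphi \cdot \mathrm{SADS}\), \(\varphi\) defaults to 1 and the yield
  is absorbed into SADS amplitudes.
* **Noise.** Gaussian and heteroscedastic on the azimuthally averaged
  curves, \(\sigma(q) = s\,I(q) + \text{floor}\), plus a per-chamber
  multiplicative jitter shared by both exposures of a chamber (the
  illumination/volume variation that window normalisation removes
  exactly). The instrument papers report signal-to-noise only
  qualitatively, so the defaults — 2 % relative noise, 1 % jitter — are a
  choice, made once, of what a practitioner would call a realistic
  azimuthally averaged shot-noise level; both are configurable. Identical
  seeds reproduce datasets bit-exactly.
* **Capillary degradation.** The conventional-setup comparison is modelled
  as geometric loss: a fraction *f* of the active population is converted
  per shot to a damaged species, so the difference-signal amplitude after
  *r* repetitions is \((1-f)^r\), while the damaged fraction contributes a
  large-\(R_g\) aggregation term that monotonically raises the static
  Guinier intensity.

What passing tests on these synthetics do **not** show: robustness to
detector artefacts (polarisation, solid angle, parasitic scattering),
non-Gaussian outliers beyond injected spikes, solvent-heating signals, or
deviations from strictly sequential kinetics. The generator is a
correctness instrument, not a beamline emulator.

## Reduction

Reduction follows the standard TRXL recipe, each step a separate tested
operation:

1. **Azimuthal integration** (`azimuthal_integrate()`): pixels are binned
   by \(q = (4\pi/\lambda)\sin(\theta/2)\) into half-open bins
   \([q_{lo}, q_{hi})\); bin centres are arithmetic midpoints, intensities
   are unweighted pixel means, and \(\sigma = \mathrm{sd}/\sqrt{n}\). The
   convention is declared so a per-pixel double-loop oracle can check it
   exactly.
2. **Hampel despiking** (`hampel_despike()`): points deviating from the
   rolling median by more than \(n_\sigma \times 1.4826 \times\) MAD are
   replaced by that median; edges use truncated windows. Default half-width
   5 points and threshold 3 — the filter is named in the method literature
   without parameters, and these are the common defaults.
3. **Window normalisation** (`normalize_curve()`): curves are divided by
   the trapezoidal integral of intensity over the open window
   (1.4, 1.6) Å⁻¹. An integral (rather than a mean or sum) is
   scale-invariant under grid refinement; the choice of statistic is
   config-exposed because the convention is not uniquely fixed in the
   literature. Normalisation is idempotent and removes per-chamber scale
   exactly.
4. **Pairing and subtraction** (`pair_and_subtract()`): dual-probing pairs
   the two exposures of each chamber; single-probing pairs adjacent
   columns within a row (the simplest geometry consistent with
   two-rows-per-40-pairs operation). Uncertainties combine as root sum of
   squares; orphan chambers are reported by (row, column).
5. **Averaging with outlier rejection** (`average_by_delay()`): per delay,
   curves whose RMS distance to the pointwise median (in median-σ units)
   exceeds 3 are rejected before averaging. The rejection rule is a
   median-based choice of ours; the field practice is chamber-consistency
   inspection without a stated rule. For noise-free data the robust scale
   of deviations substitutes for σ so identical curves are never rejected.
6. **Guinier analysis** (`guinier_fit()`): iteratively self-consistent fit
   of \(\ln I\) vs \(q^2\) with the window capped at
   \(qR_g \le 1.3\) (classical globular limit; 1.0 for sphere benchmarks),
   weighted by \((I/\sigma)^2\) — the inverse variance of \(\ln I\) —
   falling back to \(I^2\) for noiseless curves.

## Kinetic analysis

* **SVD** of the windowed matrix (default *q* ∈ [0.03, 1.0] Å⁻¹, all
  delays), with a deterministic sign convention (largest-magnitude LSV
  element positive).
* **Significance selection**: a component counts as significant when its
  singular value exceeds 5× the noise floor estimated from the trailing
  singular-value plateau *and* the lag-1 autocorrelations of both its
  singular vectors exceed 0.6. "Significant" is used but never defined in
  the experimental literature; this floor-plus-autocorrelation rule is the
  standard transient-spectroscopy practice and every threshold is an
  argument. It assumes the *q* grid resolves the signal's fringes — on a
  very coarse grid the LSV autocorrelation of a genuine component can drop
  below threshold.
* **RSV exponential fitting** (`fit_rsv_exponentials()`):
  \(v(t) = \sum_i a_i e^{-t/\tau_i} + c\) by Levenberg–Marquardt with
  multi-start over log-spaced τ combinations (28 starts for two
  exponentials), since log-spaced delay grids are rich in local minima.
  The constant offset accommodates signals that saturate inside the probed
  window. Fitting is done on the first significant RSV, matching reported
  practice; uncertainties are 1σ from the fit covariance via the delta
  method on \(\log\tau\) (how the experimental ± values were estimated is
  not stated; covariance is the reproducible default).
* **Bateman populations** (`bateman_populations()`): the sequential chain
  is solved analytically. Rates closer than a relative gap of 1e-9 would
  make the Bateman denominators cancel catastrophically, so such chains
  are routed through the exact matrix exponential of the chain generator —
  the confluent limit — instead.
* **KCA** (`kca_extract_sads()`): with populations fixed by the model,
  the SADS matrix minimising \(\lVert \Delta S - \mathrm{SADS}\,P^\top
  \rVert_F\) is the row-wise least-squares solution through the population
  pseudo-inverse. No non-negativity or smoothness constraint is imposed by
  default — whether the experimental analysis used any is unstated, and an
  unconstrained solve keeps the noise-free roundtrip exact. Rank-deficient
  population matrices raise an identifiability error naming the
  indistinguishable species pair.
* **Rate refinement** (`refine_rates()`): a variable-projection loop
  (outer Nelder–Mead on log-rates, inner linear SADS solve) that by
  contract never reports a residual above its starting point. With as many
  delays as species the inner solve is exact for *any* rates, so
  refinement is only meaningful when delays exceed species.
* **Recovery in reversible photocycles** is exposed as an optional
  explicit \(P \to\) ground rate; whether the experimental product decays
  on the probed window is system-dependent, so neither treatment is
  asserted as canonical.

## Budgets

`mass_per_ds()`, `per_chamber_mass()`, `photon_budget()`,
`allocate_chambers()` and `efficiency_ratio()` reproduce the
sample-efficiency arithmetic of fixed-target versus capillary operation.
All computation is exact; report values are rounded to two significant
figures half-away-from-zero (the style of the published figures: 3.8, 5.6,
13, 32) and the rounding never feeds back into computation.

## A worked example

```{r, eval = FALSE}
library(sxlkit)

chip <- chip_layout()                                   # 40 x 30, ~32 ng/chamber
plan <- allocate_chambers(chip, delay_grid("half-decade"), rows_per_delay = 3)
basis <- default_dissociation_basis()                    # dimer -> 2 monomers
truth <- kinetic_model(tau = c(1.1e-3, 13.4e-3))

ds <- simulate_dataset(chip, plan, basis, truth,
                       noise_model(relative_sigma = 0.02,
                                   chamber_jitter = 0.01, seed = 1))
dm <- reduce_dataset(ds)
an <- analyze_diffmat(dm)
glance(an)
autoplot(an$kca)
```

## Problem sizes and determinism

The packaged simulation studies use the instrument's own geometries: the
full 1200-chamber chip, the 10-delay half-decade grid (10 µs–316 ms, three
rows per delay) and the 15-delay quarter-decade grid (31.6 µs–100 ms, two
rows per delay), with a 240-point *q* grid from 0.01 to 1.8 Å⁻¹. The noisy
parameter-recovery study runs 50 seeded replicates per kinetic regime at
2 % noise; unit tests use a 6 × 8-chamber miniature of the same structure.
Every random draw flows from a single integer seed, so all datasets,
reports and output directories are bit-reproducible.

## Known limitations

* Strictly sequential chains only; no branched or parallel schemes.
* No absolute-intensity calibration, polarisation or solid-angle
  corrections; synthetic images are ideal isotropic renderings.
* Structural interpretation of SADSs (bead models, form-factor fitting of
  intermediates) is out of scope.
* The Guinier window cap interacts with sampling: for a homogeneous sphere
  the weighted fit at \(qR_g \le 1.0\) recovers \(R\sqrt{3/5}\) to about
  1 %, the intrinsic bias of the Guinier approximation at that cutoff.
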