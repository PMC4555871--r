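---
title: "Models and methods: TGT force-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: TGT force-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgtforce)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the tunable parameters that
matter, and the choices made where the underlying experimental
description leaves the design open.

## 1. The tension gauge tether model

A TGT sensor is a 21-bp DNA duplex anchored to the coverslip through a
biotin on the anchor strand and carrying the NP hapten on the ligand
strand. The biotin position sets the rupture geometry: positions near the
ligand end load the duplex across the helix (unzipping, low rupture
force), positions at the far end load it along the helix (shearing, high
rupture force). The package hard-codes the published position → force
map (1, 2, 4, 7, 11, 15, 18, 21 → 12, 16, 23, 33, 43, 50, 54, 56 pN) as a
bijection; `check_duplex()` verifies complementarity of the two strands
positionally against the reverse complement, with modifications (NP,
biotin) carried as metadata that never alters base pairing.

**Rupture-force distribution.** The experimental characterisation gives
only a mode and a full width at half maximum (5 pN unzipping, 15 pN
shearing). Two parameters determine a Gaussian, so the package models the
rupture threshold as Normal(mean force, FWHM/2.3548) truncated at 0 pN —
the minimal assumption consistent with that description. Truncation is
numerically exact (inverse-CDF sampling restricted to the positive-mass
interval), though for this panel the truncated mass is negligible
(the 12 pN sensor sits 5.7 sigma above zero). Whether the real
distribution is symmetric is unknown; this is an assumption, not a claim.

**Rupture mode of intermediate positions.** The mode is documented for
the force extremes but not per position. Default: positions 1–2
(12, 16 pN) unzip (FWHM 5 pN), positions 4–21 shear (FWHM 15 pN), on the
geometric argument that only anchors at the ligand-proximal end produce
peeling; `tgt_sensor(position, rupture_mode = ...)` overrides per sensor.

**Static thresholds.** The printed forces come from constant-force
(2 s time-under-load) measurements; the model treats them as static
thresholds. `survival_probability()` is simply the upper tail of the
truncated Gaussian — no loading-rate dependence is modelled, and forces
measured under other loading regimes are not comparable.

**FWHM estimation.** `estimate_fwhm()` bins the sample at 0.05 pN,
smooths counts with a boxcar of ~0.25 sample SDs (at least 5 bins),
interpolates the half-maximum crossings linearly, and then removes the
broadening the bin and boxcar introduce
(variance `(w_bin^2 + w_boxcar^2)/12`, exact for a Gaussian peak). The
smoothing scale balances peak-estimate noise (which biases raw FWHM low)
against broadening (which biases it high); at n = 10^5 the estimator's
sampling SD is ~0.04 pN for the 5 pN width and ~0.15 pN for the 15 pN
width.

## 2. The synthetic-imaging world

The generators produce ground-truthed data under the conditions the
experiments describe; their defaults are that stated world, not knobs.

**Optics (`optics_model()`).** Frames default to 512 × 512 px. The pixel
size is not printed anywhere; 0.16 µm/px is chosen so that a
136 × 136-px counting ROI is 473.6 µm², matching the stated ~473.1 µm²
counting area (and consistent with a 100×/1.49 NA objective on an EMCCD
with ~16 µm pixels). PSF sigma defaults to 0.15 µm (diffraction-limited
at that NA). The camera is an EMCCD surrogate with gain 1: Poisson shot
noise on signal photons, a fixed offset (100 counts), Gaussian read noise
(SD 10 counts), values floored at 0. No camera parameters are printed;
these are standard magnitudes.

**Single-molecule fields.** Molecule positions follow a homogeneous
spatial Poisson process at the requested density; each molecule
contributes a fixed photon budget rendered as a pixel-integrated Gaussian
(separable erf form, so the photon sum is exact). The
concentration → density curve `coating_density()` is a monotone (Hyman)
interpolation through the four measured anchors (2 → 0.3, 5 → 4.0,
10 → 19.0, 50 → 29.0 nM → molecules/µm², 0 → 0), saturating above 50 nM;
the interpolant between anchors is a smoothness assumption, only the
anchors are data.

**Synapse response model (`response_model()`).** The per-cell synaptic
accumulation plateau is drawn from the response level implied by
(isotype, sensor force): IgM-type (and the GGM tail-swap chimera) map
forces ≤ 16 pN to *low*, 23–43 pN to *medium* and ≥ 50 pN to *high*;
IgG/IgE-type (and MMG) map every force to *high* — the force-independent
phenotype. Level means default to 1 : 2 : 3.5 (arbitrary units) with
CV 25%, chosen once to qualitatively match the relative bar heights of
the endpoint quantification; the source reports arbitrary units only, so
these are configuration, not claims. (The level spread is specified as a
CV rather than one shared SD so that each level's dispersion scales with
its mean, as cell-to-cell variability does.) Non-conjugated control
tethers ("NC") draw from a baseline mean of 0.2 units. Accumulation
follows saturating growth `A(t) = plateau (1 − e^{−t/τ})` with τ = 120 s
— a time constant that puts the curve near plateau within the 10-min
imaging course, as observed; kinetics beyond that are not specified
experimentally.

**Synapse rendering (`synapse_render_params()`).** The contact footprint
is a disk of area `3 + 12 A(t)` µm². Of the synapse photons
(`3 × 10^4` per accumulation unit per frame), 70% is spread uniformly
over the disk (diffuse membrane-proximal receptor signal — in real TIRF
synapse images the footprint is clearly visible above background) and 30%
is split across microclusters whose count grows as `8 √A(t)`; per-cluster
brightness therefore grows as `√A(t)`, so stronger activation yields both
more and brighter clusters, matching the qualitative observation that
high-force tethers produce "bigger and brighter" microclusters. Clusters
are Gaussians of 1.5× the PSF sigma, placed area-uniformly at least 3 px
apart and one PSF width inside the rim, with a persistent inventory so
time-lapses are temporally coherent.

**What the generator does *not* emulate** — and hence what a green test
does not establish: receptor diffusion and nanocluster substructure,
photobleaching, stage drift, cell-shape irregularity (footprints are
disks), internalisation, and any mechanistic link between tether rupture
and accumulation (the step response is imposed, not derived;
`survival_probability()` is available as a modulator but is deliberately
not wired in by default, because the quantitative link is unknown).
Parameter-recovery results on this world validate the measurement
operators, not the biology.

## 3. Spot detection, fitting and counting

Detection band-passes the image with a difference of Gaussians (sigmas
1× and 3× the PSF sigma in pixels), thresholds local maxima at 5 robust
noise SDs, and thins them by non-maximum suppression at 2 px (brighter
candidate wins). Two numerical points:

- the blur operator renormalises its kernel at the image edge, so a
  constant offset maps to exactly zero band-pass response — detection and
  counting are offset-invariant by construction;
- the noise SD is estimated from the *negative* half of the band-passed
  deviation distribution (spots only push pixels up), which keeps the
  threshold calibrated even on crowded fields where an ordinary MAD is
  signal-contaminated.

Fitting minimises least squares for
`b + A exp(−((x−x0)^2+(y−y0)^2)/(2 s^2))` over a window of half-width
`max(3, ceil(3 sigma_psf))` px, with moment-based starts, `nls` ("port",
bounded) and a BFGS fallback; the centre is constrained to ±1.5 px of the
candidate so a bright neighbour inside the window cannot capture the fit.
Windows clipped by the border are flagged and excluded; non-convergence
is flagged, never fatal. On noiseless model images the fit is exact to
solver tolerance. The model is the *point-sampled* Gaussian while the
renderer integrates over pixels; this mismatch inflates fitted sigma by
1/12 px² in variance and deflates amplitude correspondingly, but the
integrated intensity `2πAs²` — the quantity used downstream — is
invariant to it (and recovers the photon budget to <1%).

Quality filters for counting: convergence, sigma within 0.5–3× the PSF
sigma, amplitude above 3 noise SDs. Elliptical fits are deliberately not
used; spots are round by construction and the symmetric 5-parameter model
is more stable at low photon counts.

**Overlap correction.** At a diffraction-limited PSF, molecules closer
than the detector's two-point resolution merge irrecoverably into one
candidate. `count_spots()` corrects the density with a Palm-probability
argument: for a Poisson process at intensity λ, the probability that a
molecule is the representative of its `s`-neighbourhood is
`(1 − e^{−m})/m`, `m = λπs²`, so observed ≈ true × that factor, inverted
numerically. The merge radius `s` is the pipeline's own two-point
resolution limit, found by bisection on noiseless equal-brightness spot
pairs under the configured band-pass and suppression — a deterministic
property of the detector, not a fitted constant (~2.9 px at the
defaults). Noise still merges marginally-resolved pairs, so corrected
counting is accurate to a few percent at ≤ 0.3 molecules/µm² and degrades
above ~0.5; densities beyond that must go through the MFI calibration
(section 4), mirroring the experimental practice of counting only on
"well-separated spots" surfaces.

## 4. MFI → density calibration

`compute_mfi()` is the ROI mean minus a background estimate, clamped at
zero. The background is the median of a user-designated empty region
(e.g. a blank control field) when given, else the image-wide 10th
percentile; the experimental background method is not described, so the
choice is recorded with the result. For dense surfaces the percentile
fallback would swallow signal — pass a blank-field background there.

The calibration is a through-origin least-squares line,
`slope = Σxy/Σx²`, because the printed relation has no intercept
("surface density = 2.42 × MFI" per ~473.1 µm² counting area). R² is
computed against the through-origin model with the total sum of squares
about zero — conventions differ for no-intercept models, so this is
stated explicitly; it equals 1 exactly on noiseless proportional data.
`mfi_to_density()` divides by the counting area to return molecules/µm².
The acceptance pathway builds the calibration from sparse *counted*
fields (0.05–0.25 molecules/µm²) and then reads dense fields (up to
29 molecules/µm²) off their MFI — the same low-to-high extrapolation the
experiment relies on, valid because summed PSF intensity is linear in
density at any overlap.

## 5. Synapse quantification

`segment_contact()` thresholds the σ = 1 px Gaussian-smoothed frame with
Otsu's criterion and keeps the largest 4-connected component (run-based
union-find). Two guards handle degenerate frames: an exactly/nearly
constant frame returns an empty mask directly, and a contrast guard
rejects segmentations whose foreground–background separation is below 3
robust SDs of the smoothed frame — for pure noise the Otsu split
separates the noise halves by ~1.6 SD, so such frames come back empty
rather than as noise blobs. Frames are segmented independently (cells
are stationary in this geometry; no tracking). The per-frame background
for trace metrics is the median of a 5-px border band outside the mask.
Total FI is `Σ(pixel − background)` over the mask, MFI is total/area;
total FI is additive over disjoint mask partitions and MFI is their
area-weighted mean, which the tests assert as exact identities.
`fit_plateau()` fits `A(1 − e^{−t/τ})` to a trace for plateau recovery.

## 6. Threshold statistics

Pairwise comparisons are Welch's two-tailed t-test by default: the
experimental description says only "two-tailed t tests", Welch is robust
to unequal group variances and coincides with the pooled Student test
when variances match; `var_equal = TRUE` reproduces the pooled variant.
Cross comparisons report raw p-values (matching how the comparisons are
presented) with Holm-adjusted values alongside for transparency.

**Force-level grouping.** No explicit algorithm for declaring "three
thresholds" exists in the source; `group_force_levels()` is this
package's formalisation. It sweeps sensors in ascending force order,
pooling each sensor into the current group unless a two-tailed t-test
against the pooled group rejects, in which case a new group starts —
groups are contiguous in force by construction. The per-boundary level is
Bonferroni-corrected to `alpha/(k−1)` over the `k−1` sweep tests. The
uncorrected sweep (`boundary_adjust = "none"`) splits a genuinely flat
panel with probability `1 − (1−α)^{k−1}` ≈ 30% at α = 0.05 and k = 8,
which both inflates the null split rate far above α and caps three-level
recovery near 77% even with overwhelming per-boundary power; the
correction makes the family-wise false-split probability ≈ α while
leaving power at the true boundaries essentially 1 at the default effect
sizes. Both properties are verified by simulation in the test suite.

## 7. Numerical and degenerate-input conventions

- Seeds: every stochastic entry point takes `seed`; the caller's RNG
  stream is saved and restored, and equal seeds give bit-identical
  output.
- Fits: `nls` tolerance 1e-8, max 200 iterations; zero-residual
  (noiseless) problems are handled by the "port" algorithm; fallback
  BFGS on the SSE with the same tolerance.
- Ties: candidate maxima tie-broken by brightness at suppression;
  duplicate fits (centres within 0.5 px) keep the brighter.
- Degenerate inputs: empty images, zero-area ROIs, empty masks, all-zero
  MFI, n < 2 samples and zero-variance pairs raise immediate errors;
  blank frames segment to area 0 (not an error); per-pair failures in
  cross comparisons are flagged, not fatal.
- `estimate_fwhm()` requires the half-maximum crossings to be bracketed
  by the sample and errors otherwise.

## 8. Known limitations

- Counting above ~0.5 molecules/µm² is biased low despite the overlap
  correction (noise-induced merging); use the MFI pathway there. No
  multi-emitter deconvolution is attempted.
- The rupture model is a symmetric truncated Gaussian with static
  thresholds; loading-rate and bond-lifetime effects are out of scope.
- The three-level response is imposed by configuration; the package
  cannot, and does not claim to, derive activation levels from tether
  mechanics.
- Images are in-memory matrices; there is no TIFF reader/writer in this
  environment, so file-based pipelines must convert externally.
- The grouping procedure assumes approximately normal per-cell
  accumulations within a level; heavy-tailed responses would need a
  rank-based variant, which is not implemented.
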