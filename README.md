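# tgtforce

Quantitative analysis of DNA **tension gauge tether (TGT)** force-sensor
experiments on B cells imaged by TIRF microscopy.

A TGT is a short dsDNA linker between a coverslip and a receptor ligand
(here the NP hapten recognised by B1-8 B-cell receptors). The duplex
ruptures when the cell pulls harder than a threshold set by where the
biotin anchor sits on the anchor strand: pulling across the helix unzips
base pairs sequentially (low force), pulling along it shears all pairs at
once (high force). A panel of eight tethers — biotin at bases
1, 2, 4, 7, 11, 15, 18, 21 giving mean rupture forces
12, 16, 23, 33, 43, 50, 54, 56 pN — turns the coverslip into a mechanical
force gauge: a receptor that needs more than *F* pN to signal cannot
activate on a tether that breaks at *F*. Each threshold is really a
distribution (FWHM 5 pN for unzipping, 15 pN for shearing), modelled here
as a zero-truncated Gaussian.

The package provides, as tested, reusable code:

- **Sensor panel** — strand sequences, the biotin-position → force map,
  rupture-force sampling and tether survival probabilities
  (`build_sensor_panel()`, `check_duplex()`, `sample_rupture_forces()`,
  `survival_probability()`).
- **Synthetic TIRF imaging** — ground-truthed single-molecule fields
  (spatial Poisson molecules, Gaussian PSF, EMCCD-like noise), the
  incubation-concentration → surface-density curve, and B-cell synapse
  endpoint frames / time-lapses whose accumulation follows a three-level
  step response over the force panel for IgM-type receptors and a flat
  response for IgG/IgE-type receptors (`simulate_molecule_field()`,
  `coating_density()`, `simulate_cell_timelapse()`,
  `simulate_condition_panel()`).
- **Spot quantification** — difference-of-Gaussians detection and 2D
  Gaussian fitting `b + A exp(-((x-x0)^2+(y-y0)^2)/(2 s^2))`; integrated
  intensity `2 pi A s^2` is the microcluster volume proxy
  (`detect_candidates()`, `fit_gaussian_2d()`, `count_spots()`,
  `quantify_clusters()`).
- **Density calibration** — background-subtracted MFI and the
  through-origin regression `density per counting area = k × MFI`
  (slope `k = Σxy / Σx²`), used to read surface densities off dense
  fields where single molecules cannot be counted (`compute_mfi()`,
  `fit_calibration()`, `mfi_to_density()`).
- **Synapse quantification** — Otsu contact-area segmentation and
  per-frame MFI / total-FI traces (`segment_contact()`,
  `accumulation_metrics()`, `quantify_timelapse()`,
  `summarize_endpoint()`).
- **Threshold statistics** — Welch two-tailed t-tests, all-pairs cross
  comparisons, and an agglomerative force-sweep that groups the panel into
  statistically distinct activation levels (`t_test_two_tailed()`,
  `cross_compare()`, `group_force_levels()`).

Images are plain numeric matrices (row = y, column = x); stacks are 3-D
arrays or lists of matrices. No image-file I/O is required.

## Worked example

Simulate 40 cells per sensor under the IgM response model and ask how many
statistically distinct activation levels the force panel produces:

```r
library(tgtforce)

panel <- build_sensor_panel()
resp  <- response_model("IgM")
sim   <- simulate_condition_panel(resp, panel, n_cells = 40, seed = 1)
group_force_levels(split(sim$truth$accumulation, sim$truth$force))
#> <threshold_grouping> 3 group(s) at alpha = 0.05 (per-boundary 0.00714286)
#>  force group  n     mean
#>     12     1 40 1.007482
#>     16     1 40 1.018641
#>     23     2 40 1.974951
#>     33     2 40 1.959264
#>     43     2 40 2.103686
#>     50     3 40 3.469314
#>     54     3 40 3.309959
#>     56     3 40 3.242829
```

The sweep recovers the multi-threshold structure: a weak level at
12–16 pN, a medium level at 23–43 pN and a strong level at 50–56 pN
(`mean` is synaptic accumulation in arbitrary units; the per-boundary
level is `alpha / 7`, so the family-wise chance of a spurious split is
~0.05). Under `response_model("IgG")` the same call returns a single
group — force-independent activation.

Individual sensors expose their rupture model directly:

```r
s <- tgt_sensor(21)   # biotin at base 21
s
#> <tgt_sensor> TGT_56pN: 56 pN (shearing, FWHM 15 pN), biotin @21, NP-conjugated
survival_probability(s, 40)
#> [1] 0.994
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the empirical
FWHM of 10^5 rupture forces sampled from the 12 pN (unzipping) and 56 pN
(shearing) sensors, and the R² of the through-origin MFI → density
calibration fitted on a simulated single-molecule calibration series
(sparse fields counted by 2D Gaussian fitting, MFI measured against a
blank-field background, optical gain chosen so that the true relation is
density per ~473 µm² counting area = 2.42 × MFI). Results are written as
JSON keyed `t4`, `t5`, `t7`.
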