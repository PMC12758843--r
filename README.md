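# photocolony

Analysis toolkit for bacterial **structural color** (SC): iridescent
coloration produced not by pigments but by wavelength-selective interference
with the nanoscale order of a colony. In *Flavobacterium* IR1, rod-shaped
cells pack hexagonally into polycrystalline 2-D domains; the packing period
sets the reflected color, and genetic perturbations that narrow the cells
(such as deleting the molybdenum-cofactor gene *moeA*) blue-shift the whole
optical response.

The package is written for microbiologists and biophotonics researchers who
need to go from angle-resolved reflectance measurements (goniometry) and
standard omics tables to quantitative structural parameters and regulation
calls, with every stage testable against synthetic data of known truth.

## What it computes

**Optics.** In scattering geometry, diffraction spots obey the grating
equation

    theta_m = arcsin(m * lambda / d - sin(theta_i)),   m = 0, ±1, ±2, ...

and fitting observed spot positions recovers the in-plane lattice period
*d*. In specular geometry, multilayer interference follows the Bragg–Snell
relation

    lambda_B = 2 * n_avg * d * cos(arcsin(sin(theta_in) / n_avg))

and fitting the peak dispersion recovers the effective refractive index
`n_avg` and layer spacing. `photocolony` provides the forward simulators
(`simulate_scattering_map()`, `simulate_specular_map()`), deterministic
peak extraction (`extract_peaks()`), diffraction-order assignment
(`assign_orders()`), the closed-form sin-space period fit
(`fit_grating_period()`), the multi-start nonlinear dispersion fit
(`fit_specular_dispersion()`), and an RMS-deviation lattice disorder
metric (`disorder_metric()`). Fits carry seeded bootstrap CIs and support
`tidy()`, `glance()`, `autoplot()`.

**Comparative genomics.** Presence/absence summaries of the eight MoCo
pathway genes by SC class (`gene_prevalence()`, `pathway_completeness()`)
and proximity-based operon clustering with a 5 kb gap rule
(`cluster_loci()`).

**Proteomics.** Thresholded differential abundance for a two-strain
triplicate design: pooled t-test on log2 abundances, Benjamini–Hochberg
correction, |log2FC| > 1 and p < 0.01 gating, complete
repression/induction by detection pattern, secretion-likelihood filtering,
percentage bookkeeping, and per-operon regulation overlays
(`proteome_de()`, `secretion_filter()`, `overlay_clusters()`,
`plot_volcano()`).

**Synthetic data.** `scenario_config()` presets carry the study's strain
parameters (WT period 410 nm, mutant 365 nm, n_avg 1.38);
`make_goniometry_pair()`, `make_presence_fixtures()` and
`make_abundance_table()` generate all inputs with embedded ground truth.

## Worked example

Simulate a wild-type goniometry pair and invert both maps:

```r
library(photocolony)

cfg  <- scenario_config("WT", seed = 7)
pair <- make_goniometry_pair(cfg)

extract_peaks(pair$scattering) |>
  assign_orders(incidence_deg = 60) |>
  fit_grating_period(incidence_deg = 60, seed = 7)
#> <gonio_fit: grating_period>
#>   period_nm        410  [95% CI 409.9, 410.1]
#>   rms residual:    0.3304 deg on 638 points

extract_peaks(pair$specular) |>
  fit_specular_dispersion(seed = 7)
#> <gonio_fit: specular_dispersion>
#>   n_avg            1.351  [95% CI 1.32, 1.383]
#>   layer_spacing_nm 363.4  [95% CI 353.5, 373.8]
#>   rms residual:    7.096 nm on 11 points
```

The scattering fit recovers the preset 410 nm period to a tenth of a
nanometer from a map with 5% multiplicative noise; its RMS angular
residual (0.33°, dominated by the 1° detector grid) is the lattice
disorder metric. The specular fit recovers the effective index near the
preset 1.38 from eleven Bragg peaks carrying 1% position jitter — the
bootstrap interval shows how shallow the (n, d) valley is at an 11-point,
50° design.

Genomics and proteomics bookkeeping run the same way:

```r
fx <- make_presence_fixtures()
pathway_completeness(fx$sc)
#> # A tibble: 3 × 5
#>   class n_missing n_genomes complete all_absent
#>   <chr>     <int>     <int> <lgl>    <lgl>
#> 1 SC            0        61 TRUE     FALSE
#> 2 SC            1        10 FALSE    FALSE
#> 3 SC            2        16 FALSE    FALSE

summarize_counts(3181, 5471)   # identified / known proteins -> 58.1 (%)
summarize_counts(909, 1504)    # significant / detected      -> 60.4 (%)
```

See the vignette (`vignettes/colony-structural-color.Rmd`) for the model
assumptions, parameter meanings, and numerical choices.

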