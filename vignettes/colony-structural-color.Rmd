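---
title: "Goniometry inversion and omics bookkeeping for bacterial structural color"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goniometry inversion and omics bookkeeping for bacterial structural color}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocolony)
library(dplyr)
```

## The physical model

Colonies of *Flavobacterium* IR1 derive their vivid, angle-dependent color
from structure rather than pigment: rod-shaped cells pack hexagonally into
polycrystalline two-dimensional domains. That periodic organization acts on
light in two complementary ways, and `photocolony` models both.

**Diffraction (scattering geometry).** The in-plane rows of cells form a
surface grating of period $d$. Illuminated at a fixed angle
$\theta_i$, constructive interference of order $m$ appears at

$$\theta_m = \arcsin\!\left(\frac{m\lambda}{d} - \sin\theta_i\right),
\qquad m \in \{0, \pm 1, \pm 2, \dots\}$$

Our sign convention takes incidence positive, so the $m = 0$ (specular)
locus sits at $-\theta_i$ on the detection arm and the first visible
diffraction order at positive angles. Orders whose sine argument leaves
$[-1, 1]$ are evanescent; `grating_angle()` returns `NA` for them rather
than an error, because scanning across a wavelength grid routinely crosses
the propagation boundary.

**Interference (specular geometry).** Vertically, the stacked rows behave
as a multilayer of repeat distance $d$ and volume-averaged effective index
$n_{avg}$. Combining Bragg's and Snell's laws, the specular reflectance
peak for illumination at $\theta_{in}$ (with detection at
$\theta_{out} = \theta_{in}$) is

$$\lambda_B = 2\, n_{avg}\, d \cos\!\left(\arcsin\frac{\sin\theta_{in}}{n_{avg}}\right)$$

which is strictly decreasing in $|\theta_{in}|$ and reduces to
$2d\cos\theta_{in}$ in the vacuum limit $n_{avg} = 1$.

A single symbol $d$ appears in both relations, but the two geometries probe
different spacings. `photonic_model()` therefore carries them separately:
`period_a` enters the grating equation, and `layer_spacing` enters the
Bragg–Snell relation, defaulting to `period_a * sqrt(3) / 2` — the row
stacking distance of a hexagonal packing — while remaining independently
settable, since either convention for the specular spacing is defensible.

The two strain presets in `scenario_config()` encode the study conditions:
the wild type has `period_a = 410` nm and the *moeA* deletion mutant
`period_a = 365` nm, both with $n_{avg} = 1.38$. Shrinking the period
rescales every fixed-angle diffraction wavelength by exactly the period
ratio — a first-order spot at 550 nm (green) moves to
$550 \times 365/410 \approx 490$ nm (blue), which is the mutant's blue
shift.

## Forward simulation

`simulate_scattering_map()` renders the enumerated spots as Gaussian ridges
in angle, of width `max(disorder_sigma_deg, grid step)`, with intensity
decaying in $|m|$ and in the family factor, a constant background, and
seeded multiplicative log-normal noise. `simulate_specular_map()` places a
Gaussian peak in wavelength on the Bragg–Snell curve at each incidence
angle. The intensity model is deliberately simple plumbing: no
electromagnetic solver stands behind it, and nothing downstream fits
intensities — only peak *positions* carry physical meaning, and only they
are inverted.

Two noise channels exist in specular mode because they stress different
things: `noise_sd` perturbs map values (detector noise), which barely moves
the per-angle argmax, while `center_jitter` applies multiplicative
log-normal jitter to the peak center wavelengths themselves
(sample-to-sample positional noise). Parameter-recovery exercises use a 1%
`center_jitter`, the harder condition for the $(n_{avg}, d)$ fit.

`family_factors` can scale `period_a` into additional grating-row
families, reproducing the kind of secondary spot sets seen in measured
maps. Their lattice origin is not asserted; the default is the primary
family only.

Instrument defaults mirror goniometer practice: a 1° detection arm,
scattering incidence 60°, wavelengths 250–800 nm (covering the
near-UV spots of higher orders). The specular preset scans incidence
15–65° in 5° steps over 400–1200 nm: for the preset photonics the
Bragg–Snell peak ranges over roughly 739–963 nm, so a visible-only
wavelength window would truncate the dispersion curve to a narrow
incidence span and make $(n_{avg}, d)$ practically unidentifiable.

```{r forward}
cfg <- scenario_config("WT", seed = 7)
pair <- make_goniometry_pair(cfg)
pair$scattering
```

## Inverse fitting

`extract_peaks()` digitizes ridges deterministically: per-wavelength local
maxima over angle (scattering) or per-incidence maxima over wavelength
(specular), gated at 3 times the map median with a 3-grid-step minimum
separation. An all-flat map raises a typed "no peaks" condition rather
than returning an empty table.

`assign_orders()` labels each peak with the order/family pair whose
predicted angle is nearest, seeded by a period guess from the brightest
off-specular spot under the $|m| = 1$ assumption. Ties break toward
smaller $|m|$, then smaller family factor; peaks with no candidate within
a 5° gate are flagged unassigned. The gate is configurable because its
right width depends on how wrong the initial period may be — second-order
ultraviolet predictions move by tens of degrees under a 10% period error.

`fit_grating_period()` works in sin-space, where the grating equation is
linear in $1/d$:
$\sin\theta_m + \sin\theta_i = (m\lambda)\cdot(1/d)$.
That gives a closed-form least-squares estimate with uniform leverage
across spots, an RMS *angular* residual that doubles as the lattice
disorder metric (`disorder_metric()`), and invariance under duplicating
spots. `fit_specular_dispersion()` is a genuine nonlinear fit
(`minpack.lm::nlsLM`) over $(n_{avg}, d)$, multi-started from
$n_{avg} \in \{1.1, 1.3, 1.5\}$ because the RSS valley is shallow and
curved; it refuses fewer than 3 points or under 20° of incidence span,
where the two parameters are near-collinear.

No analytic uncertainty is available for either fit under the disorder
model, so both report a seeded nonparametric bootstrap over peaks
(200 resamples by default, seed recorded in the result). Fits are plain
objects with `tidy()`, `glance()` and `autoplot()` methods.

```{r inverse}
fit <- extract_peaks(pair$scattering) |>
  assign_orders(incidence_deg = 60) |>
  fit_grating_period(incidence_deg = 60, seed = 7)
tidy(fit)
glance(fit)
```

## Pathway presence/absence and operon clustering

The comparative-genomics side summarizes presence/absence of the eight
MoCo (molybdenum cofactor) synthesis genes — *moeA*, *mobA*, *sumT*,
*moaD*, *moeZ*, *moaE*, *moaC2*, *moaA* — across genomes labeled by
structural-color class. `gene_prevalence()` prints integer percentages
(half away from zero, matching printed-table convention);
`pathway_completeness()` histograms genomes by the number of genes
missing. Percentages and completeness are deliberately separate summaries
of the same matrix: published marginal prevalences and completeness counts
for real genome panels need not be jointly satisfiable by any single
matrix, and the fixtures here target each summary on its own terms.

`cluster_loci()` groups genes into putative operons purely by proximity:
consecutive loci on one contig join a cluster while the intervening gap
(`next start − previous end − 1`, with a running maximum end so
overlapping genes merge) stays within 5 kb; a contig change always splits.
Strand is carried but ignored — co-orientation is not required for the
proximity rule. Coordinates are 1-based inclusive (GFF3 convention)
throughout.

```{r genomics}
fx <- make_presence_fixtures()
pathway_completeness(fx$sc)
```

The fixture's gene-loss pattern is fixed and documented: the single-gene
losses are assigned to *moaD* and the double losses to {*mobA*, *moaD*},
the two genes observed below full prevalence in structural-color strains.
The choice of *which* genes are lost is a fixture convention, not a
reconstruction.

## Differential proteomics

`proteome_de()` implements thresholded differential-abundance calling for
a two-strain, triplicate design. Per protein: a pooled-variance two-sided
Student's t-test on log2 abundances (`two_group_test()`, with an epsilon
variance floor so two unequal constant groups give a vanishing p-value
instead of 0/0), Benjamini–Hochberg correction across testable proteins
(`bh_adjust()`), and a fold change computed from linear-scale group means.
A protein is *down* when $p < 0.01$ and $\log_2(\mathrm{FC}) < -1$, *up*
symmetrically. Detection patterns override the quantitative rule: a
protein detected only in the reference strain is completely repressed,
only in the mutant completely induced — no fold change exists for these.

Missingness is resolved conservatively: `NA` means *not detected*
(distinct from zero); a protein absent from all replicates of exactly one
group is a complete pattern; otherwise at least two detected replicates
per group are required, else the protein is `untestable` and excluded from
the multiplicity correction. The significance gate defaults to the raw
p-value, with the BH q-value reported alongside and a `gate = "q"` switch
for FDR-gated calling. Testing on log2 abundances with a pooled t is the
default because triplicate group variances are too poorly estimated for
Welch to help.

`secretion_filter()` intersects calls with per-protein SignalP-style and
SecretomeP-style flags (signal peptide, non-classical secretion), keeping
the union and reporting both sub-counts. `summarize_counts()` does
one-decimal percentage bookkeeping. `overlay_clusters()` joins calls onto
proximity clusters and reports each putative operon's dominant regulation
direction (complete patterns count toward their direction; ties are
`mixed`).

```{r proteomics}
ab <- make_abundance_table(scenario_config("WT", seed = 42, n_proteins = 300))
calls <- proteome_de(ab$abundance)
count(calls, call)
```

## What the synthetic data do and do not show

`scenario_config()` plus the three generators produce every input the
pipeline consumes, with truth recorded in metadata, so all stages are
testable end to end without any external download. Defaults: 5%
multiplicative noise on scattering maps, 1% specular peak-position jitter,
log-normal replicate noise of $\sigma = 0.25$ (natural log) around
log-normal protein baselines, a 10% planted-effect fraction at
$\pm 2$ log2 units, and 3 replicates per group.

The generators emulate the *structure* of real acquisitions, not their
physics or chemistry: Gaussian ridges instead of real speckle and domain
statistics, no absorption or pigment background, no correlated
peptide-level missingness, no shared-peptide protein inference. Passing
recovery tests therefore demonstrates that the inversion and calling
machinery is correct and calibrated under the stated noise models — not
that those noise models exhaust real colonies or real LC-MS/MS runs.

## Numerical choices and test scales

- Peak threshold 3 × map median; minimum separation 3 grid steps.
- Assignment gate 5°; ties toward smaller $|m|$, then smaller family.
- Specular fit: multi-start `nlsLM`, bounds $n_{avg} \ge 1$, $d \ge 1$ nm;
  span guard 20°.
- Bootstrap 200 resamples by default; tests use 10–50 for speed.
- Rounding is half-away-from-zero at the printed precision (integer
  percent for prevalence tables, one decimal for proteome percentages).
- Recovery sweeps in the test suite run periods {300–500 nm} × 3 seeds and
  $n_{avg}$ {1.30, 1.38, 1.45} × 3 seeds, and calibration checks use 10
  null tables of 300 proteins plus one 1000-protein recovery table —
  sizes chosen to exercise the estimators well past their asymptotic
  wobble while keeping the default suite fast to run.

## Known limitations

Azimuthal averaging over polycrystalline domains is collapsed to a 1-D
grating in the detection plane; intensities are cosmetic; no polarization,
absorption, or 3-D colony curvature. The specular and grating spacings are
tied by the hexagonal default unless overridden, and the disorder metric
has no external calibration target — it is a relative, not absolute,
measure of lattice quality.
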