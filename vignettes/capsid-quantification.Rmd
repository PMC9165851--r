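---
title: "Quantifying full and empty rAAV capsids from cryoTEM micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying full and empty rAAV capsids from cryoTEM micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidquant)
```

## The measurement problem

Recombinant adeno-associated virus (rAAV) preparations are mixtures of
capsids that carry the therapeutic genome ("full") and capsids that do not
("empty"). The fraction of full particles is a critical quality attribute of
a gene-therapy drug: biopotency per capsid rises with it, and empty capsids
are generally treated as a process-related impurity. CryoTEM images the
preparation in a near-native vitrified state, so the interior density of
every particle is visible directly: a genome-containing capsid is
electron-denser and appears as a uniformly dark disk, while an empty capsid
shows a dark shell ring around a bright lumen. `capsidquant` turns this
contrast into a quantitative, automated estimate of the percentage of full
particles, together with the validation statistics used to qualify such an
assay (repeatability, spiking-series linearity, comparison with the
orthogonal vg/cp titre ratio, and biopotency correlation).

## The model

An idealised capsid is a spherical protein shell of outer radius $R_o$
(default 12.5 nm) and thickness $t$ (default 2.5 nm), with inner radius
$R_i = R_o - t$. In a bright-field projection the image contrast is
proportional to the mass-thickness integrated along the beam. At radial
distance $r$ from the particle centre:

$$ T_\mathrm{empty}(r) = 2\left(\sqrt{R_o^2 - r^2} - \sqrt{R_i^2 -
r^2}\right), \qquad T_\mathrm{full}(r) = T_\mathrm{empty}(r) + \rho \cdot
2\sqrt{R_i^2 - r^2}, $$

with each square root taken as zero where its argument is negative, and
$\rho$ the packaged genome's density relative to shell protein (default
0.8). Two facts drive the whole classifier: $T_\mathrm{full}$ is maximal at
$r = 0$ (darkest at the centre), and $T_\mathrm{empty}$ is maximal at
$r = R_i$ (darkest on a ring at the inner wall). `projected_thickness()`
exposes this model and is the analytic oracle for the simulator tests.

## Pipeline

1. **Detection** (`detect_particles()`). Candidate capsids are found by
   circular Hough accumulation on the gradient of the image, over the radii
   spanned by a physical size window — 18–28 nm diameter for cryoTEM, 25–35
   nm for negative-stain images, where stain enlarges the apparent particle.
   The accumulator uses the *signed radial component* of the gradient:
   capsid rims (dark inside, bright outside) produce gradients pointing
   outward, so a circle centred on a particle collects positive support
   while circles merely osculating a rim from outside collect negative
   support. This orientation-aware form is what makes the detector precise
   at moderate signal-to-noise without any tuned suppression radius. Scores
   are expressed relative to the image's median gradient, making the
   threshold (default 2.0) dimensionless and transferable across contrast
   and dose settings. Local maxima above threshold are greedily
   non-maximum-suppressed (centre distance below $0.8 (r_i + r_j)$; ties
   broken by score, then lower y, then lower x, for determinism), and picks
   closer than $1.2 r$ to the border are discarded because their radial
   profile would be truncated. Candidates whose response is still rising at
   the edge of the radius window (checked with probe radii one step outside
   it) are rejected as objects of the wrong size.

2. **Profiling** (`radial_profile()`). Each particle's centre is refined by
   an iterated centroid of darkness mass (`refine_centre()`; at most 5
   iterations, 0.1 px tolerance, movement capped at half the pick radius).
   The radial density profile (RDP) is the mean intensity in B = 32
   equal-width annuli over $[0, 1.2r]$, normalised against the local
   background annulus $[1.3r, 1.6r]$: subtract its centre, divide by its
   spread. Normalising the radial axis by each particle's own radius makes
   profiles of different-sized capsids commensurate, and the background
   normalisation removes per-image offsets from ice thickness and
   illumination so particles from different micrographs cluster together.

3. **Classification** (`fit_pca()`, `cluster_and_label()`). A mean-centred
   PCA is fitted to the RDP matrix and each particle projected onto the
   first two components; full and empty populations form two clusters in
   this plane. A two-component Gaussian mixture with full covariances is
   fitted to the scores, and labels are anchored physically rather than by
   cluster index: the cluster with the lower mean central-bin intensity
   (darker centres) is "full". Particles whose mixture posterior falls
   below 0.99 are labelled "uncertain" and set aside. A dataset-level
   diagnostic reports whether the two clusters' 99% confidence ellipses
   (chi-square quantile, 2 d.f.) are disjoint — the quantitative reading of
   "unambiguous binary discrimination". `manual_assign()` retains the
   operator action of relabelling selected particles, with provenance.

4. **Quantification** (`percent_full()`). The headline statistic is
   $100 \cdot n_\mathrm{full} / (n_\mathrm{full} + n_\mathrm{empty})$ with a
   Wilson 95% interval on the full fraction. Uncertain and
   curation-excluded particles are reported but excluded from the
   denominator by default. A dataset must contain at least 3 micrographs
   and 1500 curated particles (`enforce_minimum_count()`); the
   `sample_size_study()` Monte-Carlo shows why 1500: the binomial sampling
   sd of the estimate at $p = 0.5$ is then
   $100\sqrt{0.25/1500} \approx 1.29$ percentage points, and halves only
   when the count quadruples.

## The synthetic-data generator

No public micrographs exist for this assay, so `simulate_micrograph()`
generates images with exact ground truth. Particles are placed by dart
throwing with a minimum separation, classes drawn i.i.d. Bernoulli($p$)
(a fixed-count mode exists for deterministic tests), and the analytic
projected thickness rasterised by 4×4 super-sampling per pixel — which is
what keeps `projected_thickness()` valid as an independent oracle for the
rendered images. Intensities follow the bright-field convention
(background minus contrast × thickness; particles darker), with optional
Gaussian blur standing in for defocus and additive Gaussian noise (Poisson
shot noise behind a flag; the classifier operates on annulus means, which
are insensitive to the noise family at these signal levels). The stated
signal-to-noise ratio is the peak depth of a full particle divided by the
pixel noise sd (`noise_sd_for_snr()`).

What the generator deliberately does **not** emulate: the contrast transfer
function (a Gaussian blur is not a CTF), ice-thickness gradients,
aggregates and broken capsids, partially filled capsids, and the
stain-pooling physics of negative staining. Passing benchmarks on these
images therefore demonstrates the correctness and statistical behaviour of
the algorithms under controlled conditions — not performance on real
micrographs, which additionally depends on curation of debris and imaging
artefacts.

## Numerical choices

* **Annulus binning.** Profile annuli are binned at width
  $\max(0.9\ \mathrm{px}, 1.2r/B)$; any annulus at least 0.9 px wide
  contains a pixel centre, so native annuli are never empty, and when the
  target width is at least that the native grid *is* the target grid (no
  resampling). Coarser particles fall back to wider native annuli linearly
  resampled to B bins.
* **Robust background.** The background annulus can graze a neighbouring
  particle at the minimum separation, so its centre/spread are estimated by
  median and MAD rather than mean and sd.
* **Noiseless degeneracy.** A noiseless synthetic image has exactly
  constant background, so the background MAD is zero; the normalisation
  then falls back to a unit divisor and flags the profile
  (`bg_sd_degenerate`), keeping values finite and the analytic comparison
  meaningful.
* **PCA sign convention.** Each component's sign is fixed so its loading at
  the central bin is non-positive, making scores reproducible across runs
  and platforms.
* **Mixture initialisation.** The Gaussian mixture is fitted with
  model-based agglomerative initialisation (mclust), which is deterministic
  by construction — no EM restart seed is needed, and the recorded seed in
  reports covers only the simulation stages.
* **Degenerate mixtures.** Single-population samples (e.g. a
  reference-empty preparation) make a two-component fit meaningless: when
  one component empties, the fit fails, or the components do not differ in
  central intensity by at least 2 pooled sds, all particles are assigned
  one class chosen from the physics — the pooled profile's central bins
  darker than its inner-wall ring means full, otherwise empty — with a
  warning and a FALSE separation flag.
* **Ellipse disjointness.** Tested by 720-point boundary sampling plus
  centre-containment checks; an independent brute-force grid oracle backs
  this in the tests.
* **Rounding.** Reported percentages round half away from zero (as printed
  release tables do), in integer or one-decimal mode.

## Design decisions on open points

* The published workflow labels clusters manually on a scatter plot; this
  package automates the decision by central density, which reproduces the
  same physical rule without operator subjectivity, and keeps the manual
  override for parity.
* "Uncertain" has no published per-particle rule; here it is a mixture
  posterior below 0.99. The "99% confidence" non-overlap language is read
  as a dataset-level cluster-separation diagnostic (disjoint 99% ellipses),
  not a per-particle criterion, and is flagged as a design choice.
* Uncertain particles are excluded from the percent-full denominator by
  default (they are rare when the clusters separate; a config switch
  includes them).
* The spiking-series theoretical values follow the particle-weighted blend
  $\%F = 100\,(f C_f F_f + (1-f) C_e F_e) / (100\,(f C_f + (1-f) C_e))$,
  which reduces to the linear blend at equal concentrations; published
  theoretical values are treated as inputs of the linearity analysis, not
  as reproduction targets, because the exact predilution concentrations
  behind them are not public.
* The published detector settings are not public either; this package
  exposes the algorithmic family's knobs (smoothing sigma, threshold, NMS
  overlap, eccentricity cap) as configuration with defaults tuned on the
  simulator.

## Benchmark problem sizes

The validation benchmarks simulate at 1 nm/px on 1024×1024 frames (512×512
for the detection precision/recall bench), with 300–500 particles per frame
and 1500 particles per sample — the counting rule's floor — at
signal-to-noise 5. Physics checks (profile-vs-oracle agreement, ring
positions) use 0.5 nm/px where rasterisation detail matters. The
simulator's own defaults (2048×2048 at 0.5 nm/px) mirror a typical 2k CCD
acquisition; the benchmark sizes are chosen to keep a full validation run
in minutes on a laptop while leaving every statistical conclusion
unchanged — estimates at these sizes are dominated by binomial sampling
error, not by image scale.

## Known limitations

* Binary classification only: partially filled capsids, when present, land
  in "uncertain" or on the wrong side of the boundary; the method does not
  resolve them.
* Broken particles, doublets and debris are a curation responsibility
  (status/label edits on the pick table), not an automated detector.
* The negative-stain modality is supported only as a wider size window; the
  stain's contrast inversion physics is out of scope, and the vg/cp and
  biopotency benches operate on assay tables, not images.
* The simulator's noise and blur are idealised; detector thresholds that
  are comfortable at simulated SNR 5 may need adjustment on real data with
  structured backgrounds.
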