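---
title: "Quantifying NETosis from high-content images: models and methods"
author: "netquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NETosis from high-content images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay

Neutrophils can die by NETosis: the nuclear envelope breaks down, chromatin
decondenses until it fills the whole cytoplasm and is finally extruded as a
neutrophil extracellular trap (NET). In a high-content screening version of
this assay, neutrophils are plated in 96-well plates, stimulated with PMA
(100 nM, ~210 min endpoint) or the calcium ionophore ionomycin (5 uM,
~90 min), stained with a Hoechst-like DNA dye, imaged, and every nucleus is
classified as *resting* (lobulated, bright), *NETotic* (grossly enlarged,
dim, diffuse) or *apoptotic* (condensed, smaller but markedly brighter).
The primary readout is the per-well percentage of NETotic cells; around it
sit the usual screening statistics: Z' plate quality control, hit calling
against a percent-NETotic threshold, four-parameter logistic (4PL) EC50
fits for dose series, and kinetic summaries of cytosolic-ROS (DCF) and
mitochondrial-potential (TMRM) channels.

`netquant` implements that pipeline end to end, together with a seeded
synthetic-plate generator that produces images plus per-cell ground truth,
so the whole chain is testable without access to donor material.

## The synthetic plate generator

### Nuclear phenotypes

Each nucleus is rendered as a sum of anisotropic Gaussian blobs
(`render_nucleus()`); the ground-truth chromatin mask is the set of pixels
above 15% of the rendered peak. The presets
(`phenotype_presets()`) encode the assay's phenomenology at 0.6 um/pixel:

* **resting** — 3-5 partially overlapping lobes, total area ~42 +/- 6 um^2
  (a neutrophil nucleus is ~30-50 um^2), peak intensity 3000 camera units;
* **NETotic** — one large diffuse core with 4-8 curvilinear filament
  strokes at the margin; area is drawn at `chromatin_spread` (3.8) times
  the resting mean with a hard floor of twice the resting mean, because
  the lytic endpoint is *defined* by chromatin spreading well beyond the
  original nuclear outline; peak intensity 1100 (decondensed chromatin
  stains dimmer per pixel);
* **apoptotic** — a single compact blob of ~24 um^2 with peak 6500
  (condensed chromatin is brighter and smaller).

Fields (`simulate_field()`) place nuclei with rejection of excessive
overlap — candidate positions are rejected while the *low 5% isophote*
("dim skirt") of the new nucleus overlaps already-placed skirts, because it
is skirt contact, not mask contact, that fuses thresholded objects — then
add a constant background offset (200), Poisson shot noise and Gaussian
read noise (sd 30), and quantize to 16 bit. The default geometry, 4 fields
of 1024 x 1024 pixels with 500 cells each, follows the assay's plating
density: 40,000 cells distributed over a ~32 mm^2 well is ~470 cells per
0.38 mm^2 field; 500 is used and gives ~2,000 analyzed cells per well.

### The response law

The true NETotic fraction of a well is

```
f(well) = baseline + (induced(t) - baseline) * (1 - inhibition(c))
```

with `baseline = 0.01` (spontaneous NETosis stays below 1-2% in vehicle
wells). `induced(t)` is a Hill curve in time per stimulus, calibrated to
two anchors each: PMA (t50 = 64 min, h = 3) reaches 0.70 at its 210-min
endpoint with a slow sigmoidal onset; ionomycin (t50 = 15 min, h = 2)
reaches 0.70 at 90 min while already exceeding 0.60 at 45 min. For
ionomycin a steeper exponent cannot satisfy both anchors simultaneously,
which is why its exponent differs from PMA's. `inhibition(c)` is a Hill
curve in compound concentration; the built-in "capsaicin-like" reference
inhibitor has EC50 1.5 uM, Hill 2 and complete maximal inhibition, so a
5 uM dose inhibits ~92% — consistent with full suppression at the
screening concentration.

Inter-well variability is a Beta-distributed jitter of the true fraction
with concentration 1500 (sd ~1.2 percentage points at f = 0.7, ~0.25 at
f = 0.01). This matches the very tight control wells implied by a Z' near
0.9; the jitter is a named parameter, not a constant. A constant 2%
apoptotic fraction is mixed into every well. Donor-level random effects
are not simulated by default.

### Kinetic channels

ROS (DCF) fold-change follows `1 + (A - 1)(1 - exp(-t/tau))`; the PMA
preset uses A = 6, tau = 20 min, so the signal plateaus at 6-fold with
95% of the plateau reached at `-tau ln 0.05` = 59.9 min (~1 h). Vehicle
and ionomycin presets stay near 1 (calcium-ionophore NETosis is
NADPH-oxidase independent). TMRM accumulation is
`1 + d * M (1 - exp(-t/tau))` with d = 1 for polarized mitochondria and
d = 0.2 for uncoupled ones (CCCP, ionomycin, alexidine presets), M = 5,
tau = 25 min over a 60-min window. Noise is additive Gaussian per
timepoint (default sd 0.05 fold).

### What the simulator does *not* emulate

No optical point-spread function, no uneven illumination or vignetting, no
out-of-focus fields, no autofluorescence, no cell debris or doublets of
mixed phenotype, no donor effects by default, and the MPO-like secondary
channel is simply intensity proportional to the NETotic label plus noise.
Tests that pass on simulated plates therefore demonstrate that the
*algorithmic chain* is correct and well calibrated — not that the
classifier generalizes to any particular microscope; on real data the
classifier must be retrained on curated examples.

## Segmentation

`segment_nuclei()` runs: Gaussian smoothing (sd 1.5 px) → top-hat
background subtraction (grayscale opening, disc radius 15 um) → global
Otsu threshold on the background-subtracted image, with an absolute floor
of 100 camera units so empty fields yield no objects → hole filling →
connected components → per-object boundary refinement → selective
watershed splitting → area filter (15-500 um^2) → border-object removal.

Two steps deserve explanation:

* **Per-object boundary refinement.** A single global threshold cannot
  trace both a bright condensed nucleus and a NETotic region whose
  chromatin is ~3-fold dimmer: whichever class dominates the field drags
  the Otsu threshold toward itself, and the minority class is clipped or
  bloated — the measured object areas then depend on the *composition* of
  the well, which would leak treatment information into the features. The
  refinement step therefore grows every Otsu seed out to a fixed fraction
  (15%) of its own background-subtracted peak, assigning contested support
  pixels to seeds by intensity-guided propagation, and measures the
  boundary on a lightly smoothed image (heavy smoothing deflates peaks and
  pushes a relative isophote outward). After this step object extent is
  composition-independent, and detection precision/recall on simulated
  fields is ~1.0/0.98-0.99 with per-object Jaccard ~0.8-0.9.
* **Selective watershed splitting.** Touching compact nuclei must be
  split, but a lysed, spread NETotic region must stay one object.
  Candidates for splitting are objects with solidity above 0.75 and area
  below 90 um^2: measured on the generator, fused pairs of round nuclei
  have solidity ~0.80 (single nuclei ~0.95, diffuse NETotic regions are
  larger and stringier), so a higher solidity floor would exempt exactly
  the objects the step exists for. Lobed single nuclei are protected by
  the watershed depth tolerance (2 px): their internal distance-transform
  saddles are shallow.

`match_to_truth()` matches predictions to ground truth greedily by
descending pixel overlap, one-to-one, requiring Jaccard >= 0.3 for a
valid match; unmatched predictions are false positives.

## The feature set

`extract_features()` computes, per object, on the nuclear channel:

* **Morphology** — area (um^2), perimeter (weighted border-configuration
  estimator, calibrated for smooth contours: digital disks give form
  factor ~1.00, axis-aligned rectangles come out ~10-15% short), form
  factor `4*pi*A/P^2` capped at 1.1, solidity (pixels / convex-hull area
  with a half-perimeter lattice correction), equivalent diameter, and
  lobe count (local maxima of the smoothed in-object distance transform,
  minimum separation 3 px).
* **Intensity / density** — mean, population sd, max and total of the
  in-object intensities in native camera units; density = total
  intensity per um^2. ("Density" is implemented as total/area; other
  definitions exist, and this one is flagged as an assumption.)
* **Haralick (GLCM)** — intensities inside the object are min-max
  quantized to 32 gray bins (a constant object maps to bin 0 by
  convention: contrast 0, energy 1, entropy 0 — degenerate objects must
  not crash a screen), co-occurrences are counted symmetrically at the
  four distance-1 offsets, each offset matrix is normalized to sum 1, and
  contrast, correlation (0 when a marginal sd is 0), energy, homogeneity
  and entropy (natural log, 0 ln 0 = 0) are averaged over offsets.
  Min-max quantization makes these features exactly invariant to affine
  intensity rescaling.
* **Gabor bank** — 2 frequencies (0.15, 0.30 cycles/px) x 4 orientations,
  complex kernels with an envelope-weighted DC correction so constant
  images give zero magnitude; per object the mean and population sd of
  the response magnitude. Filter responses are evaluated only at object
  pixels (in C), which keeps screening runs fast on sparse fields.
* **Spots / edges / ridges** — at scales sigma = 1 and 2 px: *spot* is
  the mean positive part of the scale-normalized Hessian determinant
  (x4; equal to the squared scale-normalized Laplacian on an isotropic
  blob and zero on a straight ridge — the raw squared Laplacian would
  tie with the ridge measure on lines, which defeats the purpose of
  separating the two), *edge* the mean squared scale-normalized gradient
  magnitude, *ridge* the mean squared difference of Hessian eigenvalue
  magnitudes. Each is divided by the squared mean object intensity for
  illumination invariance. The derivative kernels are sampled Gaussian
  derivatives with their sums corrected to exactly zero, so all three
  measures vanish identically on constant images.

A field of ~500 cells takes ~2-3 s on one CPU for the full vector.

## Phenotype classification and the lytic gate

The default classifier (`train_classifier(kind = "rlda")`) is a linear
discriminant on standardized features with the pooled covariance shrunk
toward a scaled identity (`lambda` = 0.1) — linear, fast, well suited to
three well-separated classes and to serialization as plain coefficient
blocks in JSON; a multinomial-logistic alternative is provided for
comparison. Cross-validation is stratified 5-fold with a seeded fold
assignment recorded in the model.

Training labels come from the simulator's ground truth (`make_training_set()`)
— the documented stand-in for the human-curated training set a real screen
would use. Training fields use the *screening* density and alternate
balanced and resting-heavy compositions, because crowding measurably
shifts texture features (a neighbour's dim skirt adds intensity gradients
across an object); a classifier trained on isolated nuclei is
miscalibrated on real fields.

The **lytic gate** enforces the rule that only lytic NET formation counts:
a cell whose discriminant argmax is NETotic must also be large
(area >= the 5th percentile of NETotic training areas) and texturally
homogeneous (Haralick contrast <= the 95th percentile of the NETotic
training class); otherwise it is relabeled to its runner-up class and
flagged `net_like_nonlytic`. Two consequences follow from this percentile
construction and are worth stating plainly:

* by design the gate trims roughly 10% of *true* NETotic cells (the
  marginal 5% of each bound), so flagged cells are treated as
  *indeterminate* and excluded from the well denominator by default
  (`summarize_wells(exclude_gated = TRUE)`); counting them as their
  runner-up class would bias percent NETotic downward by ~g·f(1-f) with
  g ~ 0.1;
* even with the exclusion, a small negative bias (up to ~2-3 percentage
  points at intermediate fractions) remains; the recovery tests budget
  for it. On simulated wells the residual error of percent NETotic
  against the generator's truth is within 3 percentage points across
  f = 0.01 ... 0.7 at ~2,000-3,000 cells per well.

On held-out simulated fields, detection precision/recall are >= 0.95,
classification accuracy over analyzed cells is ~0.99, and
NETotic/apoptotic confusion is ~0 — size and intensity alone separate
those two classes widely in the generator's conditions.

## Screen analytics

* **Z'** — `1 - 3(sd_p + sd_n)/|mu_p - mu_n|` with sample (n-1) standard
  deviations (the window statistic's reference does not fix the
  convention; n-1 is used and documented). Equal means are reported as a
  failure, not a number.
* **Hit calling** — replicate wells are averaged (arithmetic mean), then a
  compound is *active* when percent NETotic is strictly below 50 and
  *strong* below 10. The 50 encodes "a 30% reduction of a ~70% induction
  rate"; both thresholds are arguments, not constants.
* **4PL dose-response** — `R(c) = bottom + (top - bottom)/(1 + (c/ec50)^h)`
  fitted by Levenberg-Marquardt from a 3 x 3 grid of starts (EC50 at the
  dose quartiles, Hill in {0.7, 2, 4}), parameterized in log EC50 with
  Hill bounded to [0.05, 20]. Zero doses anchor the top plateau exactly.
  Flat responses are flagged degenerate (no EC50); an EC50 outside the
  tested range x [0.1, 10] is flagged extrapolated. On exact model data
  all starts converge to the generating parameters within 1e-6.
* **Kinetic summaries** — the plateau comes from an exponential-approach
  fit with fallback to the mean of the last three points; steady state is
  operationalized as the first timepoint at 95% of the plateau ("~1 h" is
  not a formula; 95% is, and gives 59.9 min for tau = 20). With a
  baseline trace, summaries are computed on the pointwise ratio, so
  `peak_fold` is the maximal stimulated/unstimulated ratio.
* **Group comparisons** — one-way ANOVA, then Dunnett comparisons of each
  group against the control with critical values from a seeded Monte
  Carlo of the null maximum |t| (shared control, pooled variance; 1e5
  draws by default, reproducible and table-free). With a single
  comparison the critical value agrees with the two-sample t quantile to
  Monte-Carlo error; the family-wise error at nominal 0.05 measures
  ~0.05-0.06 over 2,000 null datasets. Kolmogorov-Smirnov normality
  checks are reported per group as warnings, never as gates.

## Numerical and design notes

* Pixel coordinates are 0-based (row, column), origin top-left; images are
  read and written without rescaling (8/16-bit grayscale TIFF).
* All randomness flows through explicit seeds; per-well child seeds are
  derived with a fixed 32-bit-safe linear rule, so a plate is bit-identical
  given (layout, config, seed).
* Problem sizes in the tests — 2,000-3,000 cells per well, 10 + 10 control
  wells for the Z' check, 24 + 24 in the acceptance script, 2,000
  Monte-Carlo datasets for the error-rate check — were chosen as the
  smallest sizes at which the quantities of interest are stable to well
  under their tolerance; the statistics scale to full plates unchanged.
* Known limitations: the perimeter estimator is biased on axis-aligned
  polygons (documented above); lobe counts on objects touching another
  object share one distance transform and can be off by one; the gate
  bias analysis above is specific to the generator (on real data the
  flagged population genuinely contains non-lytic NET-like cells, which
  is what the gate is for); and the classifier is linear by design —
  phenotypes requiring nonlinear boundaries would need the logistic or an
  external model.
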