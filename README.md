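# netquant

High-content image analysis of NETosis — the lytic form of neutrophil
death in which the nucleus loses its lobulated shape and decondensed
chromatin spreads through the whole cytoplasm before being extruded as a
neutrophil extracellular trap (NET).

The package is aimed at people building or validating screening assays of
NET formation: it implements the full analysis chain of a plate-based
assay (nuclear-stain segmentation → multiparametric per-cell features →
three-class phenotype calling → per-well percent NETotic → screening
statistics), together with a seeded synthetic-plate simulator that
produces images *with per-cell ground truth*, so every stage can be tested
quantitatively without donor material.

## What it computes

Per segmented nucleus, a multiparametric feature vector: morphology (area,
perimeter, form factor 4πA/P², solidity, lobe count), intensity and
density, Haralick features from the normalized gray-level co-occurrence
matrix (contrast Σp(i−j)², correlation, energy Σp², homogeneity
Σp/(1+(i−j)²), entropy −Σp ln p), a Gabor filter bank (2 frequencies × 4
orientations, response-magnitude mean/sd), and spots/edges/ridges energies
from scale-normalized Gaussian derivatives.

A regularized linear discriminant on the standardized features assigns
each cell to resting / NETotic / apoptotic; a **lytic gate** (minimum
area, maximum texture heterogeneity, derived from the NETotic training
class) enforces that only lytic NET formation counts as NETotic.
Well summaries feed:

* **Z′ = 1 − 3(σ₊+σ₋)/|μ₊−μ₋|** — plate quality control from control wells;
* **hit calling** — active below 50% NETotic (a 30% reduction of a ~70%
  induction), strong below 10%;
* **4PL dose-response** R(c) = bottom + (top−bottom)/(1+(c/EC50)^h) with
  multi-start Levenberg-Marquardt;
* **kinetic summaries** of ROS (DCF) and TMRM traces — plateau, peak fold
  change, time to 95% of plateau;
* **one-way ANOVA + Dunnett** comparisons against a control group, with
  Monte-Carlo critical values.

## Worked example

Train the default classifier on simulator ground truth, run a small
simulated control plate end to end, and compute the screening statistics:

```r
library(netquant)
model <- train_default_classifier(n_per_class = 200, seed = 1)
print(model)
#> <net_classifier> rlda, 38 features, classes: apoptotic, netotic, resting
#>   5-fold CV accuracy: 1.000
#>   lytic gate: area >= 132.7 um2, Haralick contrast <= 17.02

lay <- control_layout(n_neg = 3, n_pos = 3, stimulus = "ionomycin")
res <- run_screen(lay, model, n_fields = 2L, cells_per_field = 400L, seed = 1)
res[, c("well_id", "role", "n_cells", "pct_netotic", "f_true")]
#>   well_id             role n_cells pct_netotic     f_true
#> 1     A01 negative_control     794   0.8816121 0.01082336
#> 2     A02 negative_control     792   1.1363636 0.01260033
#> 3     A03 negative_control     796   0.7537688 0.01143590
#> 4     A04 positive_control     679  63.3284242 0.69664968
#> 5     A05 positive_control     660  62.4242424 0.69279658
#> 6     A06 positive_control     682  65.5425220 0.68974151

zprime(res$pct_netotic[res$role == "positive_control"],
       res$pct_netotic[res$role == "negative_control"])
#> <zprime_result> Z' = 0.9141 (pos 63.77 +/- 1.60, neg 0.92 +/- 0.19)
```

Reading the output: vehicle wells sit at ~1% spontaneous NETosis while
ionomycin drives ~63-66% of cells into the lytic phenotype against a true
simulated fraction of ~69% (the percentile-based lytic gate deliberately
excludes borderline cells, which costs a couple of percentage points —
see the methods vignette); the control arms are tight enough for an
excellent screening window (Z′ ≈ 0.91). Kinetics work the same way:

```r
pma <- simulate_ros_trace("pma", seed = 2)      # DCF fold-change trace
veh <- simulate_ros_trace("vehicle", seed = 3)
summarize_kinetics(pma, baseline = veh)
#> <kinetic_summary> peak fold 6.32, plateau 5.92, t_steady 40 min
```

i.e. a ~6-fold peak of cytosolic ROS relative to unstimulated cells, with
the stimulated/unstimulated ratio settling within the first hour.

A thin command-line front end over the same functions is installed at
`inst/cli/netquant.R` (subcommands `simulate`, `segment`, `features`,
`train`, `classify`, `summarize`, `screen`, `fit-dr`, `kinetics`,
`stats`).

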