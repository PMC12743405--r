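# spermtopo

Chromosome topology analysis in human sperm nuclei: an R package for
quantifying where centromeres sit inside the sperm head, from multi-channel
FISH/IF microscopy images or per-signal coordinate tables.

Sperm chromatin is not a bag of DNA — chromosomes occupy reproducible
territories, and their centromeres cluster into chromocenters whose position
shifts between unfractionated ejaculate ("raw") and the good-quality
fractions produced by swim-up (SU) or density-gradient centrifugation (DGC)
selection. spermtopo implements the standard 2D coordinate model for
measuring this, a statistics layer for comparing it across fractions and
epigenetic strata, and a seeded simulator so the whole chain is testable
without any microscope.

## The model

Each nucleus is an ellipse with longitudinal axis `L` (basal tail-attachment
point → apex) and short axis `l`. A FISH signal centroid is expressed as:

* **Linear zone** — its axial fraction `t` in thirds: `b` (basal, t < 1/3),
  `m` (middle), `a` (apical, t ≥ 2/3); populations are summarized as a/m/b
  frequency tables.
* **Radial position** — `(D/L, H/L)`, where `D` is the distance to the
  basal point (Euclidean or axial-projection convention, configurable) and
  `H` the unsigned perpendicular distance to the axis (mirror-folded;
  maximum ≈ 0.3 at the membrane). Group means ± SE place each chromosome as
  a point in the nuclear plane.
* **Chromocenters** — Ward clustering (Euclidean linkage) of the
  per-chromosome mean points, exported as Newick trees, plus convex-hull
  areas of the chromocenter region.
* **Distances** — per-cell inter-centromere distances (µm) for pairs 4–8,
  7–9, 18–X, 18–Y, with fold changes between fractions.
* **Epimarks** — per-cell 5mC/5hmC immunofluorescence intensities classify
  cells as hyper- (both positive) or hypomethylated (both negative);
  topology is additionally stratified by this state. Chromatin-integrity
  labels (aniline blue, acridine orange, TUNEL) are tabulated as class
  frequencies.
* **Tests** — Shapiro–Wilk-gated Mann–Whitney / Welch t for two groups,
  Kruskal–Wallis + Dunn (Bonferroni) across fractions, α = 0.05; significant
  shifts become directional repositioning calls (basal–apical,
  center–periphery, both, none).

## Worked example

```r
library(spermtopo)

cfg <- preset_from_tables(n_cases = 5, cells_per_case = 200, seed = 11)
res <- run_all(cfg, out_dir = "demo_out")

subset(res$topology, epistate == "all" & fraction == "raw" &
                     !chromosome %in% c("18-X", "18-Y"))
```

```
 chromosome n_signals mean_d    se_d mean_h    se_h a_pct m_pct b_pct
          4      1000  0.463 0.00381  0.164 0.00148   4.9  80.7 14.40
          7      1000  0.556 0.00377  0.148 0.00159  18.6  78.4  3.00
          8      1000  0.473 0.00386  0.149 0.00158   5.9  80.9 13.20
          9      1000  0.550 0.00381  0.140 0.00147  17.0  80.0  3.00
         18      1000  0.533 0.00377  0.151 0.00154  13.4  82.0  4.60
          X       503  0.586 0.00545  0.127 0.00212  23.1  74.3  2.59
          Y       497  0.573 0.00522  0.134 0.00213  20.9  77.3  1.82
```

Read: in simulated raw sperm, chromosomes 4 and 8 sit most basally
(mean D/L ≈ 0.46–0.47) and most peripherally (H/L ≈ 0.15–0.16), X sits most
apically (D/L ≈ 0.59) and most centrally — the configured topology, read
back by the measurement chain with SEs of ≈ 0.002–0.005 at n ≈ 1000 signals.

```r
res$chromocenters$raw$partition      # Ward clusters of the 7 mean points
#> [[1]] "4" "8"   [[2]] "7" "9" "18"   [[3]] "X" "Y"
subset(res$distances, pair == "4-8")
#>  pair fraction    n mean_um   se_um fold_vs_ref
#>   4-8      DGC 1000   1.580 0.02641        1.05
#>   4-8      raw 1000   1.512 0.02485        1.00
#>   4-8       SU 1000   1.624 0.02589        1.07
```

(Cluster membership of sampled means fluctuates with the seed; on the
published table of means the partitions are exactly {4,8} | {7,9,18,Y} | {X}
for raw at k = 3, {4,8} | {7,9} | {X,Y} | {18} for SU at k = 4, and
{4,8,18} | {7,9,X,Y} for DGC at k = 2 — asserted in the test suite. Pair
distances are induced by independent placement; use
`calibrate_pair_distance()` to target a stated mean.)

Image mode renders the same population into noisy multi-channel scenes,
re-segments nuclei, re-detects spots and runs the identical analysis:

```r
res_img <- run_all(cfg, out_dir = "demo_img", mode = "image")
```

A command-line wrapper is installed at `inst/cli/spermtopo`
(`simulate`, `segment`, `measure`, `classify`, `aggregate`, `stats`,
`run-all`; exit codes 0/2/3 for ok/config/data errors).

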