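---
title: "Methods: the sperm-nucleus topology model in spermtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sperm-nucleus topology model in spermtopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The coordinate model

A decondensed human sperm head lying flat on a slide is close to an ellipse.
spermtopo reduces each nucleus to its longitudinal axis, running from the
basal tail-attachment point to the apex (length $L$, µm), and the short axis
at the widest part (length $l$, µm). A FISH centromere signal is reduced to
its 2D centroid and expressed in two systems:

* **Linear zoning**: the axial fraction
  $t = \langle \mathbf{x} - \mathbf{b}, \mathbf{u} \rangle / L$ (with
  $\mathbf{b}$ the basal point and $\mathbf{u}$ the unit basal→apex vector)
  is cut into three equal territories: $t < 1/3$ basal (`b`),
  $1/3 \le t < 2/3$ middle (`m`), $t \ge 2/3$ apical (`a`).
* **Radial positioning**: $D/L$ with $D$ either the Euclidean distance from
  signal to basal point (literal definition) or the axial projection
  (bounded by 1.0 inside the nucleus), and $H/L$ with $H$ the unsigned
  perpendicular distance to the axis. For a shape ratio $L/l = 1.7$ the
  in-nucleus bound on $H/L$ is $l/2L \approx 0.294$, matching the
  conventional "maximum near 0.3" for the most peripheral signals.

Because a sperm can lie in only two poses that are mirror images of each
other, the sign of $H$ carries no information; spermtopo always folds it
(`H >= 0`). Both $D$ conventions are implemented (`d_mode = "euclidean"` or
`"axial"`) because the verbal definition and the stated maximum of 1.0
conflict; the pipeline requires simulator and measurement to share one mode,
and the synthetic presets are expressed on the axial scale. Neither mode is
claimed to be the original authors' computation.

### Quality control and degenerate input

* Shape gate: nuclei with $L/l$ outside $[1.2, 2.2]$ are excluded. The
  swelling protocol's stated "1.4–1.5-fold" volume increase describes
  decondensation, not an $L/l$ window, so the default gate is deliberately
  permissive and configurable.
* Axial fractions outside $[0, 1]$ by at most $\varepsilon = 0.02$ are
  clamped (boundary measurement noise); beyond $\varepsilon$ the signal is
  flagged a spot-assignment error and dropped with a reason code.
* Zone boundaries are half-open with the apex inclusive, so ties are
  deterministic; boundary hits have measure zero for continuous data.

## Statistical policy

Summaries are mean ± sample SD (across cases, n−1) for zone frequencies and
mean ± SE (pooled over signals) for radial coordinates. Pooling over signals
rather than averaging per-case means is a package choice: the per-signal n
reported next to each SE matches that convention, and with it the simulated
SEs at n ≈ 1000 reproduce the magnitude (0.002–0.008) of the published
tables.

Hypothesis tests follow the source protocol: Shapiro–Wilk gates the choice
between Welch's unpaired t (both groups normal at α) and the Mann–Whitney
rank-sum test; three or more groups use Kruskal–Wallis with Dunn's post hoc
z-tests, Bonferroni-corrected over the three fraction pairs, at α = 0.05.
Because the original report does not say which comparisons used which
two-group test, the gate is explicit, overridable, and every result names
the test used.

**Repositioning calls.** A call between two fractions combines one test per
axis (D/L and H/L). Uncorrected, the family-wise false-call rate would be
$1-(1-\alpha)^2 \approx 2\alpha$, so each axis is tested at $\alpha/2$
(configurable). Under the null the non-"none" rate is then
$1-(1-\alpha/2)^2 \approx \alpha$, which the calibration test verifies over
500 replicates. Directions follow the sign of the mean difference: higher
D/L in the comparison group is "basal–apical" (toward the apex), higher H/L
is "center–periphery".

**Chromocenters.** Ward linkage on Euclidean distances between the
per-chromosome mean (D/L, H/L) points, `ward.D2` by default (`ward.D` gives
identical partitions on the published means; the tests assert partitions,
never merge heights, since the two variants scale heights differently). k is
a required argument — the published analysis implicitly chose k = 3, 4, 2
for raw, swim-up and gradient fractions, and no automatic k selection is
implied. Hull areas use the convex hull of the mean points (shoelace
formula), optionally unioned with the H-mirrored points.

**Reporting arithmetic.** Fold changes and percentages are computed on exact
values and rounded half-up to 2 decimals for reporting (half-up matches
every printed value, including "1.1" for 1.098 at one decimal). Two printed
values do not reproduce exactly from their own printed inputs (+24.24%
recomputes to +24.23, +11.66% to +11.67); the acceptance checks carry a
0.01–0.015 absolute allowance for exactly those two, documented in the
repository's decision log.

## The synthetic generator

The generator states the study's design: `n_cases = 5` donors × 3 fractions
(raw, SU = swim-up, DGC = density-gradient) × `cells_per_case = 200` cells.
Each cell is haploid: one signal each for chromosomes 4, 7, 8, 9, 18 and one
sex chromosome (X or Y, equiprobable). Chromosome 18 positions are drawn
from bearing-specific presets (`18-X` / `18-Y`); its "unselected" summary is
therefore an equal mixture.

* **Positions (radial mode, default).** The axial fraction is a truncated
  normal on $[0.02, 0.98]$ whose target mean is the published per-
  chromosome/fraction/epistate D/L; $|h|$ is a truncated normal bounded by
  0.95× the local ellipse half-width with a random mirror sign. Truncation
  shifts a raw normal's mean, so the generator numerically corrects each
  location parameter (1D root-finding against the truncated-normal mean,
  with the $t$-dependent bound averaged over the axial density) so the
  realized population mean equals the preset. Per-signal SDs are not
  published (only SEs of means); the defaults SD(t) = 0.12 and SD(h) = 0.05
  are package choices that reproduce SEs of ≈ 0.004–0.008 at n = 100–1000,
  and are config-overridable. They are declared approximations, not source
  values.
* **Positions (zone mode).** Alternatively a zone is drawn from the
  published a/m/b multinomial and $t$ uniformly within the zone — the
  parameterization that states linear-zone tables directly.
* **Epimarks.** A latent standard bivariate normal with correlation ρ = 0.7
  maps through $A e^{\sigma z}$ (A = 500, σ = 0.5) to 5mC/5hmC intensities;
  positivity thresholds are the lognormal quantiles matching the published
  positive percentages, so flags, hyper/hypo/mixed strata and intensities
  cohere by construction, and high-5mC cells have high 5hmC. The observed
  Pearson correlation of the intensities is ≈ 0.67 (lognormal attenuation
  of the latent 0.7), inside the ±0.1 recovery band. The positivity
  criterion of the original IF analysis is unstated; the classifier
  therefore supports both a fixed threshold (background mean + k·SD, k = 2,
  or explicit thresholds such as the generator's) and per-mark Otsu, as
  documented alternatives.
* **Cells with discordant marks ("mixed")** draw positions from the
  unstratified preset, count toward positive frequencies, and are excluded
  from hyper/hypo topology strata.
* **Chromatin classes** (aniline blue pink/purple/navy, acridine orange,
  TUNEL) are multinomial labels at the published per-fraction proportions —
  stain chemistry is out of scope, the package only tabulates.
* **Pair distances are induced, not stated**: chromosomes place
  independently, so the mean 4–8 distance emerges from the positional
  presets (≈ 1.5 µm at default spreads). `calibrate_pair_distance()` finds a
  common multiplier on the positional SDs that matches a stated target mean
  (e.g. the published 1.888 µm) against a Monte-Carlo oracle; published
  distance means are recovery targets only after that explicit calibration.
* **Rendering.** Scenes of 9 cells on a 420² px field at 0.1 µm/px:
  uniform ellipse fills (nuclear and IF channels, IF amplitude = the cell's
  intensity), Gaussian FISH spots (σ = 0.15 µm, amplitude 5000, one channel
  per chromosome), then Poisson shot noise plus Gaussian read noise
  (SD 20) over a background of 200 counts, clamped to 16 bits. Basal ends
  are not inferable from images (tails are not rendered); the ground-truth
  sidecar provides the basal annotation, as a stand-in for the visible tail
  used in manual scoring.

### What the generator does *not* emulate

No per-donor random effects (cases differ only by sampling noise, so
across-case SDs are narrower than the published ones), no spatial
correlation between chromosomes beyond shared nucleus geometry, no optics
beyond Gaussian spots, no overlapping or non-elliptical nuclei, no 3D. A
green recovery test therefore establishes that the pipeline is an unbiased
measurement chain for populations with the published first moments — not
that it would reproduce the published tables from the real slides.

## Imaging front-end

Segmentation is a global Otsu threshold plus 8-connected components,
filtered by area (15–80 µm²), solidity (≥ 0.9) and border contact; geometry
comes from an intensity-moment ellipse fit (axis length = 4× the principal
SD of a uniform ellipse). Spot detection is local maxima above background
median + 5·MAD with 3 px minimum separation and intensity-weighted 5×5
sub-pixel centroids. IF intensity is the within-mask mean minus the median
of all out-of-mask pixels. On default-noise synthetic scenes this chain
recovers per-chromosome mean D/L and H/L within 0.001 of the coordinate
truth (budget 0.01 at n ≥ 300 spots) with spot recall and precision above
0.99. There is no TIFF codec in the supported dependency set, so scenes
serialize to plain-text matrices with a JSON channel map.

## Numerical choices, collected

| Quantity | Default | Why |
|---|---|---|
| axial clamp ε | 0.02 | boundary noise vs. mis-assignment |
| shape gate on L/l | [1.2, 2.2] | permissive; source window unstated |
| zone boundaries | half-open thirds, apex-inclusive | deterministic ties |
| SD(t), SD(h) | 0.12, 0.05 | reproduce published SE magnitudes |
| truncation | t ∈ [0.02, 0.98], h ≤ 0.95·half-width | strictly interior signals |
| epimark ρ, σ, A | 0.7, 0.5, 500 | stated correlation; arbitrary units |
| detection | Otsu; bg + 5·MAD; 3 px separation | standard robust defaults |
| α, axis split | 0.05, α/2 per axis | family-wise calibrated calls |
| Ward variant | ward.D2 (ward.D supported) | partitions identical on published means |
| fold rounding | half-up, 2 decimals | matches every printed value |

All thresholds live in the configuration with these defaults; there are no
hidden constants.
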