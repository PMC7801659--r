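---
title: "Quantifying condensate dynamics, puncta morphometry and aggregation"
author: "condensr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensate dynamics, puncta morphometry and aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensr)
```

## Scope and scientific background

Proteins such as the brain-expressed ubiquilins (UBQLN1, UBQLN2, UBQLN4)
self-associate along a continuum from liquid-like condensates to solid
aggregates. Four complementary assays probe where on that continuum a
protein sits:

1. **FRAP** (fluorescence recovery after photobleaching) of intracellular
   puncta measures molecular mobility inside a condensate;
2. **puncta morphometry** in cell images (area, circularity, roundness,
   aspect ratio, solidity, corrected fluorescence) characterizes the
   assemblies themselves, and a two-component normal mixture of punctum
   areas separates a uniformly small population (P1) from a larger,
   broader one (P2);
3. **biochemical fractionation** quantifies the percentage of a protein in
   the PBS-insoluble (pellet) fraction from Western-blot densitometry;
4. **ThT kinetics** track amyloid fibril formation in vitro, summarized by
   the time to half transition to steady state.

`condensr` implements the full quantification chain for all four assays,
plus the rank-based statistics used to compare experimental groups, and a
synthetic-data generator that produces every input with known ground
truth. The generator is first-class, tested code: every analysis stage is
validated in closed loop against the model that generated its input.

## The FRAP model

A punctum is bleached in a small circular stimulation ROI and imaged
before and after. After two-anchor normalization the recovery is fitted
with the single-exponential model

$$ F(t) = A\,\bigl(1 - e^{-t/\tau}\bigr), $$

where $A$ is the **mobile fraction** (the asymptotic recoverable signal;
$1 - A$ is immobile) and $\tau$ the recovery time constant. We keep the
field's labeling of $\tau$ as the "half time" in the `half_time_s` field,
but note that the literal time to half recovery of this model is
$\tau \ln 2$; both are reported (`t_half_ln2_s`), clearly named, so no
reader has to guess which convention a number uses.

### Pipeline and its conventions

* **Acquisition schedule** (`frap_schedule()`): 5 pre-bleach frames every
  2 s, then 12 post-bleach frames every 5 s and 36 every 10 s — dense
  early sampling for the rising phase, 7 min total. Time zero is the
  first post-bleach frame; pre-bleach frames carry negative timestamps,
  because the model is defined on recovery time.
* **Candidate selection** (`select_bleach_candidates()`): a punctum is
  bleachable when the stimulation ROI covers at most 80% of its area and
  no neighbouring punctum centroid lies within the exclusion radius.
  "Immediately neighbouring" is not a number, so the default radius is
  twice the candidate's equivalent diameter — close enough to catch
  content exchange between touching puncta, scale-aware for small and
  large puncta alike. An optional size band restricts candidates to the
  large-population (P2) size range actually bleached in practice.
* **FRAP ROI** (`build_frap_roi()`): the thresholded pre-bleach signal
  minus the thresholded post-bleach signal, i.e. the region that lost
  signal. This mask arithmetic is equivalent to the classic
  invert-the-pre-mask-and-subtract recipe.
* **Trace extraction** (`extract_trace()`): per frame, the integrated
  density of the FRAP ROI divided by the integrated density of the
  pre-bleach ROI. The default denominator is the pre-bleach ROI's density
  averaged over the pre-bleach frames — a fixed reference. The
  alternative (`reference = "per_frame"`) divides by the same-frame
  density; it cancels whole-frame acquisition photobleaching exactly, but
  because the recovering bleached region is itself part of the pre-bleach
  ROI, a per-frame denominator distorts the recovery curve (the measured
  plateau overshoots the true mobile fraction by roughly the bleached
  fraction of the punctum). With the fixed reference the extracted curve
  is an affine image of the generating model, and the closed-loop
  round trip (simulate, extract, normalize, fit) recovers $(A, \tau)$ to
  numerical precision. Use `per_frame` only when acquisition bleaching
  dominates; no further bleaching-reference correction is applied in
  either mode.
* **Normalization** (`normalize_trace()`): the affine map forced by two
  anchors — mean of the pre-bleach values to 1, first post-bleach value
  to 0. The contract holds to machine precision and the map is
  idempotent.
* **Fitting** (`fit_recovery()`): bounded Levenberg–Marquardt nonlinear
  least squares over the post-bleach points only (the model is a pure
  recovery curve; pre-bleach points are anchors, not data). Bounds
  $A \in [0, 1.5]$ (loose above 1 to let noise average correctly),
  $\tau \in (0, 10\,t_{\max}]$. Start values: $A_0$ = mean of the last
  three normalized points, $\tau_0$ = first crossing of $A_0/2$ (fallback
  mid-span). Because $A$ enters linearly, a profile grid over $\tau$ with
  closed-form $A(\tau)$ seeds retries and serves as a deterministic
  fallback for near-flat traces, where the gradient is singular. Fits
  with $A < 0.02$ are flagged: an immobile punctum leaves $\tau$
  unidentifiable, and its value should not be interpreted.

### Accuracy under the study conditions

With the default schedule and trace noise of sd 0.01, the test suite
verifies over the grid $A \in \{0.3, 0.6, 0.9\} \times \tau \in
\{20, 60, 120\}$ s (20 seeds each) that the median absolute error of
$\hat A$ stays within 0.05 and the median relative error of $\hat\tau$
within 10%; in practice both are several-fold smaller. Noiseless
recovery is exact to $10^{-3}$. A three-group comparison with
$\tau_1 < \tau_2 = \tau_3$ (30 vs 60 = 60 s, six puncta per group)
identifies the faster-recovering group in at least 19 of 20 runs —
the design mirrors a fast-recovering protein versus two similar slower
ones.

## Image operations

* **Registration** (`register_stack()`): translation-only FFT
  cross-correlation against the first frame, with parabolic subpixel
  refinement (quarter-pixel accuracy) and bilinear resampling;
  out-of-field pixels take the frame's median. Classic rigid-body
  registration also allows rotation; punctum drift in these time-lapses
  is overwhelmingly translational, so rotation is deliberately out of
  scope.
* **Segmentation** (`segment_puncta()`): Otsu's global threshold computed
  on a 3×3-median-filtered copy but applied to the unfiltered image —
  the filter stabilizes the threshold against shot noise without eroding
  small puncta — then 8-connected components, with components under
  `min_area_px = 4` px discarded.
* **Morphometry** (`measure_punctum()`): circularity
  $4\pi A / P^2$ (clipped at 1), roundness $4A/(\pi\,\text{major}^2)$,
  aspect ratio major/minor, solidity $A / A_{\text{hull}}$ (clipped at
  1). The perimeter is the Moore boundary-trace contour length with
  Vossepoel–Smeulders step weights (0.980 axial, 1.406 diagonal), which
  de-biases the staircase overestimate; a single-pixel component is
  assigned perimeter $2\sqrt{\pi}$ so its circularity is exactly 1 by
  convention. Axes come from the second-moment-equivalent ellipse with
  each pixel treated as a unit square (variance 1/12 per axis), and the
  convex hull is taken over pixel centres, which pairs correctly with a
  pixel-count area. Every discrete perimeter convention distorts some
  shape: ours renders discs near circularity 1 (by design, they are the
  reference shape) at the cost of inflating rasterized squares somewhat
  above the analytic $\pi/4$.
* **Fluorescence statistics**: CTCF (corrected total cell fluorescence)
  is integrated density minus cell area times mean background, with the
  background ROI supplied by the user — the standard form, adopted here
  as an explicit convention since published methods sections rarely spell
  it out. CTFP is the punctum analogue, and percent punctate fluorescence
  is $100 \sum \text{CTFP} / \text{CTCF}$.

## Mixture modeling of punctum areas

`em_fit()` implements expectation-maximization for univariate normal
mixtures, with:

* **initialization** by quantile split of the sorted sample into K blocks
  (block means/SDs, equal weights); each of the 10 default restarts
  jitters the block boundaries, and the best final log-likelihood wins;
* **convergence** at relative log-likelihood change below $10^{-8}$ or
  1000 iterations; a variance floor of $10^{-6} (\max x - \min x)^2$
  blocks the classical degenerate collapse;
* **label switching** resolved by sorting components by ascending mean,
  so P1 (small puncta) is always component 1;
* the per-iteration log-likelihood trace stored on the model, and
  asserted non-decreasing in the tests for every run.

Sampling fixtures use population weights 0.40/0.60, the midpoints of the
published 37–43% / 57–63% ranges. Recovery fixtures draw from
*untruncated* normals even though an area cannot physically be negative:
the fitted model is the plain normal mixture, so truncating the generator
would bias maximum-likelihood recovery; `truncate_at_zero` exists only
for image-geometry uses. Whether published fits pooled puncta across
cells and experiments is not stated; the package fits whatever sample it
is handed, and the per-dataset log-likelihoods reported elsewhere are not
reproducible without the raw puncta tables, so they are not targets.
`compare_components()` adds AIC/BIC over candidate K (with $3K-1$ free
parameters) — information criteria select the generating K in simulation,
and the log-likelihood is non-decreasing in K by nesting.

## Solubility and aggregation kinetics

`percent_insoluble()` computes
$100 \, P_{\text{corr}} / (S_{\text{corr}} + P_{\text{corr}})$ where each
band is divided by its own lane's loading normalizer (Ponceau or a
housekeeping protein) and multiplied by an explicit per-sample
lysate-volume factor. The volume correction is exposed as an explicit
factor because the published arithmetic ("corrected for concentration
based on lysate volume") under-determines it; with factors of 1 the
formula reduces to the plain normalized ratio. The result is invariant
under common rescaling of both lanes and always lies in $[0, 100]$.

"Time to half transition to steady state" for ThT curves has no agreed
formula; `tht_t50()` adopts a model-free estimator — baseline = mean of
the first 5% of points, plateau = mean of the last 10%, t50 = first
midpoint crossing, linearly interpolated — because it is assumption-light
and matches the phrase directly. Steady state is declared when the
least-squares slope over the last 10% of points is below 1% of the
dynamic range per hour; otherwise t50 is withheld rather than reported
from a still-rising curve. A logistic-fit estimator
(`method = "logistic"`) is available as a cross-check; on clean sigmoid
data the two agree to a fraction of the sampling interval. The estimator
is exactly invariant under affine transforms of the fluorescence axis and
scales with time units. Whether published t50 values were read from mean
curves or per replicate is unknown; both are supported
(`average_replicates()` produces the mean ± SEM curve).

## Statistics

`kruskal_wallis()`, `dunn_posthoc()` and `anova_oneway()` are implemented
from their defining formulas — midranks and tie corrections in both the
H statistic and the Dunn variance — rather than delegated, because the
surrounding pipeline needs auditable, table-friendly outputs; base R's
`kruskal.test` and `aov` serve as independent cross-checks in the test
suite, where agreement is exact. Dunn p-values are unadjusted by default
with a Bonferroni option, since the original analyses do not state an
adjustment; the all-values-tied sample is given the convention
$H = 0, p = 1$. At very small samples ($n \le 8$) the chi-square
approximation is anticonservative relative to the exact permutation null
(gap up to about 0.2 in p at $n = 4$); the tests document this gap, and
the simulated type-I error at the working sample size (3 groups × 10) is
within [0.04, 0.06] at $\alpha = 0.05$.

## What the generator does and does not emulate

`simulate_frap_stack()` renders a disc punctum, bleaches the stimulation
ROI by a depth factor (default 0.1; achieved laser bleach depth is
instrument-specific and unpublished, so this is a free choice), and lets
bleached pixels recover along the single-exponential model — by
construction, since that is the model being fitted. Optional layers:
whole-frame acquisition photobleaching, rigid drift (the bleached
molecules travel with the punctum), additive Gaussian noise. Fixed
conventions: with zero noise and drift, intensity outside the stimulation
ROI is constant (recovered fluorescence is *not* drawn from the
unbleached pool — condensate-bound protein vastly outnumbers the bleached
molecules, so depletion of the reservoir is negligible and is not
modeled). Not emulated: diffusion-PDE recovery profiles (the fitted model
is the single exponential, so generating anything richer would test a
different model), Poisson shot noise (optional additive Gaussian only),
3-D stacks, multi-channel imaging. Passing tests therefore demonstrate
correctness of the quantification chain under its own model assumptions,
not robustness to reaction–diffusion kinetics or detector physics.

All generators take explicit integer seeds and touch no global random
state; identical spec + seed gives bit-identical output.

## Problem sizes in the tests and acceptance script

Mixture recovery runs at $n = 2000$ areas per parameter set — enough that
three standard errors of a component mean ($3\sigma/\sqrt{n w}$) is a
tight band (±0.06 µm² for the smallest P1, ±0.93 µm² for the widest P2)
while EM converges in well under a second. FRAP recovery uses the full
53-frame default schedule; the Monte-Carlo blocks use 20 seeds per
condition, the null-calibration block 5000 replicates. These sizes were
chosen as the smallest that make the statistical assertions sharp.

## Known limitations

* Registration is translation-only; strong rotational drift would leak
  into the FRAP ROI.
* Segmentation assumes a global threshold separates puncta from their
  surroundings; touching puncta are not watershed-split, and cell
  boundaries are inputs, not outputs.
* The FRAP model is the single exponential; two-component or
  diffusion-limited recoveries will show structured residuals (inspect
  `rss` and the trace) rather than a warning.
* Mixture fitting assumes normal components on the untransformed area
  scale, mirroring the published analysis; heavy right tails can inflate
  the P2 variance rather than add components.
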