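# condensr

Quantification of protein condensate dynamics, puncta morphometry and
aggregation assays.

Proteins implicated in neurodegeneration — the brain-expressed ubiquilins
UBQLN1/2/4 are the motivating case — self-associate along a continuum from
liquid-like condensates to solid aggregates. Where a protein sits on that
continuum is measured by four complementary assays, and `condensr`
implements the quantification chain for all of them:

* **FRAP** (fluorescence recovery after photobleaching): rigid stack
  registration, FRAP-ROI construction by mask arithmetic, two-anchor trace
  normalization, and bounded nonlinear fitting of the recovery model
  `F(t) = A (1 − exp(−t/τ))`, where `A` is the mobile fraction and `τ` the
  recovery time constant (reported both as `τ` and as the literal
  half-recovery time `τ ln 2`);
* **puncta morphometry**: Otsu segmentation, per-punctum area, perimeter,
  circularity `4πA/P²`, roundness, aspect ratio, solidity, and the
  corrected fluorescence statistics CTCF/CTFP with percent punctate
  fluorescence `100 ΣCTFP / CTCF`;
* **two-population mixture modeling**: maximum-likelihood fitting of
  K-component univariate normal mixtures by expectation-maximization
  (restarts, variance floor, monotone log-likelihood), separating the
  small-puncta population P1 from the large population P2;
* **biochemistry**: percent-insoluble protein
  `100 P/(S+P)` from loading- and volume-corrected densitometry, and the
  thioflavin-T time to half transition to steady state;
* **statistics**: tie-corrected Kruskal–Wallis, Dunn's post-hoc z tests,
  and one-way ANOVA with Bonferroni pairwise comparisons, implemented from
  their defining formulas.

A synthetic-data generator produces every input the pipeline consumes —
FRAP image stacks, fixed-cell images, punctum-area samples, densitometry
tables, ThT traces — with known ground truth and explicit seeds, so the
entire chain is testable without a microscope. See the vignette
(`vignettes/condensate-quantification.Rmd`) for the models, conventions
and design decisions.

## Worked example

Simulate a FRAP experiment with known truth (mobile fraction 0.7, τ = 60 s,
additive noise), then run the full analysis chain on the rendered images:

```r
library(condensr)

truth <- frap_ground_truth(mobile_fraction = 0.7, half_time_s = 60,
                           noise_sd = 1.5, seed = 42)
sim   <- simulate_frap_stack(truth)                  # 53-frame image stack
stack <- register_stack(sim$stack)$stack

lvl <- (truth$background_level + truth$punctum_level) / 2
pre_mask  <- stack$pixels[, , 1] > lvl               # thresholded pre-bleach
post_mask <- stack$pixels[, , stack$bleach_frame_index] > lvl
frap_roi  <- build_frap_roi(pre_mask, post_mask)     # bleached-signal region

trace <- normalize_trace(extract_trace(stack, frap_roi, pre_mask))
fit   <- fit_recovery(trace)
fit
#> <frap_fit> A = 0.700, tau = 59.95 s (t1/2 = 41.56 s), rss = 2.18e-05
```

The fitted mobile fraction (0.700) and time constant (59.95 s) recover the
generating truth; `t1/2` is the literal half-recovery time `τ ln 2`, and
the tiny residual sum of squares confirms the single-exponential model
describes the trace.

Decompose punctum areas into two populations with EM (the generating
parameters are the published UBQLN1 values: P1 0.8 ± 0.6 µm², P2
11.2 ± 10.1 µm², weights 0.40/0.60):

```r
areas <- sample_puncta_areas(mixture_spec(weights = c(0.4, 0.6),
                                          means = c(0.8, 11.2),
                                          sds = c(0.6, 10.1),
                                          n = 2000, seed = 1))
em_fit(areas$area, K = 2, restarts = 10, seed = 1)
#> <mixture_model> K = 2, logLik = -6386.86 (n = 2000)
#>  component weight   mean     sd
#>          1  0.393  0.780  0.624
#>          2  0.607 11.444 10.542
```

Component 1 (P1, small puncta) comes back at 0.78 µm² with weight 39% and
component 2 (P2) at 11.4 µm² — within sampling error of the generating
parameters.

Compare groups nonparametrically:

```r
kw <- kruskal_wallis(c(1,2,3,4,5,6,7,8,9), rep(c("U1","U2","U4"), each = 3))
#> H = 7.2, df = 2, p = 0.027
```

A command-line wrapper over the same functions is installed at
`exec/condensr` with subcommands `morpho`, `analyze-frap`, `mixture`,
`solubility`, `tht` and `stats` (CSV/TIFF in, CSV/JSON out).

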