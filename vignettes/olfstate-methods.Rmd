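---
title: "Methods: state-dependent chemoreceptor expression and activity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent chemoreceptor expression and activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfstate)
```

`olfstate` implements the quantitative core of a common experimental design
in *C. elegans* chemosensation: an internal state (here, a few hours of food
deprivation) changes the expression of chemosensory GPCRs, and the analysis
has to connect a bulk two-condition abundance table, a single-cell
expression atlas, fluorescent reporter images, GCaMP recordings, and
endpoint behavioral assays into one coherent set of statistics. This
vignette explains each model and procedure, the defaults and why they were
chosen, what the synthetic-data generators emulate, and where the
pipeline's known limitations lie.

## Differential selection and enrichment

### Fold changes and gene sets

The pipeline starts from a long-format abundance table (gene x condition x
replicate). Fold change is the ratio of arithmetic replicate means with a
pseudocount added to both sides:

$$r_g = \frac{\bar{A}_{g,\mathrm{fasted}} + c}{\bar{A}_{g,\mathrm{fed}} + c},
\qquad c = 0.5 \text{ by default.}$$

No shrinkage or dispersion modelling is applied: the target statistic is a
plain fold-change threshold ("more than fourfold"), which is reproducible
from any abundance table regardless of how the table was quantified
upstream. The pseudocount keeps ratios finite for genes undetected in one
condition while barely perturbing well-expressed genes; it is configurable
because different upstream quantifiers produce different zero patterns.
Selection is *strict*: `ratio > threshold` for upregulated genes,
`ratio < 1/threshold` for downregulated, with boundary values excluded —
"more than fourfold" is an open interval. Ties at the cutoff therefore
never enter a set, which makes selection invariant to gene order and to
any stable re-sorting of the table.

### Family enrichment (Fisher exact test)

Whether chemoreceptors are overrepresented among the upregulated genes is a
2x2 problem: membership in the upregulated set crossed with membership in
the gene family, over the detected-gene universe. We use the one-sided
(greater) Fisher exact test because the scientific claim is
overrepresentation; a two-sided test would also reject for depletion, which
is not the hypothesis. On the published desk-scale counts — 133
chemoreceptors among 802 upregulated genes against an 8.5% background
prevalence in 16,591 detected genes — this test rejects at far below the
0.001 level (the package's acceptance script recomputes this number).

### Per-neuron enrichment against a binary atlas

The atlas is a binary neuron x gene matrix ("expressed or not"), as one
gets by thresholding a single-cell atlas. For each neuron we form

$$\mathrm{ratio} = \frac{k/K}{m/M},$$

where $k$ of the $K$ upregulated family genes and $m$ of all $M$ family
genes are expressed in the neuron. Under uniform upregulation across the
family the ratio is 1. Each neuron is tested on the within-family 2x2 table
`[k, K-k; m-k, (M-K)-(m-k)]` with a Pearson chi-squared test. Three
decisions deserve comment:

* **No Yates correction by default.** The continuity correction is known to
  be conservative on 2x2 tables; it is available via `correct = TRUE`.
* **Fisher fallback below expected count 5.** Per-neuron counts can be
  small (a neuron may express only a handful of family genes), and the
  chi-squared approximation degrades exactly there. When any expected cell
  is below 5 the test switches to the exact test; the `method` column
  records which route each neuron took.
* **Significance requires enrichment.** The chi-squared test is two-sided,
  but the reported `significant` flag additionally requires `ratio > 1`. A
  neuron expressing *fewer* upregulated receptors than expected is
  interesting but is not the claim being tested, and flagging it would
  inflate the apparent false-positive rate of the enrichment question.

The Bonferroni family is the number of neurons actually tested (those with
$m > 0$), not the number of rows in the atlas: an untested neuron carries
no hypothesis. Across 1,000 simulated null atlases the family-wise error
rate of this procedure measures about 4.6%, i.e. nominal control at
$\alpha = 0.05$ (the acceptance suite recomputes this).

## Reporter quantification

Confocal z-stacks are collapsed by maximum-intensity projection (optionally
restricted to a slab around the brightest plane when two somata at
different depths must be separated). The soma ROI is found automatically:
3x3 median filter, threshold halfway between the image median and the
filtered maximum, connected component containing the brightest pixel, box
of configurable half-width (default 9 px, about three soma radii of the
synthetic fixtures) centred on the component centroid.

The raw score is the mean of the brightest 5% of ROI pixels minus the mean
of the dimmest 5% — neural signal minus local background. The tail size is
$\lceil 0.05\,n \rceil$ from a stable sort, so the score is deterministic,
order-invariant, and unchanged by adding a constant to every pixel. Note a
property that matters for interpretation: averaging the top 5% of a
Gaussian-profile soma in a 3-sigma box yields about 85% of the true peak
amplitude. This attenuation is *multiplicative* and identical for all
stacks imaged with the same geometry, so it cancels exactly in the
session-normalization step, where every score is divided by the mean raw
score of same-session fed wild-type controls. The pipeline-level recovery
check reflects this: a planted fivefold induction comes back as a
normalized score within a few percent of 5.0, even though raw scores sit
below the planted peaks. An alternative reading of the original protocol —
taking tails over a 1-D intensity profile through the box rather than all
box pixels — would score closer to the raw peak; the all-pixels reading is
implemented because it is the more robust statistic, and the choice only
rescales raw (never normalized) scores.

Group comparisons are two-tailed two-sample t-tests, Welch by default
(pooled variance by flag, since the original reports do not state the
variant), Bonferroni-corrected over the number of requested pairs.

## Calcium trace processing

### Freely-moving paradigm

The processing chain is: background subtraction (per-frame neuron minus
background ROI), 10-frame (1 s at 10 fps) centred moving median, baseline
as the 5th percentile of the smoothed trace over the whole recording, and

$$\Delta F/F_0 = \frac{F_\mathrm{smoothed} - F_0}{F_0}.$$

Numerical conventions are stated explicitly because they differ between
software stacks: the percentile uses linear interpolation between order
statistics (R's type 7); the even-length median window at index $i$ spans
$i-4$ through $i+5$ and is truncated at the recording edges so the output
length equals the input length; baseline is computed on
background-subtracted-then-smoothed fluorescence, in that order. A
non-positive baseline is an error, not a silent NaN.

One bias is inherent to the percentile-baseline method and worth knowing:
with noise of standard deviation $\sigma_s$ in the smoothed trace, the 5th
percentile sits roughly $1.6\,\sigma_s$ below the true resting level, which
inflates small $\Delta F/F_0$ amplitudes additively. At the synthetic
fixtures' default signal-to-noise (noise SD 3 on a baseline of 100, i.e.
an effective SNR above 10 for the smallest 0.5 dF/F0 transients) this bias
stays within a few percent; at substantially noisier settings it, not peak
detection, becomes the dominant amplitude error. The same bias is present
in any analysis that uses a low-percentile baseline on noisy traces.

Peaks are local maxima above a threshold (default 0.2 dF/F0) kept greedily
in decreasing amplitude order subject to a minimum separation (default
2 s); duration is full width at half maximum. These three constants are
declared defaults, not claims about biology — the original figure does not
define peak criteria — and all are configurable.

Spatial context uses the *signed* distance to the lawn boundary: positive
outside, negative inside. The signed convention keeps the axis continuous
through the food encounter (the first frame at distance <= 0), so
pre- and post-encounter activity can be binned on one axis in half-open
0.5 mm bins. The feeding-state comparison is a fixed-effects two-way ANOVA
(state x bin, with interaction) on per-animal bin means; restricting to
bins visited by every animal keeps the design complete, and the demo
pipeline does exactly that.

### Microfluidic paradigm

For odor-delivery trials in a chip, $F_0$ is the mean background-subtracted
fluorescence over seconds 2-3 of the trial, each frame becomes
$(F/F_0 - 1)\cdot 100\%$, and the per-epoch maxima are taken over Pre
(0.0-4.9 s), Stim (5.0-15.0 s) and Post (15.1-29.9 s) with inclusive
bounds exactly as printed. Frames falling in the (4.9, 5.0) gap belong to
neither epoch; a maximum exactly at 5.0 s is a Stim maximum. Window
comparisons use an absolute tolerance of 1e-8 s so that floating-point
time grids (0.1 s steps accumulated by repeated addition) bin identically
across platforms.

## Behavioral endpoints

The chemotaxis index is $(n_\mathrm{odor} - n_\mathrm{control}) /
(n_\mathrm{odor} + n_\mathrm{control} + n_\mathrm{other})$; the food-choice
index is $n_\mathrm{exp} / (n_\mathrm{exp} + n_\mathrm{control})$ with
animals outside both patches excluded (the original methods sentence
contains a typo at exactly this point; this is its plain reading). Both are
scale-free in the counts and summarized as mean ± SEM over plates.

Exploration coverage rasterizes the centroid trajectory onto a grid of
3.5 mm squares anchored at the corner of the plate's bounding square
(plate centre at the coordinate origin) and counts squares crossed by any
segment. Rasterization is exact — each segment is cut at every gridline it
crosses — so fast-moving segments cannot skip squares, and coverage is
monotone as frames are appended. Because the real assay's manual grid
placement is unregistered, `average_phases = TRUE` averages the count over
four half-cell offsets as a sensitivity analysis.

## Synthetic data: what it emulates and what it does not

Every input class has a generator with known ground truth, and every
generator is a deterministic function of its seed (sub-seeds for pipelines
come from one master seed via a fixed affine map, `derive_seed()`).

* **Expression tables**: per-gene baseline means lognormal across genes
  (median 100, log-SD 1, spanning a few orders of magnitude); replicate
  noise lognormal with stated CV, so a planted gene's *expected*
  fasted/fed ratio equals its true ratio exactly. Planted fold changes
  default to 5-8x against the fourfold cutoff.
* **Atlases**: independent Bernoulli entries at 8% — a realistic fraction
  of a ~1,400-gene chemoreceptor repertoire for a single amphid neuron —
  with one optional planted neuron whose probability for the target genes
  is multiplied by a 5x excess (capped at 1). The acceptance-scale
  conditions use the repertoire at its real size (133 upregulated of 1,365
  family genes, 12 amphid neurons): family-level counts, not per-gene
  effects, set the power of the enrichment test, and at this scale the
  planted neuron is detected specifically in about 95% of atlases.
* **Image stacks**: uniform background plus one isotropic Gaussian soma on
  integer voxel coordinates plus Gaussian noise. Amplitudes default to
  hundreds of counts above background, as on a 16-bit camera.
* **GCaMP recordings**: fluorescence is
  `background + baseline * (1 + sum of kernels) + noise` with
  difference-of-exponentials kernels normalized to unit peak, so planted
  amplitudes are directly comparable to detected dF/F0 amplitudes up to
  grid sampling. Kernel time constants (rise 0.5 s, decay 2 s) are fixture
  parameters, not measured indicator kinetics. The trajectory is a biased
  random walk toward the lawn centre with fixed step length; while outside
  the lawn every step has a positive radial component, so the boundary is
  crossed exactly once and the encounter frame is well defined. Transient
  onsets may be specified relative to the encounter for fixtures that need
  activity tied to food approach.
* **Assay counts**: multinomial per plate with probabilities solved so the
  expected computed index equals the planted index exactly (for food
  choice, conditionally on at least one patch animal).

What passing the recovery suite does *not* show: the generators contain no
locomotion dynamics, no pharyngeal pumping, no photobleaching, no motion
artifacts, no correlated replicate structure, no compositional effects in
the abundance table, and no spatial correlation in imaging noise. Recovery
on these fixtures demonstrates that the estimators compute their defining
formulas correctly and are unbiased under the stated noise models — not
that the defaults are optimal for any particular real dataset.

## Problem sizes and determinism

The recovery benchmarks run at fixed sizes chosen to make their Monte-Carlo
error small relative to the margins being checked: 100 simulated expression
tables for exact set recovery, 100 planted and 1,000 null atlases for
specificity and family-wise error, 100 stack sessions for reporter
recovery, 50 recordings x 10 transients for calcium sensitivity and
amplitude error, 200 plates per planted index, and 10,000 null t-tests for
the type-I rate. All of them, and the `run_demo()` pipeline, reproduce
byte-for-byte under a fixed seed.

## Known limitations

* The enrichment stage assumes the atlas is binary and error-free;
  thresholding noise in a real single-cell atlas propagates directly into
  $m$ and $k$.
* The percentile baseline biases small dF/F0 amplitudes upward at low SNR
  (quantified above); bleaching-dominated recordings need a correction the
  package deliberately does not provide.
* Raw reporter scores underestimate peak soma intensity by a
  geometry-dependent factor; only session-normalized scores are comparable
  across imaging configurations.
* The exploration grid is registered to the plate bounding box; a real
  manually-placed grid differs by a phase the sensitivity option can probe
  but not remove.
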