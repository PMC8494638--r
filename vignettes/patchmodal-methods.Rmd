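---
title: "Models and methods behind patchmodal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind patchmodal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchmodal)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the tunable parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open. It states no empirical result
that the test suite or the acceptance script does not itself compute.

## The scientific setting

Patch-seq records three modalities from one neuron: current-clamp
electrophysiology, a biocytin-filled morphology, and a single-cell
transcriptome. In human supragranular (L2–3) neocortex, transcriptomically
defined types (t-types) of glutamatergic neurons differ in their
morphoelectric phenotypes, and the dominant type varies continuously with
cortical depth. The analysis layer therefore needs: per-modality feature
extraction with quality control, assignment of each cell to a reference
t-type, normalization of anatomical position to a scaled laminar depth, and
statistics that relate features to types and to depth with robust
inference and multiple-testing control. `patchmodal` implements exactly
that layer, plus generators that produce all four input kinds with known
ground truth.

## The electrophysiology simulator

The neuron model is a leaky integrate-and-fire (LIF) cell with a spliced
stereotyped action potential and a slow rebound implementing sag. This is
deliberately the *simplest* model for which every extracted feature has a
closed-form or constructively known ground truth: acceptance is parameter
recovery, not biophysical realism.

- **Subthreshold**: deflection charges as a single exponential with time
  constant $\tau$ toward $I R$ ($R$ in M$\Omega$, $I$ in pA, so
  $\Delta V_{\mathrm{mV}} = I R \times 10^{-3}$).
- **Sag** (hyperpolarizing steps only, h-current-like): the membrane first
  charges toward an overshoot deflection $IR/(1-a)$, where $a$ is the sag
  fraction; a slow exponential (default $\tau_{\mathrm{slow}} = 100$ ms,
  engaged at $7\tau$) then relaxes it to the Ohmic steady state $IR$. In
  the long-step limit the measured sag ratio
  $(V_{\min}-V_{ss})/(V_{\min}-V_{base})$ equals $a$ exactly, the
  steady-state deflection still gives $R$, and the onset transient below
  $7\tau$ is a pure single exponential so $\tau$ is recoverable. A naive
  two-exponential sum cannot satisfy all three at once within a 1 s step
  when $\tau = 20$ ms: its deflection peak never approaches the overshoot
  asymptote unless $\tau_{\mathrm{slow}} \gg \tau$ *and* the step duration
  $\gg \tau_{\mathrm{slow}}$, which is why the delayed-onset form was
  chosen. The delayed engagement is a stylized stand-in for the activation
  delay of the h-current.
- **Spikes**: when the membrane crosses the threshold voltage, a piecewise
  linear waveform (1 ms rise to +30 mV, 1.25 ms fall to 5 mV below
  threshold) is spliced in and the membrane resets to the
  after-hyperpolarization voltage. Crossing times are computed in closed
  form, so the rheobase $(v_{th}-V_{rest})/R$ and all inter-spike
  intervals are analytically known (`lif_spike_times()` is the oracle used
  in tests).
- **Noise**: additive white Gaussian on voltage only; the current trace
  records the commanded stimulus exactly, which keeps the
  stimulus-conservation invariant exact and QC tests deterministic.

The default protocol (`default_protocol()`) uses −100/−70/−30 pA
hyperpolarizing steps and a depolarizing series in 10 pA increments
straddling the analytic rheobase, 1 s steps. The actual stimulus table of
the recordings that motivated this package is not published; this stand-in
covers every feature the extraction layer measures, and the protocol is an
explicit argument everywhere.

### Feature extraction choices

Published methods name the operations but not all operational constants;
the following were fixed once and exposed as arguments:

- Spike refinement: minimum threshold-to-peak height 2 mV, maximum
  threshold-to-peak interval 5 ms, minimum absolute peak −30 mV —
  conventional values for somatic whole-cell recordings.
- Threshold definition: first point where dV/dt reaches 5 % of the spike's
  maximal upstroke.
- dV/dt smoothing: linear-phase moving average over 0.5 ms (the contract
  is "any linear-phase smoother with configurable width").
- Adaptation index: the phrase "mean ratio of consecutive inter-spike
  intervals" is ambiguous between $ISI_{k+1}/ISI_k$ and a normalized
  difference; the normalized difference
  $\mathrm{mean}\,(ISI_{k+1}-ISI_k)/(ISI_{k+1}+ISI_k)$ was chosen because
  it is bounded in (−1, 1) and exactly 0 for a regular train.
- Sag sweep selection: nearest amplitude within ±20 pA of −100 pA, else
  missing. Before reading the sag extrema the trace is smoothed with a
  5 ms moving average: the raw minimum of a 20 kHz trace at 0.2 mV noise
  is a ~3.5-sigma noise excursion that would bias the ratio upward by
  several times the acceptance tolerance.
- $\tau$ fitting: a log-linear fit between 10 % and 90 % of the peak
  deflection seeds a nonlinear least-squares refinement on the raw
  transient (the log-linear estimator alone is biased at realistic noise).
- QC RMS windows: final 500 ms of pre-stimulus baseline after linear
  detrending; short-window RMS is the maximum over sliding 1.5 ms windows.
  The 0.07 mV short-window limit presumes Bessel-filtered hardware noise;
  the simulator's white noise at 0.2 mV intentionally fails it, so
  parameter-recovery tests run with `qc = FALSE` while QC behaviour is
  tested on quiet baselines.

## The morphology layer

Reconstructions are SWC node trees (soma/axon/basal/apical). The dialect:
1-based ids, micrometres, y increasing toward the pia; aligned
morphologies place the pia at y = 0. One soma root is required; extra
roots are tolerated only for axon fragments that could not be traced back
to the main structure (these are included in axon histograms but excluded
from branch-order statistics).

Corrections: shrinkage re-expands z about the soma by the ratio of
recorded to fixed soma depth (the soma is a fixed point; x, y unchanged);
tilt is a rigid rotation about the soma in the y–z plane, valid for
|angle| < 90°. Features dominated by z are not emitted (slice compression
makes them artefactual); the tangential width uses x only.

The laminar histogram apportions each inter-node segment's 3D length
across depth bins in proportion to the segment's vertical overlap with the
bin (horizontal segments go wholly to the bin containing their depth,
deeper bin on an exact edge). This conserves total length identically —
the invariant the acceptance suite checks at 1e-9 — and is verified
against a fine-subdivision oracle. Open choices fixed here: branch order
counts soma-emanating stems as order 1 and increments at bifurcations;
"basal maximum distance" is Euclidean (radial extent), with path distance
emitted separately; default depth bin width 50 µm, while per-layer totals
always come from the layer-context boundaries.

The morphology generator builds archetypes as parameter presets — a
"superficial" cell whose apical tuft branches inside L1 and a "deep"
(COL22A1-like) cell whose apical dendrite terminates below L1 with wider
basals. It emulates the qualitative laminar contrasts (L1-reaching vs
L1-avoiding apicals, narrow vs wide basal fields) and records constructive
ground truth (apical vertical extent; the most distal basal node is placed
at exactly the designed radial extent). It does not emulate realistic
branching statistics, spines, or axon arbors.

## The transcriptomics layer

Counts are normalized as log₂(CPM + 1). "Expressed" means CPM > 1; the
published source does not name the unit behind its threshold of 1, so this
reading is a documented choice (`cpm_threshold` argument).

The **beta score** of a gene with per-cluster expressed proportions
$p_1..p_k$ is $\beta = \sum_{i<j}(p_i-p_j)^2 / (\sum_{i<j}|p_i-p_j| +
\varepsilon)$, in [0, 1], with $\varepsilon = 10^{-6}$ (the source says
only "a small constant") and pairs unweighted by cluster size (also
unstated there). The top 2000 genes by beta form the default marker panel.

**Mapping** is the correlation variant: a cell's marker-gene log-CPM
vector is correlated (Pearson) against per-cluster median centroids; the
label is the argmax and the confidence the gap to the runner-up. Ties
break by cluster label order; zero-variance query vectors are returned
unmapped with a reason. Anchor-based integration and UMAP projection are
deliberately out of scope: any embedding is presentation-layer and plays
no role in the statistics.

**Heterogeneity** follows the published recipe (80 cells, 80 most variable
genes, PC1 % variance, 100 per-gene shuffles) with two unspecified steps
fixed here: variable genes are ranked by variance of log-CPM standardized
within 20 mean-expression bins, and outlier cells (first-two-PC radius
over 4× the median radius) are dropped once. Note the statistic measures
gene-gene correlation structure: compositional coupling through library
normalization contributes to it in count data, which is why the null
calibration uses an i.i.d. Gaussian cluster (the stated null) rather than
a negative-binomial one.

**Discreteness** counts, per cluster pair after subsampling to 80 cells,
genes with log₂ fold change of mean CPM ≥ 1 (pseudocount 1), expressed
proportion ≥ 0.5 in the target, and relative proportion difference ≥ 0.7 —
target-upregulated only. The source delegates this to an external scoring
package; the explicit three-condition rule makes the statistic
self-contained and testable, with all thresholds exposed. A note on
attainability: proportions like (0.9, 0.05) cannot arise from a 4-fold
shift of negative-binomial means alone — they require an on/off expression
pattern — so the generator gives marker genes a low off-state abundance
(`marker_off_cpm`) and the discreteness recovery test plants on/off
markers directly.

**Deep-type marker selection** binarizes each gene at its own 0.7
expression quantile (the "slightly relaxed" setting), forms the posterior
$\pi_c = x_c/\sum x_c$ over the three clusters from expressed fractions
$x_c$, and retains one-type markers ($\pi_{(1)} \ge 0.75$, $x_{(1)} \ge
0.3$) and two-type markers ($\pi_{(1)}+\pi_{(2)} \ge 0.9$, both $x \ge
0.3$, $\pi_{(3)} \le 0.2$). The 0.3 floor reflects that global
0.7-quantile binarization caps a two-of-three marker's per-cluster
expressed fraction near 0.45.

The expression generator: negative-binomial counts with gene-wise
dispersion (default 0.5), log-normal library sizes (µ = log 5e5,
σ = 0.3 — typical single-nucleus scale, unstated in the source),
cluster-specific marker fold change (default 4-fold; the design records
log₂ units), and an optional cluster whose designated gradient genes have
log₂ mean linear in scaled depth (default slope 2 per unit depth — a
strong but realistic laminar gradient). It emulates discrete types plus
one continuous gradient; it does not emulate dropout beyond NB sampling,
doublets, ambient contamination, or batch effects, so a green mapping test
establishes correctness of the mapping rule, not robustness to those
artefacts.

## The histology layer

Scaled depth is $-(d - d_{L1/2})/(d_{L3/4} - d_{L1/2})$: 0 at the L1/L2
border, −1 at L3/L4. Density profiles split L2–3 into 20 bins (cells on an
edge go to the deeper bin), normalize to per-donor fractions (sum exactly
1), and drop the first and last bins from the reported series (boundary
effects). The nadir finder takes the minimum of the 3-bin moving-average
mean profile restricted to depths below −0.25 (avoiding the L2 edge);
whether the published nadir came from a smoothed or raw profile is
unstated, so both the smoothing width and the search bound are arguments.
Monotone or flat profiles return a low-confidence flag instead of a
spurious minimum. The generator's defaults — nadir at −0.575, 2× density
at the L1/L2 border relative to the nadir with a mild deep-side rebound,
soma area growing ~2× from L2 to deep L3 — restate the qualitative
structure the profiling stage is meant to detect.

## Cross-modal statistics

- **Preprocessing**: cells missing more than 3 of the 18 ephys features
  are dropped; remaining gaps are imputed as the mean of the 5 nearest
  neighbours, with distances computed on the robust-scaled complete
  features only; features are centred on the median and scaled by IQR,
  with IQR = 0 mapping to scale 1 (constant features carry no information
  either way).
- **Robust inference**: all regression/ANOVA p-values come from Wald F
  tests with the HC3 heteroscedasticity-consistent covariance (reference
  distribution F(q, n−k)), assumed global across contexts; FDR control is
  Benjamini–Hochberg, verified in tests against a brute-force step-up
  implementation.
- **Mann–Whitney post hocs**: exact U distribution when both groups have
  ≤ 20 observations and no ties; otherwise the normal approximation with
  tie and continuity corrections.
- **Pathology comparison**: the feature is regressed on the low/high score
  bin with and without scaled depth as a covariate; both bin-coefficient
  p-values are reported so effects explained by imbalanced depth sampling
  are visible. Perfect bin–depth confounding is flagged unstable rather
  than reported.
- **Sparse PCA**: penalized power iteration with soft thresholding and
  projection deflation. The structure-preservation criterion — at most 8
  non-zero loadings per component while retaining ≥ 80 % of the
  unpenalized two-component variance — quantifies an otherwise qualitative
  instruction; when both constraints cannot hold, variance preservation
  wins. Loadings above 0.05 in absolute value are reported.
- **Classifiers**: stratified 70/30 splits (default 1000, reduced in
  tests), per-split train-set standardization, class-balanced accuracy
  (mean per-class recall), shuffled-label baseline from the same split
  machinery, confusion matrix from the first split. The logistic model is
  ridge-regularized multinomial regression (glmnet); the forest is a small
  bagged-CART with per-node random feature subsampling, written in-package
  because no random-forest package is available in the target environment.
  Where the published figure and methods disagree on the model (logistic
  vs 600-tree forest), both are implemented behind one interface with
  logistic as the default.

## Determinism and degenerate inputs

Every generator and every stochastic statistic takes an explicit seed and
is bit-reproducible for a fixed seed. Degenerate inputs return flagged
values rather than errors where the spec calls for it: no sweep near
−100 pA → missing sag; no spiking sweep → six missing firing features; a
degenerate cohort of identical histograms → all-zero PC scores; a flat
density profile → low-confidence nadir; zero-variance query cells →
unmapped with reason.

## Known limitations

- The LIF generator has no noisy/chirp stimuli, no conductance-based
  dynamics, and a stereotyped AP shape; AP-shape features therefore test
  the extraction geometry, not biological variation.
- The morphology generator produces stylized trees; morphometric recovery
  tests certify the measurement code, not reconstruction realism.
- The heterogeneity and discreteness statistics depend on the documented
  variable-gene, outlier and DE-threshold choices; alternative settings
  are exposed but not separately validated.
- Headline numbers from the motivating study (classifier accuracies on
  real cells, counts of depth-correlated features and genes, retained-gene
  fractions) depend on the real human dataset and are out of desk-scale
  reach; the acceptance suite is property-based plus formula-level
  targets instead.
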