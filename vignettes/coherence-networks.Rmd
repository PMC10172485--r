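---
title: "Coherence networks from multichannel EEG: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence networks from multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cohnet` turns multichannel scalp EEG into weighted functional networks and
relates their topology to clinical outcome. This vignette is the package's
methodological account: the estimators it implements, the assumptions they
rest on, the parameters that matter and their defaults, what the synthetic
cohort generator does and does not emulate, and the design decisions that
were genuinely open.

## The analysis in one paragraph

Each recording (21 channels of the 10-20 system, microvolts) is cleaned of
ocular artifacts by ICA plus discrete-wavelet thresholding, band-pass
filtered (0.1-45 Hz, zero phase), re-referenced to the common average, cut
into 3-s segments, and segments exceeding +-120 uV are discarded. For every
surviving segment a 21 x 21 adjacency matrix of band-averaged
magnitude-squared coherence is computed from Welch auto- and cross-spectra,
and per-segment matrices are averaged into one network per subject and
task. Four weighted graph properties summarize each network: clustering
coefficient (CLU), local efficiency (LE), global efficiency (GE) and
characteristic path length (L). Groups are compared property-wise
(normality-gated t or rank tests) and edge-wise (two-sample t per edge,
Benjamini-Hochberg FDR over the 210 unique edges). Finally, the per-patient
change in the properties across treatment predicts the PANSS change ratio
`(pre - post) / pre` in a leave-one-out cross-validated linear model gated
by collinearity diagnostics (VIF < 10, tolerance > 0.1).

## Coherence estimation

Magnitude-squared coherence between channels X and Y is

  C_XY(f) = |P_XY(f)|^2 / (P_XX(f) P_YY(f)),

with auto- and cross-spectra estimated by Welch's method. Within each 3-s
segment the defaults are 1-s Hann windows at 50% overlap, so M = 5 windows
per segment; the network edge is the unweighted mean of C_XY(f) over the
analysis band (default 1-45 Hz, broadband -- the band is configurable and
every output records the band used). Coherence per segment is computed
first and the matrices are then averaged, not the other way round.

Two estimator facts drive the numerical choices:

* **Single-window coherence is identically 1**, carrying no information;
  `coherence_matrix()` therefore refuses to run with fewer than 2 windows.
* **Under independence the estimator is biased upward by roughly 1/M.**
  With M = 5 the empirical floor is about 0.20 (the package's tests verify
  0.20 +- 0.03 over 200 independent-noise segments). Edge values must be
  read relative to this floor, and any change to window length or overlap
  changes it.

## Graph metrics

Networks stay fully weighted -- no thresholding or binarization, since none
is part of the modeled analysis. The edge length underlying path-based
metrics is `1/w` (strong coupling = short path; the `1 - w` alternative is
available via the `lengths` argument). With all weights in [0, 1] this
gives GE <= 1 and L >= 1, with equality exactly on the complete unit-weight
graph.

* **GE** is the mean inverse shortest-path length over ordered pairs.
* **L** is the mean shortest-path length; unreachable pairs are excluded
  from the mean with a warning, and a completely isolated node is an error.
* **CLU** is the Onnela geometric-mean form: node-wise
  `sum_{j,l} (w_ij w_il w_jl)^(1/3) / (k_i (k_i - 1))`.
* **LE** applies the same construction inside each node's neighbourhood,
  with shortest paths restricted to the subgraph that excludes the node.

**Clustering normalization was a genuinely open choice.** The generic
recipe for weights of arbitrary units divides by the graph's maximum
weight. For coherence that normalization is harmful in group comparisons:
coherence already lives on an absolute [0, 1] scale, and dividing by a
per-network maximum makes CLU blind to overall coupling strength -- worse,
strengthening a few edges *lowers* every other node's normalized
contribution, so a genuine local increase in coupling reads as a global
clustering decrease. `network_properties()` therefore computes CLU on raw
weights; `clustering_coefficient()` still offers `normalize = "graph_max"`
for cross-package comparability, and both conventions are verified against
brute-force oracles.

A related consequence worth knowing: on dense, fairly homogeneous
coherence networks the shortest path between two neighbours is usually the
direct edge, in which case raw-weight LE coincides exactly with raw-weight
CLU. The four properties are then heavily collinear -- which is precisely
why the prediction stage gates features through collinearity diagnostics
(below).

## Preprocessing

* **Filtering.** The band-pass is realized as a cascade of 4th-order
  Butterworth high-pass (0.1 Hz) and low-pass (45 Hz) stages, each applied
  forward-backward (`signal::filtfilt`) for zero phase. A single band-pass
  design of this order is numerically ill-conditioned at a normalized low
  edge of 2e-4 (0.1 Hz at 1000 Hz); the cascade is robust there and meets
  the same passband/stopband contract (10 Hz passes within 0.1%, 60 Hz is
  attenuated by more than 20 dB).
* **Ocular artifacts.** The recording is decomposed by FastICA (symmetric,
  tanh contrast, implemented in the package). Components are flagged as
  ocular when their time course correlates with the FP1/FP2 average beyond
  |r| > 0.7 or their kurtosis exceeds 10. Flagged components are wavelet
  processed: periodized db4 DWT to depth 8, per-level universal threshold
  `K = sqrt(2 log N) * sigma_hat` with the robust scale
  `sigma_hat = median(|w|) / 0.6745`, and every coefficient **above** K is
  set to zero. Note the direction: large coefficients are the blink
  transients, so suppressing them removes artifact energy while the
  sub-threshold background passes through -- the opposite of classical
  shrinkage denoising, and the behaviour the pipeline models. The cleaned
  components are remixed; unflagged components are untouched, so
  artifact-free recordings pass through essentially unchanged.
* **ICA convergence.** The classic fixed-point stopping rule cannot settle
  on data containing a Gaussian subspace, because the unmixing rotation
  within that subspace is unidentifiable (scalp EEG background is close to
  this situation, and the synthetic background is exactly it). The
  log-cosh contrast, however, is invariant to that rotation, so the
  implementation also accepts convergence when the objective has plateaued
  over 10 iterations; the identifiable, non-Gaussian components (blinks)
  are locked in well before that point. Non-convergence after three
  seeded restarts is a hard error.
* **Segmentation** is non-overlapping, trailing remainders are discarded,
  and rejection removes any segment containing a sample beyond the
  threshold (default +-120 uV).

## The synthetic cohort

No public recordings accompany the modeled study, so the package ships a
generator whose defaults are the study conditions: 21 patients recorded
before and after treatment, 24 controls, three cool-executive tasks
(Tower of Hanoi and both trail-making variants), 21-channel montage at
1000 Hz, 60-s recordings.

* **Background signal**: 1/f-shaped noise plus an alpha-band (10 Hz) bump,
  10 uV RMS. All sources share this spectral shape so that mixed channels
  have frequency-flat coherence and band averages are interpretable.
* **Coupling**: every channel carries a global shared source (background
  coherence, default target 0.2); the six medial fronto-parietal
  electrodes FPz, Fz, Cz, Pz, P3, P4 -- a scalp proxy for default-mode
  connectivity -- additionally share a second source in the pre-treatment
  patient condition, raising all 15 pairwise coherences among them by the
  configured effect (default +0.3, a fixture choice: the modeled study
  reports no quantitative effect size). Post-treatment recordings
  attenuate the planted effect fully by default, matching the reported
  absence of treated-vs-control differences.
* **Calibration**: the mapping from mixing gain to *measured* band
  coherence has no closed form once windowing bias enters, so it is
  calibrated numerically -- the generator measures a gain grid with the
  package's own coherence estimator and inverts the monotone map
  (tolerance about +-0.02, verified +-0.05 on planted edges in tests).
* **Artifacts**: blinks arrive as a Poisson process (default 12/min),
  0.35-s raised-sine deflections, 150 uV at the frontal pole decaying
  posteriorly.
* **Clinical tables**: PANSS pre-treatment totals are drawn near 75 +- 14
  (30-210 scale), and each patient's change ratio follows
  `r = a + b * dL + noise` with the printed-model coefficients
  `a = 0.197`, `b = -2.081` as defaults, where `dL` is a latent
  per-subject change in characteristic path length drawn around -0.017
  (+-0.02) -- chosen once so the implied group-mean change ratio matches
  the printed group means (about 0.233). Behavioral measures use lognormal
  reaction times and Poisson error counts with group/phase shifts in the
  reported directions; Tower-of-Hanoi step counts never fall below the
  3-disk minimum of 7.

**What the generator does not emulate** -- and hence what passing tests do
not show about real data: no volume conduction or head-model mixing beyond
the shared-source construction, no event-related structure, no muscle or
cardiac artifacts, no non-stationarity, and (deliberately) Gaussian
backgrounds, which are kinder to coherence estimation than real EEG. The
EEG recordings carry a uniform group-level treatment effect, while the
clinical outcome couples to the *latent* per-subject `dL`; subject-level
coupling between measured networks and outcome is therefore not part of
the synthetic truth, and parameter-recovery tests use the latent features.

One wrinkle inherited from the modeled analysis deserves a note: its
printed prediction model has a negative coefficient on the change in L,
while its group results report L *shorter* before treatment (so the change
across treatment should be positive and improvements should shrink the
ratio). The generator keeps the printed coefficients and a small negative
mean `dL`, which reproduces the printed group-mean change ratio; the
printed model form is treated as a recovery target for the regression
machinery, not as a physiological claim.

## Statistics

Two-sample comparisons are gated by Shapiro-Wilk (both samples, or the
paired differences, at 0.05): normal data get the t family, otherwise
Mann-Whitney U (reported as `min(U1, U2)`, the scale of printed tables) or
the Wilcoxon signed-rank test. Within the independent t family the pooled
statistic is used when the variance-ratio F test is non-significant at
0.05, otherwise Welch -- this gate reproduces the printed behavioral t
values (pooled for the Tower task, Welch for both trail-making tasks).
`two_sample_t()` accepts group summaries directly so printed tables can be
re-tested without raw data. Edge-wise comparisons run one independent t
per unique edge with BH-FDR across the 210 edges of a single contrast (the
family is per task and contrast, not pooled). All tests are two-sided.

## Prediction

Change features are `after - before` per property, averaged over the three
tasks by default (a per-task mode exists but yields 12 predictors at
n = 21 and warns accordingly). Because the four properties are nearly --
sometimes exactly -- collinear on dense coherence networks, the pipeline
first applies the conventional collinearity gate (drop the worst VIF until
all VIF < 10 and tolerance > 0.1), which typically leaves a single change
feature; the final model is refit on all subjects after leave-one-out
evaluation. RMSE is reported both in outcome units and in percentage
points of the change-ratio scale.

A caution the tests make explicit: the leave-one-out predicted-vs-actual
Pearson correlation is *negatively biased under the null* (about -0.3 at
n = 21 with one noise predictor; exactly -1 for an intercept-only model),
because each held-out prediction tracks the mean of the remaining
outcomes. Null-model baselines for this statistic must therefore be
simulated, not assumed to be zero.

## Problem sizes used in tests

The test suite and the reproduction script run the full study design
(n = 21 + 24, three contrasts, 210-edge FDR families) but shorten the
recordings: most EEG-based checks use 12-24 s at 128 Hz, which preserves
the estimator geometry (3-s segments, five 1-s Welch windows) while
keeping the suite fast. Operating characteristics use 100-200 cohort
replicates; the end-to-end demo uses 8 + 8 subjects at 24 s. The graph
metrics are verified to 1e-10 against independent Floyd-Warshall and
triple-loop oracles on 100 random graphs, and the complete unit-weight
21-node graph yields exactly (1, 1, 1, 1).

## Known limitations

* Coherence conflates genuine coupling with volume conduction; the
  21-electrode restriction mitigates but does not remove this, and no
  phase-based alternatives (imaginary coherence, wPLI) are implemented.
* A single broadband band is analysed per run; band-specific networks
  require separate runs.
* The edge-length convention `1/w` diverges as weights approach 0; fully
  weighted dense networks keep this benign, but near-zero edges in other
  data would dominate path lengths.
* EDF input/output is not provided; recordings are exchanged as delimited
  text with a JSON sidecar.
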