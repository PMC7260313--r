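---
title: "Microstate and visibility-graph network analysis of interictal EEG"
author: "eegmicronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate and visibility-graph network analysis of interictal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmicronet)
```

## The problem

Psychogenic non-epileptic seizures (PNES) resemble epileptic seizures but
occur without epileptiform discharges, so between events the EEG of the two
patient groups looks superficially similar. Discriminating the groups from
*short, discharge-free* EEG would spare patients long video-EEG monitoring.
`eegmicronet` implements the three feature families that have been proposed
for this discrimination — per-channel signal descriptors, functional
networks built from horizontal-visibility-graph synchronization, and EEG
microstate temporal statistics — together with a synthetic EEG generator
and a patient-wise cross-validation harness, so the whole chain can be
exercised and verified without access to clinical recordings.

The package's working geometry is a 27-electrode 10–20 montage sampled at
256 Hz, analyzed in 16-s epochs ("subjects"), with 5 patients per
diagnostic group contributing 10 epochs each. Epochs are conditioned to
1–40 Hz and decomposed into delta (1–4), theta (4–8), alpha (9–13), beta
(14–30) and gamma (30–40 Hz) sub-bands; the 8–9 and 13–14 Hz gaps in this
table are deliberate and preserved.

## The synthetic generator

The generator is the package's study-condition definition, not a
convenience fixture. Each band among delta/theta/alpha/beta carries a
planted microstate process: a small set of fixed, zero-mean, unit-norm
scalp topographies (4 for delta/theta, 3 for alpha/beta; pairwise
$|r|\le 0.7$) alternates according to a semi-Markov label sequence and is
multiplied by a band-limited noise carrier. The summed band signals are
superposed with per-channel pink ($1/f$) noise — the shape of resting EEG
background — at a configurable per-channel amplitude ratio
$\mathrm{snr} = \mathrm{RMS(signal)}/\mathrm{RMS(noise)}$ (default 5).
Gamma carries background only, which is why microstate analysis is
restricted to the four lower bands.

**Label process.** Microstate durations are geometric with an 80-ms mean
(about 20.5 samples at 256 Hz) — memoryless, so the mean-run-length oracle
is exact — and the chain never self-transitions. Exact long-run coverage
under a no-self-transition chain requires solving the per-state entry
weights $w_i$ jointly with per-state mean durations: the stationary entry
share of state $i$ is proportional to $w_i(1-w_i)$, so target shares
$\pi^*_i \propto \sqrt{c_i}$ (an even split of a coverage difference
between entry rate and duration) are inverted through
$w_i(1-w_i) = \gamma \pi^*_i$, $\sum_i w_i = 1$, and the durations absorb
the remainder as $m_i = m\, c_i / \hat\pi_i$. No state can be entered more
than half the time in such a chain, so entry shares are capped at 0.45 and
shrunk toward uniform when the target coverage is too skewed; coverage
stays exact because the durations compensate.

**Group difference.** The `coverage_shift` parameter moves the second
group's beta-band coverage toward its first template. Because coverage is
the product of occurrence and duration, a pure-coverage manipulation does
not exist; the $\sqrt{\cdot}$ split above makes coverage the single most
informative temporal statistic while occurrence and duration each carry
half the (log-scale) effect. A small per-patient log-normal coverage jitter
(sd 0.02) gives every patient an individual fingerprint, which is what
makes the patient-wise split genuinely stricter than a subject-wise one.

What the generator does *not* emulate: volume conduction and electrode
geometry (templates are random vectors, not dipolar fields), eye-blink/EMG
artifacts, non-stationary background, and line noise. Passing tests
therefore certify the algorithmic chain, not robustness to the full messiness
of clinical data.

## Preprocessing

Broadband conditioning is a zero-phase Butterworth cascade: order-4
high-pass at 1 Hz followed by order-6 low-pass at 40 Hz, each applied
forward and backward. The cascade is numerically better conditioned than a
single wide band-pass of equivalent order (a transfer-function band-pass of
order 8 at this bandwidth is unstable in double precision) and attenuates a
50 Hz mains line below 5% RMS. Band decomposition uses zero-phase order-4
Butterworth band-passes at the canonical edges — simple, with a verifiable
frequency response; the band semantics are what matters downstream.

A consequence worth knowing: with 80-ms states, the ring time of a
14–30 Hz band-pass is comparable to a state's duration, so band-filtering a
switching topographic signal converts a substantial share of samples near
segment boundaries into two-template mixtures. The package's recovery tests
therefore feed the microstate stage the generator's natively band-limited
output; the filter-induced smearing is a property of preprocessing, shared
by any implementation, and not of the segmentation machinery.

## Per-channel signal features

Seven descriptors per channel and band: signal energy $E=\sum_i x_i^2$;
Shannon and Rényi ($\alpha = 2$) entropies of the amplitude histogram
(64 equal-width bins over the observed per-channel range — the bin count is
a parameter); normalized spectral entropy over the band's frequency range,
computed per 1-s periodogram window and averaged over the 16 windows of an
epoch, so a pure tone gives $\approx 0$ and a flat spectrum $\approx 1$;
and three fractal dimensions. The box-counting dimension rescales the
signal graph to the unit square and fits $\log N(\varepsilon)$ against
$\log 1/\varepsilon$ on dyadic grids $\varepsilon = 2^{-j}$,
$j = 2,\dots,\lfloor\log_2 n\rfloor-2$, clipping to $[1,2]$. The Higuchi
dimension fits the log–log slope of the normalized curve lengths $L(k)$,
$k \le K_{\max} = 20$. The Katz dimension uses the waveform convention
$L=\sum_i |\Delta x_i|$, $d=\max_i |x_i - x_1|$,
$\mathrm{KFD} = \log_{10} n / (\log_{10}(d/L) + \log_{10} n)$, which is
exactly amplitude-invariant and equals 1 for a monotone line; the
planar-curve alternative (unit time steps inside the distances) was
rejected because on 4096-sample series it degenerates into a measure of
amplitude scale. Amplitudes of synthetic data are arbitrary units, so
every feature except energy is scale-free by construction or by
normalization; energy is retained as the one deliberately
amplitude-carrying descriptor.

## Visibility-graph functional networks

Each channel is mapped to its horizontal visibility graph: samples are
nodes, and two samples see each other iff every strictly intermediate
sample lies strictly below both (ties block, per the strict inequality).
The per-node degrees in time order form a degree sequence, and pairwise
synchronization is the lagged cross-correlation of the standardized degree
sequences, $C_{xy}(h) = \frac{1}{N-h}\sum_t z_x(t+h)\,z_y(t)$, maximized
in magnitude over $|h| \le$ 125 ms (32 samples; the physiological scale of
cortico-cortical delays, configurable) with the signed value retained and
clipped into $[-1,1]$ (the $1/(N-h)$ estimator can marginally exceed 1 on
short overlaps). Standardization is what makes the $\pm 1$ interpretation
of the coefficient meaningful. Ties across lags resolve toward lag 0, then
positive lag.

From the symmetric weight matrix (unit diagonal) the package computes:
Onnela-style weighted clustering
$c_i = \frac{1}{d_i(d_i-1)}\sum_{j\ne k}(\tilde w_{ij}\tilde w_{jk}
\tilde w_{ki})^{1/3}$ with $\tilde w = |w|/\max|w|$; node strength (signed
off-diagonal row sums); betweenness centrality with edge lengths $1/|w|$
(strong correlation = short path, the standard convention for correlation
networks); and the leading eigenpair of the absolute-weight adjacency
(diagonal zeroed — self-correlation carries no edge), whose eigenvector is
the Perron centrality. Negative weights enter all path/triangle/eigen
measures through their absolute value; the signed matrix is preserved in
outputs. Every measure is checked against exhaustive brute-force
enumeration on small graphs.

## Microstate analysis

The global field power $\mathrm{GFP}(t)$ is the across-channel population
standard deviation. Topographies at GFP local maxima (minimum peak
distance 20 ms; up to 500 per epoch, highest peaks first) are pooled over
all subjects per band and clustered with the polarity-invariant modified
K-means: maps are assigned to the prototype maximizing squared spatial
correlation, and each prototype is updated as the dominant eigenvector of
its cluster's scatter matrix; 20 random restarts, best by explained
variance, empty clusters re-seeded from the worst-fitted map.

The number of classes $K$ is chosen by the cross-validation criterion
$\mathrm{CV} = \hat\sigma^2\left(\frac{C-1}{C-K-1}\right)^2$ with
$\hat\sigma^2 = \frac{\sum_n \mathbf{x}_n^\top\mathbf{x}_n -
(\mathbf{a}_{l_n}^\top\mathbf{x}_n)^2}{N(C-1)}$. The residual sum runs over
*all* EEG time samples, not only the clustered peak maps: evaluated on peak
maps alone the criterion keeps decreasing with $K$ on structured data and
selects no interior optimum, while over all samples the noise floor
flattens the residual beyond the true $K$ and the planted $K=3$ is
recovered (verified at snr 10). The conventional choice (3 maps for
alpha/beta, 4 for delta/theta) can be pinned to bypass selection. Global
explained variance is reported as the GFP²-weighted mean squared spatial
correlation — the standard definition, stated here because the measure has
no single canonical printed form.

Back-fitting labels every sample with the prototype of minimal global map
dissimilarity $\mathrm{GMD} = \|\mathbf{x}/\mathrm{GFP}_x -
\mathbf{y}/\mathrm{GFP}_y\|/\sqrt{C}$, equivalently maximal $|r|$ — so
labeling is polarity- and amplitude-invariant (0 = same shape, 2 =
opposite polarity). A peaks-only mode (labels assigned at GFP peaks and
spread to the surrounding troughs) is available; all-samples is the
default because the segmentations it produces are what the temporal
statistics are defined on.

**Small-segment rejection.** Segments shorter than 30 ms are dissolved one
at a time, shortest first: each sample of the rejected segment is
relabeled to the GMD-nearest class *among the adjacent segments' classes*,
and the run-length table is recomputed after every dissolution. Two design
points matter. Restricting candidates to the neighboring classes is what
makes rejection a *merge*: a global "next-best class" rule oscillates
between two classes on fragmented stretches and measurably destroys
correct labels. Recomputing runs after each dissolution is equally
essential — with a stale run table, fragments of a long run are dissolved
into classes their neighbors no longer hold. With both in place, 30-ms
smoothing raises planted-label accuracy under noise (the acceptance script
reports the measured gain at snr 2) and converges without hitting its
iteration cap. At high snr smoothing slightly *lowers* raw label accuracy,
because a geometric duration distribution places a few percent of time in
genuine sub-30-ms states that rejection, by definition, erases; this is
the documented cost of enforcing a minimum duration, not an implementation
artifact.

Per class, the temporal statistics are occurrence (segments per second),
duration (mean segment length, ms) and coverage (fraction of samples);
coverage sums to 1 and occurrence × duration ≈ coverage up to
epoch-boundary effects.

## Evaluation protocol

Classification is patient-paired: every (epilepsy, PNES) patient pair in
turn is the test set (all of both patients' epochs) and the remaining
patients train — 25 folds at the default 5+5 geometry, enumerated
exhaustively rather than sampled, which is deterministic and equivalent in
expectation. Features are z-scored with training-fold statistics only.
The battery covers kNN (k = 5), linear and RBF SVM, a decision tree,
random forest (100 trees) and gradient boosting (50 rounds, depth 3);
hyperparameters are pinned in the run manifest. Epilepsy is the positive
class for precision/recall; specificity is computed on PNES. Reported
metrics are means over folds; AUC comes from the package's own
threshold-sweep ROC, cross-checked in the tests against the rank-statistic
(Mann–Whitney) identity and an established ROC implementation.

Band and feature importance use leave-one-out re-runs: remove one band's
(or one temporal family's) columns and re-evaluate. Random forest is the
designated classifier for these tables: the three temporal families are
algebraically redundant (coverage ≈ occurrence × duration), so single-family
removals produce small drops whose ordering a nearest-neighbour classifier
scrambles, while impurity-based trees rank the precise, low-variance
coverage estimates consistently.

## Verification design and problem sizes

The test-suite and acceptance script run, from scratch: HVG equivalence
with an $O(n^2)$ scan on 100 series of 200 samples; graph measures against
exhaustive enumeration on 200 random weighted graphs of up to 7 nodes;
the closed-form feature values; the microstate algebra identities; planted
recovery on beta-only data (template correlation ≥ 0.95 at snr 10,
CV-selected $K = 3$ over $K\in\{2..6\}$ on 2×2 patients × 5 epochs,
noiseless back-fit ≥ 95%, smoothing gain at snr 2); and the full
classification chain at the default 5+5×10 geometry — chance-level
accuracy (binomial 95% band around 0.5) for `coverage_shift = 0`, AUC ≥
0.9 for beta-coverage features at `coverage_shift = 0.2`, and the beta /
coverage leave-one-out orderings at that shift. The planted shift of 0.2
is chosen mid-range deliberately: at saturating shifts every feature
subset classifies perfectly and importance orderings degenerate to ties.
Determinism is checked by re-running an experiment from one manifest and
comparing output bytes.

## Known limitations

* Band-pass smearing bounds attainable back-fit accuracy on filtered data
  with 80-ms states; near-perfect label recovery is only possible on
  natively band-limited signals.
* Geometric durations put substantial mass below any realistic smoothing
  threshold; real microstate duration distributions are more peaked, so
  the smoothing cost measured here is an upper bound.
* The EDF writer/reader covers the plain 16-bit EDF layout (one sampling
  rate, no annotations); it is a data-exchange convenience, not a full
  implementation of the format family.
* Synthetic amplitudes are arbitrary units; only relative and scale-free
  quantities are meaningful across runs.
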