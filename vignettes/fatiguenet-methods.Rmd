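---
title: "Frequency-banded brain-network analysis of mental fatigue: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-banded brain-network analysis of mental fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguenet)
```

# The analysis in one paragraph

`fatiguenet` turns multichannel fNIRS hemoglobin recordings into
fatigue-state assessments in six steps. (1) Each channel's oxy-, deoxy-
and total-hemoglobin series is decomposed into five physiological
frequency bands (I: 0.005–0.021, II: 0.021–0.052, III: 0.052–0.145,
IV: 0.145–0.600, V: 0.6–2.0 Hz) with a zero-phase Chebyshev Type I
band-pass filter. (2) Channels are fused into eight cortical regions of
interest (ROIs) by entropy weighting. (3) Pearson correlations between
ROI series define, per band and species, an 8-node weighted
functional-connectivity network, characterised by its clustering
coefficient $C$, characteristic path length $L$, and small-worldness
$\sigma = \gamma/\lambda$ with $\gamma = C/C_{random}$ and
$\lambda = L/L_{random}$ against 100 matched random networks. (4) MFI-20
questionnaire scores and n-back behavioural scores label each session as
non-fatigue (L1), moderate (L2) or severe fatigue (L3) via a k-means
split and a threshold scan. (5) Two-way ANOVA (level × task) with
partial $\eta^2$ and Tukey–Kramer post-hocs locates band-specific group
differences. (6) A random forest with Gini-importance feature selection
and genetic-algorithm tuning classifies fatigue states from a
2,250-dimensional feature vector under nested fivefold cross-validation.
A synthetic-data generator stands in for the original recordings, so the
whole pipeline is testable without any download.

# Signal model and preprocessing

## The Chebyshev band-pass filter

The band decomposition uses a Chebyshev Type I design of order 4 with
0.5 dB passband ripple, applied forward and backward so the net phase is
zero (`bandpass()`). Only the filter family is fixed by the analysis
convention; order and ripple are exposed as arguments.

Two numerical choices deserve comment:

* **Second-order sections.** At 16 Hz sampling, band I spans
  0.0006–0.0026 of the Nyquist range. In expanded transfer-function form
  the eight poles of the band-pass design are so close to $z = 1$ that
  double-precision polynomial deflation fails — filtering white noise
  through the textbook recursion overflows to $10^{200}$. The design is
  therefore kept in zero-pole-gain form and realised as a cascade of
  biquad sections (`cheby1_bandpass_sos()`), the standard remedy; the
  forward pass matches an independent SOS implementation to $10^{-14}$.
* **Edge transients.** Zero-phase filtering uses odd-symmetric reflection
  padding of three periods of the band's low edge (capped at the signal
  length). With band-I impulse responses lasting minutes, *some* edge
  convention is unavoidable; measurements on sinusoids (passband gain
  0.92, stopband leakage 0.002 in band II) are taken over the central
  half of the record, and tests do the same.

## Entropy-weighted ROI aggregation

Each ROI's channels are combined as $y = \sum_j X_{ij}\,\omega_j$. The
weights derive from information entropy: each filtered channel is
min–max rescaled, normalised to a probability distribution over time
points, and scored by its normalised Shannon entropy $e_j$; weights are
proportional to the divergence $1 - e_j$, so channels with more
structure (lower entropy) count more. Three conventions make this
well-defined on real signals:

* min–max rescaling first, because band-passed hemoglobin values are
  negative half the time and the raw $p_{ij} = x_{ij}/\sum_i x_{ij}$
  transform is meaningless for signed data;
* a constant channel maps to the uniform distribution ($e = 1$, weight
  0), and if *every* channel in an ROI is constant the weights fall back
  to uniform;
* weights are computed per band on the filtered submatrix, following the
  order of operations of the analysis (filter first, then ROI
  aggregation). Weights are a probability vector, so the ROI series is a
  convex combination and lies inside its channels' pointwise envelope.

# Network construction and graph metrics

Connectivity is the Pearson correlation between ROI series. Graph
analysis uses $w = |r|$ with a zero diagonal: negative correlations
carry connectivity information of equal magnitude, and the signed $r$ is
preserved separately for the classifier features. Node clustering is the
geometric-mean triangle intensity with max-normalised weights
$\hat w = w/\max(w)$:

$$C_u = \frac{1}{\deg(u)(\deg(u)-1)}
  \sum_{v,w}\left(\hat w_{uv}\hat w_{uw}\hat w_{vw}\right)^{1/3},$$

averaged over nodes for the network coefficient. Path lengths take each
edge's length as $1/w$ and average Dijkstra shortest paths over ordered
pairs. Binarization at sparsity $s$ keeps the $k = \mathrm{round}(s
\cdot n(n-1)/2)$ strongest edges — exactly 13 of 28 at the default
$s = 0.45$ — with lexicographic tie-breaking so every network in a study
has the same edge count deterministically.

## Matched random networks and small-worldness

"Matched" nulls are built by Maslov–Sneppen double-edge swaps
($10\times$ the edge count of attempts) followed, in weighted mode, by a
random permutation of the original weight multiset over the rewired
edges. Node count, edge count, degree sequence and weight multiset are
preserved exactly; replicate-level invariants are asserted in the test
suite. On graphs too dense to swap the nulls reduce to weight
permutation and the result carries a `swap_fallback` flag.

**Both weighted and unweighted small-worldness are computed on the
sparsity-thresholded network** (weighted mode keeps the surviving edges'
weights; `sparsity = NULL` restores full-matrix behaviour). This is a
deliberate design decision with a mathematical reason behind it. A
correlation-based network is complete, and on a complete topology
degree-preserving rewiring cannot change anything, leaving weight
permutation as the only null. But the Onnela triangle sum is *exactly*
permutation-invariant in the log domain (each edge sits in $n-2$
triangles, so $\sum_{\triangle}\log(\hat w_1\hat w_2\hat w_3)^{1/3} =
2\sum_e \log\hat w_e$), which pins $\gamma$ to $\approx 1$, while
clustered weight arrangements can only lengthen shortest paths relative
to scattered ones, pinning $\lambda \ge 1$. Hence $\sigma \lesssim 1$
*for any coupling structure whatsoever* — we verified this empirically
across block-modular, graded, core–periphery and extreme-clique
structures. Small-world organisation of a full correlation network is
simply not measurable against a permutation null; on the thresholded
support, where rewiring genuinely randomises topology, it is. At the
default sparsity the 13-edge graphs are occasionally disconnected; $L$
is then averaged over reachable pairs and flagged, rather than failing,
since the flag concerns individual null replicates of an 8-node graph.

# The synthetic-data generator

The generator emulates the *structure the analysis assumes*, not the
physics of the instrument: band-limited latent oscillations with
controllable inter-ROI coupling per band, three correlated hemoglobin
species, channel noise, and fatigue-dependent questionnaire and
behavioural scores.

## Signals

Per band, eight white-noise series are band-pass filtered, standardised,
mixed with the symmetric square root of the target correlation matrix,
and re-standardised; the per-band latents are scaled by 1/f-like
amplitudes (1.0, 0.9, 0.7, 0.5, 0.4 from band I to V) and summed. Mixing
filtered noise rather than sinusoids keeps the within-band spectrum flat
and the sample correlation full-rank. Each band's latent is synthesised
with a 10% guard trimmed from both band edges: the five analysis bands
share edges, and a flat-spectrum signal otherwise places full power at
the shared edge, where the analysis filter's transition band leaks it
into the neighbouring band and destroys the controllability of per-band
coupling (real hemodynamic spectra roll off within bands, so the guard
also improves realism). Channels copy their ROI latent plus Gaussian
noise (sd 0.3); HbR is $-\kappa$ times the HbO latent plus independent
band-structured signal ($\kappa = 0.5$, relative amplitude 0.4); HbT is
exactly HbO + HbR, total hemoglobin's definition.

The default coupling is modular: a frontal/attention community (three
prefrontal ROIs plus both frontal eye fields) and a motor community
(supplementary motor area plus both premotor ROIs), with within-module
correlations 0.5–0.65 and between-module 0.15–0.25, declining with
frequency. Fatigue levels modify the off-diagonal coupling
multiplicatively, mirroring the qualitative directions reported for
fatigued cohorts: moderate fatigue raises band-II coupling (×1.10, and
×1.20 extra on right-hemisphere pairs, producing the right-greater-left
asymmetry), and lowers band-III coupling (×0.75); severe fatigue lowers
band III (×0.70) and band IV (×0.70) while band II stays elevated. The
magnitudes are invented generator parameters; only the directions mirror
published findings.

## Questionnaire and behaviour

MFI-20 items are drawn around per-level centers 1.7 / 2.8 / 3.4 (L1 /
L2 / L3) with between-participant spread 0.18 and item spread 0.6,
clipped to integers 1..5. The centers and spreads encode the geometry
that makes score-based labelling meaningful: the dominant gap sits
between non-fatigue and fatigue (so a 2-means split lands there), and
the moderate band is narrow, consistent with fatigue-threshold
conventions on the 1–5 scale. n-back trials draw reaction times around
per-level means 0.55 / 0.65 / 0.80 s (accuracy 0.95 / 0.88 / 0.78), with
a within-level coupling of 0.15 s per MFI point so behaviour tracks the
latent severity continuously, as it does across levels — without this,
behaviour would be piecewise constant in severity, an artifact of the
discrete level labels rather than a property of fatigue.

## Determinism

Every cell of a study derives its seed by hashing the master seed with
the participant/task/level tags (`derive_seed()`), so enlarging a study
or generating only a subset of species reproduces the existing sessions
bit-for-bit. All stochastic stages (k-means restarts, null networks,
forest fits, GA) consume seeds derived the same way.

## What the generator does *not* emulate

Hemodynamic response shapes, motion artifacts, optode-distance physics,
systemic physiology (Mayer waves aside from their band), non-stationary
coupling, or missing data. Passing tests therefore demonstrate that the
*pipeline* recovers structure it is pointed at under realistic noise —
not that any specific neurophysiological effect exists in real
recordings.

# Labelling

The session score is the mean of the 20 oriented MFI items. The
non-fatigue threshold is found by 1-D k-means (k = 2, 20 restarts): the
minimum score of the upper cluster, so "score below threshold" is
non-fatigue. The severe threshold scans candidates in 0.01 steps up to
5.00, splitting fatigue sessions at each candidate and scoring the split
by the Welch test between the groups' behaviour scores
(reaction time of correct trials ÷ accuracy). Three robustness choices:

* the split is scored by $-\log_{10} p$ rather than raw $|t|$, because
  the Welch degrees of freedom then discount near-edge splits where a
  handful of sessions can have arbitrarily small variance;
* all candidates between two adjacent observed scores induce the same
  partition, so the maximising candidates form a plateau; the plateau
  *midpoint* is returned (the left end would bias the threshold low by
  the inter-score gap);
* `label_fatigue()` requires each group to hold at least 10% of the
  fatigue sessions (minimum 3), keeping borderline sessions that
  straddle the k-means threshold from anchoring degenerate splits.

Under the default design the recovered severe threshold is unbiased to
within ±0.1 of the generative L2/L3 midpoint (20-seed mean), with
per-seed scatter of ±0.2 reflecting argmax noise at 72 fatigue sessions;
label agreement with the generator's ground truth averages ~0.89, with
confusions only ever between adjacent levels — the ~9% overlap of the
L2/L3 score distributions is irreducible at these spreads.

# Group statistics

`two_way_anova()` fits fixed effects with interaction using
sum-to-zero coding and Type III sums of squares (the convention of the
mainstream statistics packages for unbalanced factorial designs — and
score-based labelling always produces unbalanced cells), reporting
partial $\eta^2 = SS_{effect}/(SS_{effect}+SS_{error})$.
Tukey–Kramer post-hocs use the unequal-$n$ standard error
$\sqrt{(MSE/2)(1/n_i+1/n_j)}$ with studentized-range p-values, applied
to fatigue levels only where the level main effect is significant
(α = 0.05) and the interaction is not — the standard reporting rule for
crossed designs. No multiple-testing correction is applied across the 28
connectivity pairs, matching common practice in this literature;
`p.adjust` can be applied downstream by users who want it. Type-I error
calibration on null simulations is asserted at 3–7% in the tests.

# Classification

The 2,250 features per session concatenate, for each of the 15
(species × band) pairs: 28 signed ROI-pair correlations, the weighted
network's $(L, C)$, and 15 time-domain features per ROI series (mean,
population sd, coefficient of variation, energy, range, biased Fisher
skewness and excess kurtosis, peak, Hjorth mobility, 64-bin histogram
entropy, RMS, and the kurtosis/waveform/pulse/margin factors of the
condition-monitoring literature). "Hjorth parameter" is implemented as
mobility: activity duplicates the variance feature and adding complexity
would make 16 features instead of the advertised 15. Degenerate ratios
on constant signals return 0, never `NaN`, so tree models see no missing
values.

Classification is a random forest. Feature selection (Gini importance
ranking, top 50), hyperparameter tuning (a small real-coded genetic
algorithm — tournament selection, uniform crossover, per-gene mutation,
one elite — maximising inner 3-fold CV accuracy over tree count,
feature-subsample fraction and minimum node size) and the final fit all
run *inside* each outer fold of a stratified fivefold cross-validation.
The nesting is not negotiable: selecting features on the full data
before cross-validating leaks labels, and the test suite contains an
explicit leakage check with a feature crafted to be informative only in
the held-out fold. Reported metrics are pooled over outer folds;
positive classes are *fatigue* and *severe* respectively.

# Problem sizes and runtimes

The default design simulates 12 sessions per (task × level) cell — 108
sessions, mirroring a 36-participant cohort tested three times — of
600 s at 16 Hz. The test suite scales some Monte-Carlo checks to keep a
full run inside a coffee break: the classification benchmark runs ten
studies of 300 s sessions (band III and above are unaffected; band I/II
estimates are noisier, which only makes the benchmark harder), and the
parameter-recovery checks generate questionnaire/behaviour data without
signals where signals are irrelevant. The acceptance script computes
weighted small-worldness for 10 sessions × 5 bands × 100 nulls in about
a minute.

# Known limitations

* Sample correlations of narrow-band signals carry few effective
  degrees of freedom (≈ $2 \cdot BW \cdot T$); at 600 s, band-I
  estimates have an effective n of ~20, and session-level network
  metrics in the slow bands are accordingly noisy. This is a property of
  the analysis design itself, not of the implementation.
* The max-normalised clustering coefficient is sensitive to the single
  strongest edge of each network; group contrasts on $C$ therefore need
  cohort-scale samples, as reflected in the power checks.
* Small-worldness of *full* correlation networks against permutation
  nulls is degenerate (see above); results with `sparsity = NULL` should
  not be interpreted as evidence for or against small-world topology.
* The GA is a small heuristic search; with the default budgets it
  reliably avoids bad hyperparameter corners rather than locating global
  optima, which is all nested tuning needs here.
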