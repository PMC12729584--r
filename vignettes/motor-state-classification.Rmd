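---
title: "Constructed digital biomarkers for ON/OFF motor-state classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructed digital biomarkers for ON/OFF motor-state classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gefc)
```

## The modelling problem

A levodopa-treated Parkinson's patient alternates between a practical
OFF state (medication worn off) and an ON state (medication effective).
The motor signature of that alternation — resting tremor in the 4–6 Hz
band, bradykinetic slowing of repetitive movement, loss of movement
smoothness — is measurable with a glove-mounted inertial unit sampled
at 100 Hz during short standardised exercises. `gefc` treats the
problem as binary classification of 1-second analysis windows pooled
across patients, with three methodological stages: a fixed multi-domain
feature bank, a composite feature-ranking scheme, and
grammatical-evolution (GE) construction of a handful of symbolic
features that a small radial-basis-function (RBF) network can separate.

The package assumes recordings are artifact-free and uniformly sampled;
it performs no resampling, filtering or artifact rejection.

## Signal features

All descriptors are computed on the per-sample magnitude
$d_t = \sqrt{x_t^2 + y_t^2 + z_t^2}$ of each sensor, which removes
orientation dependence at the cost of rectifying oscillations around
the gravity offset. Windows are 100 samples (1 s) with a 50-sample hop;
trailing partial windows are discarded and windows are never padded.
The bank has 29 entries per sensor (87 columns for the three sensors):

* *statistical* (12): mean, median, standard deviation, variance, min,
  max, range, skewness, kurtosis, IQR, quartile deviation
  $(Q_3-Q_1)/2$, and coefficient of variation $\sigma/|\mu|$;
* *energy* (4): signal magnitude area (mean absolute value), RMS,
  total energy $\sum v^2$, and logarithmic energy
  $\sum \log(v^2 + 10^{-12})$;
* *spectral* (8): dominant frequency, flatness, flux, variability,
  normalised entropy, centroid, spread, 85% roll-off;
* *nonlinear* (5): mean absolute deviation, RMSSD, Higuchi fractal
  dimension, largest Lyapunov exponent, sample entropy.

Numerical conventions, chosen once and documented here because the
field uses several dialects:

* The spectrum is the one-sided periodogram of the mean-removed window
  with a rectangular taper; the DC bin is excluded everywhere, so the
  dominant frequency is never 0 Hz by construction. A window with
  numerically zero spectral power returns 0 for every spectral
  descriptor except flux.
* Spectral flux is the Euclidean distance between the raw power
  spectra of consecutive windows of the same sensor stream; the first
  window's flux is 0. Spectral variability is the standard deviation
  of the normalised spectrum.
* Skewness and kurtosis use population (biased) moments, kurtosis is
  excess kurtosis, and both return the sentinel 0 on constant windows,
  as does the coefficient of variation when $|\mu| < 10^{-12}$.
* Sample entropy uses template length $m = 2$, tolerance
  $r = 0.2\,\mathrm{sd}$, Chebyshev distance, self-matches excluded,
  with templates restricted to the first $n - m$ starts at both
  lengths; when no matches exist at either length the sentinel is 0
  (the logarithm would be undefined).
* The Higuchi fractal dimension uses $k_{\max} = 10$ and the
  least-squares slope of $\log L(k)$ against $\log(1/k)$; a straight
  line scores ≈ 1 and a constant window returns 0.
* The Lyapunov exponent follows the Rosenstein construction with
  embedding dimension 2, delay 1, a Theiler window of 1 and a
  divergence fit over the first 10 steps, in units of 1/sample; 100
  sample windows are too short for heavier estimators. Degenerate
  windows return 0.

All descriptors are finite on any finite window after sentinel
handling; this is asserted property-style in the test suite.

## Composite feature scoring

Three views of each feature are combined:

* **Statistical significance.** A t-test between OFF and ON values
  mapped through $-\log_{10}(p + \varepsilon)$ with
  $\varepsilon = 10^{-10}$. The constant sits *inside* the logarithm:
  that realises its purpose of guarding a p-value of zero, capping the
  score at exactly 10. When patient identifiers are available the test
  is paired on per-patient means — windows are not one-to-one across
  states, so the patient is the natural pairing unit — otherwise the
  package falls back to Welch's unpaired test with a logged warning.
* **Model-based importance.** Mean decrease in Gini impurity over a
  200-tree random forest (unlimited depth, $\sqrt{p}$ candidate
  features per split), deterministic given the scoring seed. The
  importance is left unnormalised: it is defined as an average over
  trees, not a unit-sum vector.
* **Variance contribution.** Columns are standardised and the score is
  the sum of absolute correlation loadings (eigenvector entries scaled
  by component standard deviations) across *all* components with
  eigenvalue above $10^{-12}$; truncating the component set would
  silently reweight features. Zero-variance columns score 0.

Each raw score vector is min-max normalised independently (a constant
vector maps to all zeros rather than NaN) and combined as
$0.4\,\mathrm{ttest} + 0.3\,\mathrm{RF} + 0.3\,\mathrm{PCA}$. Ranks
break ties by ascending feature name so orderings are reproducible.
The best $\max(1, \lfloor 0.8\,n \rfloor)$ features are retained.

## Grammatical evolution

The expression grammar over retained features $x_1 \ldots x_d$ is

```
<expr>     ::= ( <expr> <op> <expr> ) | <func> ( <expr> ) | <terminal>
<op>       ::= + | - | * | /
<func>     ::= sin | cos | exp | log
<terminal> ::= <xlist> | <const>
<xlist>    ::= x1 | ... | xd
<const>    ::= <digit> . <digit>
<digit>    ::= 0 | ... | 9
```

Mapping is the classic leftmost derivation: each nonterminal consumes
the next codon $V$ and selects rule $V \bmod NR$. Design points that
the derivation tables of the GE literature leave open:

* **Wrapping.** Fixed-length random chromosomes need a policy for
  codon exhaustion; the mapper wraps to the start of the stream up to
  2 times per expression and marks the mapping invalid beyond that.
* **Constants.** Decimal literals are built from two digit
  nonterminals (`3.7`); a grammar flag removes the constant branch for
  work with variables only.
* **Guarded evaluation.** Division by $|b| < 10^{-100}$, logarithms of
  non-positive arguments and magnitudes above $10^{100}$ are guarded at
  evaluation time rather than excluded by the grammar; invalid
  evaluations are penalised downstream, the usual GE practice.

Serialised expressions parse back to structurally identical trees; the
round trip is property-tested over a thousand random chromosomes.

## Feature construction

A generational GA over integer chromosomes (100 codons, values 0–255)
evolves the mapped feature sets. Per generation the population is
sorted by fitness, the best $(1 - p_s)N_c$ survive unchanged, and
$p_s N_c$ offspring are bred by size-4 tournament selection, one-point
crossover (cut uniform in $[1, L-1]$) and per-codon uniform-redraw
mutation. Defaults follow the package's reference configuration:
$N_g = 500$ generations, $N_c = 500$ chromosomes, selection rate 0.10,
mutation rate 0.05.

The fitness of a chromosome is the training sum of squared errors
$\sum_j (C(\hat{x}_j) - t_j)^2$ of an RBF network $C$ on the
transformed patterns. The RBF head uses seeded k-means centers, widths
equal to the mean member-to-center distance (floored at $10^{-6}$),
Gaussian units and ridge-stabilised ($10^{-8}$) least-squares output
weights — training is a single linear solve, which is what makes the
inner loop affordable. Open choices and their resolutions:

* The $N_f$ expressions are mapped *sequentially from one codon
  stream* (expression $i+1$ resumes where $i$ stopped). The
  alternative — splitting the chromosome into equal segments — caps
  every expression's size a priori and was rejected.
* The node count of the fitness network is 10, mirroring the 10
  processing nodes used by the evaluation networks.
* The penalty fitness for invalid chromosomes is finite ($10^{100}$)
  so that sorting remains total.
* Elitism makes the best-ever fitness non-increasing; this is asserted
  on every run.

## Evaluation protocol

Stratified k-fold cross-validation (default 10 folds, 30 repeats,
repeat-indexed seeds) with classification error in percent, macro
precision/recall over both classes (a zero-denominator class
contributes 0), and threshold-sweep ROC/PR curves with trapezoid areas.
Fold assignment deals each class's shuffled windows round-robin with a
counter continuing across classes, so fold sizes differ by at most one
both overall and per class. For constructed-feature methods the whole
GE search runs inside each training fold and the held-out fold is only
transformed — no leakage. An optional patient-grouped mode keeps all of
a patient's windows in one fold; window-level stratification is the
default because pooled-window evaluation is the common protocol, but
the grouped mode exists precisely because pooled windows are optimistic
when patients dominate the variance.

The constructed features are classified by the same RBF head used in
the fitness (rather than a GA-trained neural network): comparing
`method_fc()` against `method_rbf()` then isolates the effect of the
representation, which is the question of interest. GA-trained and
PCA+BFGS MLP baselines (`method_gen_mlp()`, `method_pca_mlp()`, 10
sigmoid hidden nodes, GA genes in $[-10, 10]$, prediction threshold
0.5) are provided for reference.

## The synthetic cohort

Because glove recordings of real patients are not distributable, the
simulator generates cohorts with the statistical structure the
analysis targets (defaults: 14 patients, both states, four exercises):

* a tremor sinusoid at a patient-specific frequency drawn from
  4–6 Hz, with OFF amplitude 1.0 vs ON amplitude 0.4 (arbitrary sensor
  units) and phase/amplitude jitter 0.3 vs 0.1;
* high-frequency "jerk roughness" (first-difference noise scaled by
  jitter × amplitude) feeding the gyroscope strongly and the
  accelerometer weakly — this is the component the regularity
  descriptors detect;
* task components: slow postural drift (exercise 1) and periodic
  Gaussian tap bursts at 1.5 Hz OFF vs 2.5 Hz ON (exercises 2–3,
  bradykinetic slowing);
* gravity offset on the accelerometer, differentiated oscillation on
  the gyroscope, slow drift with attenuated tremor on the
  magnetometer (deliberately the least informative sensor), white
  sensor noise of SD 0.05, and a bounded random per-session rotation
  (≤ 0.6 rad) coupling the axes — a worn glove wobbles around a
  task-imposed posture rather than taking a uniformly random attitude,
  and an unbounded rotation can null the tremor's projection onto the
  magnitude signal entirely;
* per-patient random effects: log-normal amplitude scale
  (sdlog 0.45, roughly 0.4×–2.5×) and a personal roughness multiplier
  in [0.6, 1.6] applied to both states. These are essential: with only
  mild inter-subject variability the cohort is linearly separable on
  absolute amplitude and even a raw-feature RBF is nearly perfect,
  which is not the regime the method addresses. With realistic
  overlap, absolute amplitude features are patient-confounded and the
  medication contrast must be found in relative and regularity
  structure — which is exactly what the constructed features recover.

Session durations default to 10/13/16/12 s for exercises 0–3, chosen
so a 14-patient cohort yields a few hundred windows per class per
exercise (266/350/434/322), the scale at which the method is meant to
operate. What the simulator does **not** emulate: biomechanically
realistic hand kinematics, sensor calibration error, dropped samples,
artifacts, dyskinesia, or within-session medication dynamics. Passing
tests on synthetic cohorts therefore demonstrate the pipeline's
correctness and its qualitative orderings, not clinical performance.

## Reproducibility and problem sizes

Every stage draws its seed deterministically from one pipeline seed,
and seeded subroutines (k-means, the random forest) run under a
save/restore RNG discipline, so identical configurations reproduce all
artifacts byte for byte — this is asserted in the test suite by
comparing files from two full runs.

The package's own checks run the GA at reduced budgets (30–50
generations, 50–100 chromosomes) and a single cross-validation repeat
on the default cohort; those sizes are where the qualitative behaviour
(elitism, determinism, the constructed-features-vs-raw-RBF ordering
with a margin above five percentage points) is already stable, while
the full default budgets remain available for real analyses.

## Known limitations

* The paired t-test aggregates to per-patient means before pairing;
  window-level pairing is undefined when states have unequal window
  counts.
* Gini importance dilutes credit among strongly correlated features —
  visible in the feature bank, where dispersion measures share
  importance; the composite's PCA and t-test branches compensate only
  partly.
* The Lyapunov and fractal estimators on 100-sample windows are rough
  descriptors, not dynamical-systems-grade estimates; they are used as
  discriminative features, nothing more.
* `exp`-heavy expressions saturate the evaluation guards quickly; the
  GA routes around them via the penalty, but grammars with bounded
  operators would search more efficiently.
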