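---
title: "Co-activation pattern dynamics: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activation pattern dynamics: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdyn)
```

## The model

Resting-state BOLD activity visits a small repertoire of recurring whole-brain
configurations. Co-activation pattern (CAP) analysis treats every fMRI frame
(one TR of parcellated, z-scored data) as a point in parcel space and clusters
the pooled frames of all subjects and sessions with k-means under correlation
distance,

$$d(x, c) = 1 - \mathrm{cor}(x, c),$$

so that frames with the same *shape* of activation — regardless of amplitude —
fall in the same cluster. The cluster centroids are the brain states; the
per-frame cluster labels turn every session into a categorical state sequence
$s_1, \dots, s_T$. Three summaries of that sequence are analysed:

* **Fraction of time (FT)** — the share of frames spent in each state,
  $\mathrm{FT}(k) = \#\{t : s_t = k\}/T$. FT vectors sum to 1.
* **Mean dwell time (MDT)** — the average length, in TRs, of maximal
  uninterrupted runs of a state. Unvisited states are *missing*, not zero.
* **Transition probability (TP)** — estimated on the sequence after
  consecutive duplicates are removed (to control for the autocorrelation
  induced by state persistence): $\mathrm{TP}(A, B)$ is the number of
  $A \to B$ steps over the number of occurrences of $A$ with a successor.
  The diagonal is structurally zero after collapsing. The collapsed sequence
  is a Markov jump chain; its analytic prediction for a chain with transition
  matrix $P$ is $P_{ij}/(1 - P_{ii})$, which the test suite uses as an oracle.

## Choosing the number of states

k-means is run for each $k$ in a scan range (default 2–15, configurable
upward). Each solution is scored by a cluster validity index (CVI): the mean
correlation distance from each frame to its own centroid divided by the mean
distance to all other centroids — a within/between ratio where lower is
better. The literature this follows cites the ratio verbally without a
formula; this frame-based reading was chosen because it is computable from a
single fitted model and decreases smoothly in $k$, which the elbow fit needs.
The elbow itself is found by least squares: every two-segment piecewise-linear
model with a breakpoint at an interior $k$ is fitted, and the breakpoint with
the smallest total residual sum of squares is selected, ties toward smaller
$k$. If the best two-segment fit improves on a single line by less than 1% of
its RSS the curve is declared effectively straight and the smallest $k$ is returned
with a warning flag. The raw CVI values are fitted (not a normalized curve);
on our synthetic curves the choice is immaterial because the breakpoint
minimiser is invariant to affine rescaling of the y axis. Mean silhouette per
cluster (correlation distance, singletons scored 0) is available as an
alternative criterion; on large pools it is computed on a seeded subsample
because it is quadratic in frames.

## Numerical choices in the clustering

Frames are standardized to zero mean and unit L2 norm across parcels before
distance computations; then $1 - \mathrm{cor}$ is half a squared Euclidean
distance and Lloyd iteration with mean-then-restandardize centroid updates
(spherical k-means) is monotone in the objective, which is asserted
per-iteration in tests. Centroid updates are the arithmetic mean of member
frames; the *reported* centroids are means of the raw z-scored frames, so
their units remain interpretable z-scores. Each fit uses k-means++-style
seeding; 100 replicates (default, matching common practice for this analysis)
are run and the lowest-objective replicate kept; scans use fewer replicates
per $k$ (default 10) since only the score curve is needed, and the accepted
model is always refitted at full replicates. Empty clusters are re-seeded
from the frame farthest from its centroid. Assignment ties break toward the
lowest state id. All replicate seeds derive deterministically from one base
seed, so every result is reproducible from a single integer.

States are reported in a canonical order obtained by correlating each
centroid with binary network-membership indicators from the parcel table
(visual, somatomotor, default-mode, limbic/ventral default-mode, salience,
central executive), so "state 5" always means the salience-like state in
reports regardless of arbitrary cluster numbering.

## The statistical layer

Longitudinal treatment effects use classical paired t-tests per state; FT and
MDT each form a Bonferroni family of $K$ tests (threshold $0.05/6 = 0.0083$
at $K = 6$). TP is tested only for transitions *into* states that showed a
significant FT or MDT effect, from every other state: with 2 selected states
among 6 that family has $2 \times 5 = 10$ tests (threshold $0.005$). Reported
p-values are always unadjusted; significance flags carry the family
threshold. Brain–behaviour associations are Pearson correlations between
changes in significant CAP metrics and percent change in mood scores,
$(\mathrm{post} - \mathrm{baseline})/\mathrm{post}$ — the literal published
definition, kept even though it is asymmetric (a zero post score propagates
as missing). Cross-sectional follow-ups "controlling for age and sex" are
implemented as OLS models (metric ~ group + age + sex) reporting the group
coefficient's t on $n - 4$ df; the published phrase describes a non-standard
single test, and the ANCOVA reading is the standard interpretation. A
residualize-then-t option is exposed for sensitivity. Demographic contrasts
from printed summaries use Welch's t (reproducing the published age contrast
t = 3.70) and 2×2 Pearson chi-squares without continuity correction
(reproducing 12.851 / 1.427 / 2.055 from counts implied by printed
percentages, which imply a control n of 55).

## What the synthetic cohort emulates — and what it does not

The generator stands in for restricted clinical imaging data. It plants:

* Six spatial states built on the parcel table's networks (unit-variance
  z-score patterns, weight 1.5 on the generating network, light Gaussian
  texture elsewhere; the visual state carries a secondary dorsal-attention
  loading). Pairwise pattern correlations stay below 0.8 by construction.
* Markov switching dynamics per group. Controls use a uniform six-state
  chain with self-transition 0.75 (stationary occupancy 1/6 ≈ 0.167; at a
  0.8-s TR that is a mean dwell of ~3.2 s, in the range reported for CAP
  analyses). The depressed-baseline chain was calibrated analytically, before
  any test was run, to a stationary occupancy of +0.05 for the salience state
  and −0.05 for the central executive state, with collapsed transition
  probabilities SN→VN of 0.277 (vs 0.2) and SN→CEN of 0.149 (vs 0.2). The
  post-treatment chain lies 70% of the way back toward the control chain, so
  treatment moves metrics toward control values without reaching them.
  Effect *magnitudes* are calibration choices: the source analyses report
  only t statistics, not effect sizes.
* Per-subject heterogeneity as Dirichlet jitter of transition rows
  (concentration 400, i.e. entry-level sd ≈ 0.02), plus the binomial
  sampling noise of finite sessions (2 × 250 frames by default).
* Cohort structure: 58 treated subjects scanned twice, 56 controls, 18 of
  them rescanned with *unchanged* parameters; ages 40.7 ± 11.3 vs
  32.61 ± 12; folded-normal framewise displacement (mean 0.15 mm, sd
  0.17 mm) independent of the state sequence, so motion cannot drive
  clustering.
* A brain–behaviour coupling: percent change in reflective rumination is
  regressed on each subject's *realized* change in salience-state occupancy
  with a residual sized to hit r = −0.402 in expectation, making downstream
  recovery a genuine estimation problem rather than a bookkeeping identity.
* Parcel noise: i.i.d. Gaussian with sd 1 on unit-variance patterns, giving
  frame-to-centroid correlations around 0.7 — cleaner than real BOLD frames.
  An AR(1) option exists (default off) but real spatial noise correlations,
  hemodynamics, and preprocessing artifacts are *not* modelled.

A green test therefore establishes that the pipeline recovers what was
planted under idealized noise at desk scale; it does not establish
sensitivity at real-data noise levels, nor anything about preprocessing.

## Other conventions and degenerate inputs

* Z-scoring is per parcel *within each run* by default (runs are separate
  acquisitions; this removes run-level offsets before pooling). Whether the
  original analysis standardized per run or per concatenated session is not
  stated; a session-level option is exposed. Constant parcels error by
  default, with an opt-in zero-fill policy.
* Motion QC retains sessions with mean FD strictly below 0.5 mm (the
  inclusion criterion is "less than"), and exclusion escalates to all of a
  subject's sessions. No frame-level censoring is performed — only
  subject-level mean-FD assessment is described for this analysis.
* No dwell or transition ever spans a run boundary, and each run's chain
  restarts from the initial distribution; whether the original analysis
  bridged its two runs is unknown, and separate-acquisition semantics are
  the conservative choice. The row-stochastic TP denominator (occurrences
  with a successor) is the default because the metrics are explicitly given
  a Markov interpretation; the literal all-occurrences denominator is
  available as `mode = "literal"`.
* Transition rows of states never left (or never visited) are missing, and
  MDT of unvisited states is missing; statistics drop missing values
  pairwise.
* Cluster matching between centroid sets (e.g. subgroup vs pooled
  clustering) maximizes total pairwise correlation by exhaustive permutation
  search up to k = 8 (exact in the regime used), greedy beyond; no
  linear-assignment solver is assumed.
* The chi-square for the published sex comparison (0.035) is not
  reproducible from the printed counts under either the plain or
  continuity-corrected convention and is not used as a check.

## Known limitations

Silhouettes on subsamples are approximate; the CVI formula is one defensible
reading of a verbally-specified index; the elbow is sensitive to the scan
range on curves without a sharp bend (the ambiguity flag reports this); and
the synthetic cohort's noise model is deliberately simple. The pipeline
targets desk-scale cohorts (tens of subjects, hundreds of frames per run) on
one CPU; the only quadratic-in-frames step (silhouette) is subsampled.
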