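---
title: "Automated speech-artefact removal with EMG mutual information: models and methods"
author: "micica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated speech-artefact removal with EMG mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micica)
```

## The problem

Vocal speech produces large myogenic artefacts in MEG: the facial muscles,
jaw and tongue generate broadband electrical activity (roughly 0–200 Hz,
peaking near 100 Hz) whose magnetic fields dominate the planar gradiometers
over the frontotemporal rim of the helmet. Because the artefact spectrum
overlaps the neural one, filtering cannot remove it, and manual selection of
artefactual independent components is slow and observer-dependent.

`micica` automates the component selection. The recording protocol adds a
short *facial gesture task* — ten cued gestures, each preferentially
activating one speech muscle, performed in randomized order and repeated in
blocks — and four facial surface-EMG channels recorded alongside the MEG.
The pipeline is:

1. **ICA decomposition** of the gradiometer data (FastICA, log-cosh
   contrast, symmetric decorrelation) after PCA pre-whitening that retains
   the smallest number of components explaining 99.99% of the variance.
2. **Mutual information**: for every independent component $s_i$ and every
   principal component $y_j$ of the task-restricted EMG, estimate
   $I(s_i; y_j)$ with the Kraskov–Stögbauer–Grassberger k-nearest-neighbour
   estimator ($k = 3$) and normalize it to the *MI correlation coefficient*
   $$\rho_I(s_i;y_j) = 1 - \exp\{-2\, I(s_i;y_j)\} \in [0, 1).$$
3. **Selection by clustering**: order components by their per-component MI
   sum $\sum_j \rho_I(s_i; y_j)$, cluster with k-means ($k = 5$, confirmed
   by the elbow curve over $k = 2\ldots20$), and elect every member of the
   cluster with the highest mean MI sum for removal.
4. **Evaluation**: project the elected components out; compare original and
   cleaned evoked responses (0–1500 ms windows) with per-gradiometer-pair
   RMSD maps and sensor-level cluster-based permutation tests.

Two variants differ only in the ICA training data: **N** fits the ICA on the
picture-naming paradigm alone, **GN** on the concatenated gesture + naming
timeline. MI rows always come from the facial-gesture and vocal-naming tasks
only; silent-naming and observation samples are never used for selection.

Why mutual information rather than correlation? An artefactual component is
an independent high-frequency process whose *amplitude envelope* follows the
muscle activation; its waveform is not the EMG waveform, so the linear
correlation can be near zero while the statistical dependence is strong. MI
captures exactly this envelope-mediated dependence.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `varThreshold` | 0.9999 | cumulative explained variance retained by pre-whitening |
| `kNn` | 3 | neighbours of the KSG MI estimator |
| `kClusters` | 5 | k-means clusters for component election |
| `maxMiSamples` | 20000 | per-task sample cap (seeded uniform subsampling) for MI |
| `nPerm` | 1000 | permutations of the sensor-level cluster test |
| `alphaSensor` | 0.001 | cluster significance level, sensor space |
| `clusterAlpha` | 0.05 | two-sided cluster-forming threshold |
| `epochWindow` | 0–1.5 s | evoked / test window relative to picture onset |
| `targetSfreq` | 200 Hz | analysis sampling rate |

All of these are the method's standard settings; every run log echoes the
fully resolved configuration, and the pipeline is bitwise reproducible given
one top-level seed (every stochastic stage draws from a named substream of
it).

## The MI estimator

`knnMi()` implements KSG algorithm 1:
$I = \psi(k) + \psi(n) - \langle \psi(n_x + 1) + \psi(n_y + 1)\rangle$, with
Chebyshev-ball neighbour counts and strict inequalities. Two numerical
choices matter:

* **Tie breaking.** Exact ties break the neighbour-count logic, so both
  inputs receive a seeded jitter of relative magnitude $10^{-9}$ before
  estimation. On discrete data this makes the estimator consistent for the
  discrete MI (verified against the exact plug-in estimate in the tests).
* **Rank-to-normal transform.** MI is invariant under strictly monotone
  marginal maps, and the estimator behaves best when both marginals are
  well-spread; inputs are rank-transformed to normal scores by default
  (`rankNormal = TRUE`). A useful side effect is *exact* invariance of the
  estimate under monotone transforms of the inputs.

Negative estimates (possible for nearly independent inputs) are clipped to
zero before Eq. of $\rho_I$ is applied. The coefficient is implemented
exactly as $1-\exp(-2I)$; the textbook *information correlation coefficient*
$\sqrt{1-\exp(-2I)}$ is available via `sqrtCompat = TRUE` — the two are
strictly monotone transforms of one another, so the component election is
identical either way.

For tractability the per-task series are capped at `maxMiSamples = 20000`
samples by seeded uniform subsampling; one MI value is computed per
(task, EMG-PC, IC) triple over the concatenated task-restricted samples.
This is the simplest reading consistent with the method's printed matrix
sizes (8 rows × components for GN, 4 for N).

## The clustering feature space

The election rule is "all components of the cluster with the highest MI
sum". What k-means should cluster is genuinely open: the scalar MI sums, or
the full per-component MI row vectors. `micica` clusters the **scalar MI
sum** by default. The reason is geometric: the non-artefactual components
form a dense, low-MI set, while a family of artefactual components shares
*high* MI but couples to the four EMG channels with somewhat different
profiles. In the vector space, k-means prefers splitting that (mutually more
distant) artefact family into singletons before it subdivides the tight
non-artefact cloud — which breaks the "highest-MI-sum cluster" election
whenever more than one artefact source is present. On the scalar ordering
the artefact family coheres and the election reproduces the printed rule.
The vector variant remains available (`features = "profile"`) as a
diagnostic. Election ties break towards the higher maximum MI sum, then the
lower cluster id; k-means uses the best of 10 seeded starts.

A selection is flagged rather than silently trusted when the elected cluster
holds more than a quarter of all components (`oversize`; in practice a
removal of more than a handful of components signals failure), when the
features cannot support `kClusters` distinct clusters (`degenerate`), or
when the weakest elected member does not exceed the strongest remaining
component by at least 1.5× (`lowContrast` — on artefact-free data the
elected cluster is merely the top of the ordinary-component continuum).
`confidentSelection()` returns the empty set in all flagged cases.

## The synthetic generator

Human MEG of this kind cannot be shared, so the package ships a generator
that reproduces the *structure* of the experiment and plants ground-truth
artefacts, making the whole pipeline testable end to end.

* **Schedulers** are exact to the sample: the gesture paradigm (sets ×
  gestures × repetitions at 3.2 s cues; the full-size defaults are 5 sets of
  160 s) and the naming paradigm (3 runs × 6 task blocks in three
  predetermined pseudorandom orders; 500 ms stimulus, 2500 ms response,
  1000 ms fixation for naming, 1500 ms observation; 110 pictures per task at
  full size, in blocks of 18–19).
* **EMG**: each gesture or vocal trial triggers a burst of 20–95 Hz
  band-limited noise under a smooth envelope spanning the response period,
  scaled by a per-(driver, channel) gain matrix in which each gesture
  preferentially drives the channel over its target muscle, with realistic
  overlap; vocal speech engages all four channels. Silent-naming and
  observation trials trigger nothing beyond the low-amplitude baseline.
* **MEG**: an exactly linear mixture. Artefact sources are independent
  60–95 Hz noise carriers amplitude-modulated by the (largely common)
  envelope of the EMG channels, with topographies focused on the left and
  right frontotemporal edge of the layout. They deliberately do *not*
  resemble the EMG waveform — only its envelope — because that is the regime
  the MI selection assumes. Per-source heavy-tailedness of the carriers
  (Student-t marginals of decreasing df) models muscle groups firing with
  different burstiness and is what makes the shared-envelope mixture
  ICA-identifiable. Neural sources combine 1/f-like background,
  stimulus-locked transients (in every task, including silent naming), and
  movement-locked power modulation of the ongoing activity (ERD/ERS-like)
  with depths spanning a broad range — so non-artefactual components carry a
  realistic continuum of moderate EMG dependence. White sensor noise is
  added on top.

The desk-scale defaults — 10 gradiometer pairs + 4 EMG channels at 200 Hz,
2 gesture sets × 2 repetitions, 4 pictures per naming block, 3 planted
artefact sources, artefact gain 6 : neural 1 : noise 0.3 — keep a full
pipeline run under a minute while preserving every structural property;
`fullSize = TRUE` restores the 102-pair layout and printed paradigm sizes.
Trial-level timing always equals the full protocol. The `lowsnr` scenario
scales the speech artefact during the naming runs down to 0.15 while leaving
gesture bursts intact — the regime in which adding the gesture paradigm to
the ICA (variant GN) is expected to, and does, outperform naming-only
selection. The `null` scenario plants no artefacts and should (and does)
yield only flagged, non-confident selections.

What the generator does **not** emulate: biophysical forward models (the
topographies are layout-space Gaussian foci, not leadfields), ocular/cardiac
artefacts (assumed pre-cleaned), head movement, sensor drift, and
inter-subject variability. Passing tests therefore demonstrate the
*selection logic* under the method's own assumptions, not performance on
arbitrary raw recordings.

## Numerical choices

* **Time indexing** is 0-based with half-open epoch windows
  $[t_\min, t_\max)$, so an epoch holds exactly
  `round((tmax - tmin) * sfreq)` samples.
* **Downsampling** applies a zero-phase FIR low-pass at 0.9× the target
  Nyquist before decimation. Zero phase is obtained by group-delay
  compensation of the linear-phase filter (a forward–backward pass would
  double the attenuation at the band edge). Event onsets rescale with
  round-half-to-even.
* **Run seams** are explicit (`runStarts`); epochs and MI windows never
  straddle a concatenation boundary.
* **ICA**: log-cosh contrast, symmetric decorrelation, seeded random
  orthogonal initialisation. The fixed-point iterations run on a seeded
  subsample of at most 20 000 time points (ample for the component counts
  involved); whitening and all source projections use every sample. The
  pipeline caps iterations at 300: the artefactual components stabilise
  within tens of iterations, and the residual update drift lives in the
  near-Gaussian noise subspace, which the selection does not depend on. The
  convergence flag is reported honestly and a non-convergent model is
  returned with a warning, never silently re-seeded.
* **EMG PCA** keeps one component per channel (no truncation, matching the
  4-per-task row counts) and is a rotation only; whitening the EMG PCs would
  not change the selection because the MI is invariant to monotone marginal
  maps.
* **Evoked evaluation** follows the printed order literally: epoch →
  average → pair-RMS ($\sqrt{(a^2+b^2)/2}$, so a pair of equal channels
  returns that amplitude) → whole-head-maximum normalization → RMSD. The
  order matters: pair combination does not commute with averaging (a
  regression test documents this).
* **Cluster permutation test**: pointwise t statistics thresholded at the
  two-sided $t$ quantile for `clusterAlpha`, spatio-temporal clusters of
  equal sign under layout adjacency × temporal contiguity, cluster mass =
  summed t, null = maximum |mass| over permutations, and
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$ so p
  never reaches zero. The evaluation uses the *independent-samples* design
  between original and cleaned scaled epochs: on rectified (pair-combined)
  data a paired design would flag any removal as a trivially systematic
  amplitude decrease, while the group-level comparison detects genuine
  power differences — present in the vocal task, absent in silent naming.
  Both designs are available in `clusterPermutationTest()`. The test runs
  across epochs within one dataset (the multi-subject sensor-level variant
  is out of scope).
* **Baseline correction** of epochs is off by default (available via the
  `baseline` argument of `extractEpochs()`); the evaluation windows start at
  the stimulus onset.

## Known limitations

* The selection quality flags are heuristics; a flagged selection needs
  inspection, and an unflagged one is not a guarantee on real data.
* With few planted artefact sources and few components, the k-means
  geometry is less forgiving than with ~70 components at full scale; the
  scalar-sum feature space is the robust choice in both regimes.
* FastICA separates the shared-envelope artefact family only because the
  sources differ in their amplitude statistics; a physically identical pair
  of sources would be returned as an arbitrary rotation of its subspace
  (a limitation of ICA itself, not of the selection).
* The permutation test's epoch-level design answers a slightly different
  question from a group-level (across-subject) test.
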