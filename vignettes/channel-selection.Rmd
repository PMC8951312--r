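---
title: "Wrapper-based EEG channel selection with a hybrid FPA / beta-hill climbing search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper-based EEG channel selection with a hybrid FPA / beta-hill climbing search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

EEG-based biometric identification asks whether a person can be recognized
from the electrical activity recorded on their scalp. Full montages carry
64 or more electrodes, but placing them is slow and uncomfortable, and many
channels contribute noise rather than identity information. Channel
selection treats the montage as a combinatorial search space: find the 0/1
mask over channels whose signals suffice — or are best — for identifying
the subject.

`eegselect` implements a *wrapper* formulation of this search. Candidate
masks are scored by the validation accuracy of a classifier trained on the
masked features, and a binary metaheuristic explores the mask space. The
search itself is a Flower Pollination Algorithm (FPA) hybridized with
beta-hill climbing (beta-hc) local refinement, with a sigmoid transfer
function converting the continuous pollination moves into channel masks.

## The pipeline

Each recording passes through four stages:

1. **Segmentation and denoising.** Recordings are cut into consecutive
   10 s windows (at most six per recording; partial trailing windows are
   discarded rather than padded, because padding distorts autocovariance
   estimates at the boundary). Each window is notch-filtered and
   band-passed, both zero-phase (forward-backward) Butterworth designs.
   The mains frequency (60 Hz), notch width (Q = 30) and pass band
   (0.5–50 Hz, order 4) are package defaults — standard values for scalp
   EEG — and are configurable; nothing downstream depends on them beyond
   ordinary denoising.

2. **Per-channel features.** Either Yule–Walker autoregressive
   coefficients of order 5, 10 or 20 (`AR5`/`AR10`/`AR20`), fitted by
   solving the autocovariance equations (`stats::ar.yw`), or discrete
   wavelet sub-band statistics (`WT`): a 4-level Daubechies-4 periodized
   decomposition with energy, mean absolute value and standard deviation
   per sub-band. The wavelet family, depth and statistics are
   implementation choices (the canonical EEG defaults); the decomposition
   is verified in the test suite against an independent reference
   implementation. Feature vectors of a recording's segments are averaged
   element-wise, giving one row per recording — this is the
   "electrode-mean" aggregation that reduces within-subject dispersion; a
   per-segment layout is available via `aggregate_segments = FALSE`.
   The resulting matrix has one contiguous column block per channel, so a
   channel mask selects whole blocks.

3. **The wrapper objective.** Rows are split 50 % / 30 % / 20 % into
   training, validation and test sets, stratified by subject and
   deterministic given a seed. For a candidate mask, features are
   restricted to the selected blocks, standardized with training-set
   statistics only, and a classifier (RBF-SVM by default, with
   `C = 1e11`, `gamma = 0.01`) is trained on the training rows and scored
   on the validation rows. That validation accuracy, in percent, is the
   fitness the optimizers maximize; it is memoized per mask, and the
   distinct-evaluation count is the budget currency for optimizer
   comparisons. The final figure of merit retrains on the training set
   with the best mask and scores the untouched test set once.

   Metrics are aggregated from one-vs-rest confusion counts summed over
   subjects: `TA` (true acceptances = correctly identified samples), `TR`,
   `FA`, `FR`. With `C` subjects and `tp` of `n` correct, these counts are
   `TA = tp`, `FA = FR = n − tp`, `TR = (C−2)n + tp`; sensitivity and
   F-score both reduce to `tp/n` under this aggregation and specificity is
   close to 1 — the familiar signature of micro-averaged identification
   metrics. The reported accuracy is the sample-level identification rate
   `100·tp/n`: summing Eq.-style accept/reject counts *per decision* gives
   exactly this value, whereas plugging the summed one-vs-rest counts into
   the same ratio would inflate accuracy toward 100 % as the subject count
   grows and would break the sanity property that label shuffling drives
   accuracy to chance (`100/C` %). The package therefore reports the
   identification rate and documents the counts separately.

4. **The search.** Three optimizers share one interface and one budget
   accounting:

   * `fpa_optimize` — binary FPA. Each of `N` pollens holds a real vector
     (initialized U(−1, 1)). With probability `p = 0.8` it moves by
     *global pollination*, a Lévy-flight step toward the global best
     (`sol + L ⊙ (gbest − sol)`, `L` from the Mantegna construction with
     exponent 1.5); otherwise by *local pollination*
     (`sol + ε·(sol_j − sol_k)`, scalar `ε ~ U(0,1)`, `j, k` drawn from the
     population). The moved vector is binarized: bit `i` is 1 with
     probability `sigmoid(x_i)`, and an empty mask is repaired by switching
     on one random channel.
   * `bhc_optimize` — standalone beta-hc: candidate = one uniformly chosen
     bit flipped (N-operator), then each bit independently reset to a
     random value with probability `beta = 0.5` (beta-operator); accepted
     iff not worse. Run for an `N·T` evaluation budget.
   * `fpa_bhc_optimize` — the hybrid: every pollination result is refined
     by an inner beta-hc loop before it replaces the pollen. The pollen's
     real vector keeps the pollination result; only the binary solution is
     overwritten by the refinement, following the printed procedure.

## Design choices that were genuinely open

* **Binarization convention.** The two printed formulations of the
  transfer rule are opposite ("1 if `u > σ`" vs "1 if `σ > u`"); the
  package uses `1 iff sigmoid(x) > u`, the only direction in which a large
  positive component means *select with high probability*.
* **Lévy step scale.** The step multiplier is a free parameter here. With
  a small multiplier (e.g. 0.01) the real vectors never leave the
  neighbourhood of the origin, every sigmoid stays near 0.5, and the
  binary search degenerates to coin-flipping — empirically no better than
  random search. The package therefore applies the Mantegna step unscaled
  (`levy_scale = 1`, configurable): solution components can then grow in
  magnitude and saturate the transfer function toward the global best.
* **Acceptance ties.** beta-hc accepts equal-fitness candidates (neutral
  drift across accuracy plateaus, which are wide because validation sets
  are small and accuracy is quantized); the global best is replaced only
  on strict improvement, so the reported best mask is stable and the
  per-iteration best-fitness series is non-decreasing by construction.
* **Split protocol.** A train/validation/test split is used rather than
  cross-validating inside the objective; the validation set guides the
  search and the test set is scored exactly once per run. Per-run splits
  reshuffle by default (`fixed_split = TRUE` reuses one split).
* **`D` is the channel count.** The solution dimension always equals the
  number of channels in the feature table.

## The synthetic cohort: what it emulates and what it does not

Real multi-subject EEG corpora are large downloads; the generator builds a
desk-scale stand-in with a *known* answer. Each subject's informative
channels follow subject-specific stationary AR(5) processes whose
coefficients are drawn once per (subject, channel) — reflection
coefficients sampled in (−0.95, 0.95) and mapped through the Levinson
recursion, which guarantees stationarity by construction. All remaining
channels share one cohort-wide AR process, so after feature extraction
they contribute identically distributed noise columns. White sensor noise
(`noise_sd = 0.5` innovation units) is added to every channel. A single
seed fans out to per-(subject, channel, record) substreams, so enlarging a
cohort never perturbs already-generated recordings.

The default cohort is 8 subjects × 6 recordings of 10 s at 160 Hz over
16 channels with 3 informative ones — small enough that a full experiment
runs in minutes, large enough that the wrapper has real work to do:
single noise channels sit at chance, dense masks are degraded by noise
columns, and the planted mask scores near 100 %.

What the generator does **not** emulate: volume conduction (real
electrodes are spatially correlated), artifacts (blinks, EMG), session
effects and non-stationarity, and realistic spectral shape. Passing
recovery tests on this cohort therefore demonstrates that the search and
the wrapper work as designed — not that any particular accuracy carries
over to real recordings.

## Problem sizes used by the tests and the acceptance script

The package's own experiments run at desk scale, chosen so the whole
protocol stays interactive: optimizer budgets of `N = 8–10`, `T = 10–30`,
`bhc_inner_iters = 6–20` on 8- or 16-channel cohorts; 10–25 independent
runs per experiment; exhaustive enumeration (all 255 non-empty 8-channel
masks) as the optimality oracle; paired hybrid-vs-FPA comparisons at
matched distinct-evaluation budgets over 10–20 seeds. The full-scale
defaults (`N = 64`, `T = 100`) remain the package defaults for real use.

## Known limitations

* The identification protocol is closed-set; verification-mode analysis
  (impostor scores, EER) is out of scope.
* Accuracy plateaus mean the best mask is often one of many equally good
  masks; selection frequencies over repeated runs, not single best masks,
  are the meaningful channel-importance signal.
* The beta operator at `beta = 0.5` is strongly diffusive: on landscapes
  without plateaus it slows final convergence (each candidate re-randomizes
  half the bits), which is visible on hard toy problems at higher
  dimension. It is the configured default because it is the value the
  search protocol specifies; smaller `beta` exploits more.
* Multi-objective selection (accuracy vs channel count) is not
  implemented; the objective is accuracy alone.
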