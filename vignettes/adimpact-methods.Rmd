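---
title: "Methods: models, algorithms and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, algorithms and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`adimpact` predicts a binary purchase-intent verdict from single-channel
EEG band features. This vignette is the package's account of its science:
the generative model behind the synthetic cohorts, the algorithms and the
interpretive decisions inside them, the numerical conventions, and what the
validation results do and do not establish.

## 1. The generative model

Real cohorts of this design (consumer EEG + 22-item advertisement
questionnaire) are not publicly available, so the package validates itself
on cohorts it generates. The model treats a latent per-trial *emotion*
`e ~ N(0, 1)` as the bridge between signal and labels, `Y = f(X | E)`:

* **Voltage.** A sum of eight band-centered sinusoids (2, 5, 8, 11, 13,
  16, 40, 100 Hz — one carrier inside each analysis band) with per-trial
  random phases, plus white Gaussian noise (sd 2, same arbitrary units as
  the amplitudes). The emotion-linked carriers — Theta and the two Beta
  bands, the bands the emotion literature implicates — have amplitude
  `baseline * max(0, 1 + effect_size * e)`; the other carriers are fixed.
  The clamp at zero keeps power monotone in `e` (a negative amplitude is a
  phase flip and would fold the coupling back on itself).
* **Ranked answers.** `clip(round(3.5 + d_j + 1.5 * (e - e0)), 1, 7)` with
  small per-item offsets `d_j` spreading the eleven items. The intercept
  3.5 makes the default ranked threshold 4 split exactly at the latent
  center (`round(3.5 + x) >= 4` iff `x >= 0`), which is what lets a
  requested class balance be hit: `e0 = qnorm(1 - target_balance)` shifts
  the crossing point so the aggregated target is positive with the
  requested probability (held within ±0.05 in tests). With probability
  `label_noise` an answer is redrawn uniformly from 1..7.
* **Binary answers.** Indicators `1{e > e0 + d_j}`, each flipped with
  probability `label_noise`. At `label_noise = 0.5` a binary answer carries
  no information at all, which gives the pure-noise limit used in tests.
* **The answer gain is fixed (1.5), not tied to `effect_size`.**
  `effect_size` scales only the EEG←emotion coupling. If the answers also
  decoupled at `effect_size = 0`, the target would collapse to a constant
  class and "chance accuracy" would be undefined; with a fixed gain the
  decoupled limit yields balanced random targets and a clean 0.50
  reference.
* **Voltage abnormality.** A `round(rejection_rate * n)` subset of trials
  is overdriven 4x and clipped at the 60% quantile of its own amplitude;
  clipped samples get quality flag 200 (normal samples draw 0–25). The
  default quality filter (bad = quality > 50, tolerate at most 10% bad)
  therefore rejects exactly the planted trials.

The generator's defaults are the emulated study conditions: 30 subjects,
15 trials each, four product categories, 512 Hz. Ad durations are drawn
per category (car 24–30 s, clothing 13–20 s, digital 28–34 s, food
16–22 s) so that the per-category minimum lengths land at the canonical
trim values 24/13/28/16 one-second timestamps; a single global duration
range cannot produce four distinct category minima of that spread.
Defaults `effect_size = 1` and `label_noise = 0.05` define the
"strong-coupling, low-noise" reference cohort used by the recovery tests.

**The Bayes ceiling.** `planted_bayes_accuracy()` computes the best
achievable accuracy for predicting the aggregated target *from the latent
`e` itself*. Given `e`, each binarized answer is an independent Bernoulli
with a closed-form success probability, so the aggregate count is
Poisson-binomial and `P(target = 1 | e)` is exact; only `e` is Monte-Carlo
sampled (default 10^5 draws, reproducible to ±0.01 across seeds). No
feature-based classifier can beat this ceiling, making it the natural
yardstick for recovery: at the default configuration the ceiling is ≈0.99
and leave-one-subject-out accuracy lands within 0.01 of it, while at
`effect_size = 0` the pipeline scores 0.50 ± 0.02 over 20 seeds.

## 2. Feature extraction

Windows are 1 s, non-overlapping (512 samples at 512 Hz). The windowing is
a package choice: it makes one "timestamp" per advertisement second, which
is the only reading consistent with category trim lengths of 13–28 for ads
tens of seconds long.

Each window's band powers sum the one-sided FFT power spectrum over bins
with frequency in `[low, high)`, normalized so total power equals the
window's signal energy (Parseval, verified to 1e-6 relative in tests).
Two band presets ship because the available band-edge documentation is
internally inconsistent: `"device"` reproduces the device's stated edges
(with the evident sign typo on Delta read as 0.5–4 Hz, and Gamma capped at
Nyquist), while `"conventional"` is the conventional-literature reading
(1–3, 4–7, 8–9, 10–12, 13–17, 18–30, 31–40, 41–50 Hz). Shipping both
named presets was preferred to silently picking one; all defaults use
`"device"`.

`Attention`/`Meditation` device scores are proprietary and unpublished.
Recordings carrying device values pass them through; otherwise the package
derives bounded monotone proxies, `100·β/(α+θ+β)` (focus rises with
beta dominance) and `100·α/(α+β)` (calm rises with alpha dominance), with
0/0 mapped to the neutral 50. Any bounded monotone proxy suffices for the
pipeline: these columns are two of eleven features, not outputs.

**Flattening.** The classifier needs one fixed-length row per trial, but
trimmed lengths differ by category (24/13/28/16). The default reduction is
the per-feature mean over timestamps — the minimal fixed-length
representation that allows pooling categories into one model. A `concat`
mode (feature × timestamp columns) is provided for per-category
experiments and refuses mixed-category pooling by construction.

## 3. Labels

Binarization uses `value >= threshold -> 1` throughout. The conventional
ranked thresholds 3.5 and 4.5 avoid ties; at the integer threshold 4 a
convention is forced, and `>=` keeps the scale midpoint (7+1)/2 in the
positive class. Aggregation is *mean-then-threshold*: binarize every
answer of the selected group, average (weighted `α`/`β` for the combined
group), and compare against the dataset threshold. Dataset thresholds of
0.4/0.5/0.6 only make sense as proportions of positive answers, which is
what fixes this reading; it is nevertheless an interpretation, and it is
stated here prominently. The grid-scan API names its axes
`ranked_threshold` / `binary_threshold` / `dataset_threshold` explicitly
so no table-layout convention can silently swap them.

Both historical binary-threshold sets ({0, 0.5, 1} and {0.4, 0.5, 0.6})
are accepted; neither is privileged. A `single:Yi` label group supports
the narrow reading in which "purchase" means one specific item (e.g. Y9,
willingness to buy).

## 4. Augmentation

**Ten-fold dealing.** Positives and negatives are shuffled separately,
then folds 1–9 each take `round(ratio·n/10)` positives and
`round((1−ratio)·n/10)` negatives; fold 10 takes all leftovers. Rounding
is half-up (`floor(x + 0.5)`), and the counts are computed from the
integer class counts (mathematically identical to `ratio·n`, immune to
float error at the .5 boundary). When a class is small enough that
rounding up would overdraw it (e.g. 15 positives: 9 × round(1.5) = 18),
the deal simply runs the pool dry — later folds take what remains — which
preserves the disjoint/exhaustive partition; the per-fold counts then
follow the sequential-dealing arithmetic rather than the nominal constant.

**Gaussian bootstrap.** `x' = x + scale·g` per entry with
`scale = 0.5·(col_min + col_max)` per column and `g` a standard normal
truncated to the open interval (−1, 1) (rejection sampling). The
truncation interval is taken at face value: a symmetric zero-mean
perturbation strictly bounded by the column scale is the only reading
under which the data's spread is demonstrably preserved
(`|x' − x| < scale` always). Columns with `min + max = 0` pass through
unchanged (a zero scale would only add zeros anyway; the pass-through is
logged via an attribute rather than treated as an error).

**Combinatorial expansion.** For each subset size `r` and each selected
`r`-subset of feature columns, emit a copy of the original training block
with those columns replaced by their bootstrapped counterparts. This
subsets-of-bootstrapped-columns semantics is the only self-consistent
reading of an "nCr over columns" expansion; the nominal upper bound of 12
on `r` is exposed as the default `r_range` but the actual column count
governs. Full enumeration over 11 columns (2047 copies) is desk-hostile,
so defaults cap at 20 subsets per size (deterministic choice under the
seed, by lexicographic unranking of sampled ranks) and 50 copies total
(so at most 50·n augmented rows). The cap truncates at whole copies so
the block-wise label duplication stays row-aligned, and the emitted count
always equals `Σ_r min(C(k, r), cap)` up to that truncation — an identity
the tests check exactly. Labels are duplicated block-for-block, which
preserves the class ratio exactly.

**Leakage.** Whether the bootstrap runs before or inside the fold loop is
ambiguous in the protocol this package implements; it runs *inside* (per
training fold) because the alternative leaks augmented copies of test
rows into training. Every expanded matrix carries per-row provenance
(`original` / `boot:r=..:cols=..`) and an origin map, and every evaluation
run asserts that augmented rows trace only to training-fold originals
before any metric is computed. A fabricated violation aborts the run; the
assertion is exercised in the tests.

**Seeding.** All randomness flows from one user seed through a documented
splitting scheme (fixed offsets per stage: cohort, folds, bootstrap,
expansion, curve, permutation), so any stage is reproducible in isolation
and identical configurations are byte-identical.

## 5. The classifier

The model is linear with squared hinge loss:
`min_w,b ½‖w‖² + C·Σ max(0, 1 − y_i(⟨w, x_i⟩ − b))²`, labels internally
±1. The objective is convex and C¹, so it is minimized by BFGS with the
analytic gradient from a zero start — deterministic given the data, with
relative tolerance 1e-6. Tests verify the optimum against an independent
derivative-free multi-start minimization (agreement to 1e-4) and local
optimality under random perturbation.

* `C = 1` by default; with more samples than features the dual/primal
  distinction is an implementation detail with no numerical consequence
  at tolerance.
* Features are standardized by default (center/scale learned on the
  training rows only and stored in the fit): band powers span orders of
  magnitude and an unscaled linear margin is degenerate. Disable with
  `standardize = FALSE`. Constant columns get unit scale.
* Decision value exactly 0 predicts class 1, matching the `>=` convention
  used everywhere else.

## 6. Evaluation protocol

An **in-sample run** holds one subject out entirely (untouched), builds
targets for the rest, deals the ten folds, trains on folds 1–9 after
augmentation, and scores fold 10. Reported `n_train`/`n_test` count
pre-augmentation rows. **Leave-one-subject-out** repeats this for every
subject and macro-averages the per-subject metrics ("average of the
thirty out-of-sample judgments"); micro-averaging over pooled trials is
available by flag. Per-category accuracies are averaged across subjects.
Reported F is F1 on the positive class.

**Learning curves** reuse the same stratified splitter (consistency over
an independent splitter was a deliberate choice). For each fold and each
training fraction, the training pool is class-interleaved so every prefix
keeps the ratio; the x-axis counts pre-augmentation rows. Bands are
mean ± sd across folds. Sizes whose subsample holds a single class are
skipped with a warning.

**Threshold grid scans** run one in-sample evaluation per cell of the
Cartesian threshold grid, per category and pooled. Degenerate cells
(single-class targets at extreme thresholds, or category subsets too
small to split) are reported as `NA` rather than an error.

## 7. Problem sizes and runtime choices

The test suite validates the heavy statistical claims at the full
reference scale — 450-trial cohorts, leave-one-subject-out over 30
subjects, 20-seed nulls, 10^5-draw distributional checks — and uses
smaller cohorts (4–8 subjects, 3–6 s trials) for shape, bookkeeping and
property tests where scale adds nothing. The fold-dealing oracle check
runs 1000 random instances with n in 20..500. These sizes are the
package's own choices for a thorough-but-quick default run; all of them
are ordinary function arguments and scale up freely.

## 8. Limitations

* The synthetic EEG is deliberately minimal: stationary sinusoidal
  carriers plus white noise. No 1/f background, no blinks or EMG
  artifacts, no non-stationarity, no inter-subject variability in the
  coupling. Passing recovery tests therefore demonstrates that the
  *pipeline* extracts planted band-power signal correctly — not that real
  advertisement EEG carries such signal, and not any particular accuracy
  on human data.
* The questionnaire coupling (monotone noisy maps of one scalar latent) is
  an assumption; no published answer model exists for this design. All
  recovery results are conditional on it.
* Whether a real study would use device-reported band powers or recompute
  them from raw voltage is unknowable from the outside; both paths are
  supported (device columns pass through, the raw path computes them),
  and the presets cover both band-edge readings.
* Single-label targets (`single:Yi`) are supported but typically yield
  badly imbalanced targets at the default thresholds; grid cells for them
  are routinely `NA` at small n, mirroring how sparse such analyses are
  in practice.
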