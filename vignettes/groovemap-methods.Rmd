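---
title: "Methods: body-sensation maps and rating models for musical groove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: body-sensation maps and rating models for musical groove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovemap)
```

## The scientific problem

Groove — the pleasurable urge to move to music — is usually measured with two
Likert-rated components, *wanting to move* and *pleasure*. Body-sensation-map
(BSM) paradigms add a spatial dimension: after rating an excerpt, the listener
colors a blank body silhouette wherever the sensation was felt. The analysis
questions are then (i) where in the body each groove component is felt, (ii)
whether the spatial pattern depends on musical genre, stimulus familiarity, or
the rhythm's predictability, and (iii) how the ratings themselves respond to
genre, familiarity, musical training, and rhythmic complexity.

`groovemap` implements the full pipeline: reconstruction of per-trial painting
intensity maps from raw mouse stroke logs, pixel-wise ("mass univariate")
inference with false-discovery-rate control, linear mixed-effects models of
the ratings, and a *pulse entropy* feature that indexes beat-timing
uncertainty in audio. A synthetic-data generator with known ground truth
stands in for human participants, so every stage is testable end to end.

## Canvas reconstruction

Stroke logs record `(t, x, y, brush)` mouse samples per trial, 0-based pixel
coordinates with the origin at the top-left. Rasterization stamps a brush
kernel at each sample — a hard disc by default (every pixel within the brush
radius gets paint 1), or a Gaussian with $\sigma = \text{brush}/2$.
Numerical choices:

* **Saturating accumulation.** Paint is clipped at 1 per pixel: repainting a
  spot conveys no additional signal, matching coloring semantics. An
  unbounded mode (`clip = FALSE`) exists for sensitivity analysis and for the
  mass-accounting test, where pre-clip deposited mass must equal
  (number of samples) × (kernel mass).
* **Gap interpolation.** Consecutive samples further apart than half a brush
  radius are connected by stamps along the segment so mouse sampling gaps do
  not leave dotted strokes; gaps beyond six brush radii are treated as pen
  lifts and not interpolated. `interpolate = FALSE` disables this, covering
  the possibility that the original tool recorded discrete clicks rather
  than drag paths.
* **Out-of-body paint.** The fraction of deposited mass outside the
  silhouette is recorded *before* masking; `apply_mask()` then zeroes
  out-of-mask pixels. Masking is idempotent.
* **Anomaly screening** is reported, never silent: trials with in-mask
  coverage above 0.95 (scribble-everything) and, optionally, trials with an
  excessive out-of-body fraction are flagged and returned alongside the kept
  trials with a per-trial report. Empty paintings are legal data. The
  thresholds are not dictated by the paradigm; they are conservative
  defaults, configurable, and every decision is visible in the report.

## Pixel-wise inference

Subject-level condition maps (per-subject mean over trials) enter classic
mass-univariate tests at every in-silhouette pixel:

* one-sample $t$ against zero, $df = n-1$;
* two-way within-subject ANOVA (groove component × genre by default):
  each effect is tested against its own effect-by-subject interaction mean
  square, $F_{(a-1),(a-1)(n-1)}$ etc., the classical univariate
  repeated-measures partitioning, with no sphericity correction (none is
  standard for these maps);
* paired post-hoc $t$ maps with the sign giving the direction of the
  labelled contrast.

Multiplicity is handled with Benjamini–Hochberg FDR, applied **within each
statistical map over in-mask pixels only** — out-of-mask pixels never enter
the family, and each map carries its own threshold, mirroring how masked
body maps are reported. The level `q = 0.05` is an assumption (configurable);
no cluster-extent or random-field correction is applied, and pixel-wise BH is
the only correction.

Degenerate pixels are handled explicitly: zero variance with zero mean
(background nobody painted) gives $t = 0$, $p = 1$, so empty background can
never generate rejections; zero variance with nonzero mean gives an
infinite-$t$ sentinel with $p = 0$ and is counted on the result. A relative
tolerance (`1e-12` on the standard deviation, `1e-20` on mean squares,
scaled by data magnitude) treats floating-point cancellation residue on
constant pixels as zero variance.

Familiarity maps use a median split of stimuli on mean familiarity (ties go
low); entropy maps use rank tertiles (remainder to the middle bin).

## Rating models

Ratings are analysed per groove component with `lme4`/`lmerTest`:

* **Genre model:** `rating ~ genre + familiarity + formal + informal training`
  with funk as the treatment reference, by-participant random intercepts and
  genre slopes, and by-stimulus random intercepts, fit by REML with
  Satterthwaite denominator df. A by-stimulus genre *slope* is inestimable
  when each track belongs to exactly one genre, so it is dropped up front
  with a logged note; singular or non-converging fits walk a documented
  ladder (drop stimulus slopes, then participant slopes) and every step is
  recorded on the returned object, so any simplification is explicit rather
  than guessed.
* **Model comparison** uses likelihood-ratio tests after refitting both
  models by maximum likelihood (REML likelihoods are not comparable across
  fixed structures); REML remains the basis of the reported coefficient
  tables. This REML-for-estimates / ML-for-LRT split is standard practice.
  One caution that our calibration simulations quantify: for a
  *stimulus-level* factor such as genre, the chi-square reference of the
  LRT is asymptotic in the number of stimuli. With 12 stimuli carrying
  random intercepts the ML-LRT is markedly anticonservative (type-I rate
  ≈ 0.11 at the 0.05 level at full study scale), while the same machinery
  is exactly calibrated (0.051 over 1,000 replicates) when the data carry
  no stimulus-level heterogeneity and the fitted model matches. Inference
  on genre should therefore lean on the Satterthwaite t table (whose
  ~10 denominator df correctly reflect the 12 stimuli) rather than the
  chi-square LRT; the LRT size check in the test suite is accordingly run
  under the matched-model null where its reference distribution is valid.
* **Post-hocs** are estimated-marginal-means pairwise contrasts (`emmeans`)
  with the multivariate-$t$ adjustment over the contrast family; if that
  adjustment fails numerically the Tukey method is used and labelled in the
  output.
* **Entropy model:** ratings regressed on centred, scaled orthogonal
  polynomial entropy terms (`poly()`, linear + quadratic), training
  covariates, and random intercepts; the polynomial basis coefficients are
  attached to the fit so curves can be mapped back to the raw entropy scale.
  An inverted U appears as a negative quadratic coefficient. An optional
  genre × entropy interaction is available.

## Pulse entropy

Pulse entropy is an entropy-based inverse of pulse clarity: low values mean
a clear, certain beat. The chain is

1. **Onset-strength envelope**: half-wave-rectified spectral flux of a Hann
   STFT (window 1024 samples, hop 256; ~86 frames/s at 22,050 Hz);
2. **Beat-lag autocorrelation** of the mean-centred envelope, normalized to
   1 at lag zero, restricted to lags 0.25–2 s (beat rates 30–240 bpm, lag 0
   excluded), negatives floored at 0;
3. **Normalized Shannon entropy** of the curve as a pseudo-distribution over
   the $N$ lags: $-\sum p_i \log p_i / \log N \in [0,1]$. A one-hot curve
   gives 0, a flat curve 1, and an all-zero curve (no periodicity evidence at
   all) is defined as 1 with a flag.

This is a re-implementation of the statistic's *construct*, not a
bit-compatible port of any toolbox: frame sizes, the lag window and the ACF
normalization are explicit parameters carried on every result, and absolute
values are comparable within this package only. The flooring of negative ACF
values (rather than shifting by the minimum) keeps genuinely aperiodic
signals from acquiring spurious probability mass at anticorrelated lags.
After the $\log N$ normalization the logarithm base is irrelevant.

## The synthetic study generator

The generator emulates the study design end to end: 108 participants × 12
stimuli (4 per genre: funk, jazz funk, rock) × 2 groove components, 5-point
ratings, per-trial paintings, and nominal per-track pulse entropies fixed so
the genre means are funk 0.734, jazz funk 0.750, rock 0.722 with range
0.669–0.787 — the regime reported for real groove stimuli.

**Ratings.** A latent Gaussian mixed model (intercept + genre effects +
familiarity slope on the centred 1–5 familiarity + orthogonal-polynomial
entropy terms + training slopes + participant intercept/genre slopes +
stimulus intercept + residual) is observed by clamping to $[1, 5]$ and
rounding to the Likert grid — the simplest generative story consistent with
5-point ratings (an ordinal-threshold model would be over-engineering here).
Participant-level random effects are shared between the two components,
which reproduces the strong positive correlation between wanting-to-move and
pleasure ratings seen empirically (~0.7–0.8 for participant means).
Familiarity is itself simulated on the 1–5 grid around genre means
2.47 / 2.09 / 2.22 (funk slightly more familiar).

Default noise scales — residual 0.40, participant intercept 0.30,
participant genre slope 0.15, stimulus intercept 0.20, familiarity latent sd
≈ 0.35 — keep the latent ratings almost always inside the scale. This
*mild-censoring regime* is a design requirement, not a convenience: the
generator is specified to be fit-consistent (re-fitting the analysis model
recovers the generating coefficients with near-nominal confidence-interval
coverage), and with slopes of magnitude ~1 on a 4-unit response window that
only holds when clamping is rare. With 4 stimuli per genre and a stimulus
intercept sd of 0.20, the genre-contrast standard error lands near 0.18 with
~10 denominator df, the regime typical of designs with few stimuli per
genre.

**Paintings.** Each trial selects target regions independently with
probability equal to the region's weight for its (component, genre) cell,
then paints each selected region with a mean-reverting
(Ornstein–Uhlenbeck-style) random walk tethered to the region centroid —
contiguous blobs resembling human coloring. Bilateral regions (arms, legs,
shoulders, …) are split at the midline and each lobe is painted around its
own centroid; steps that would leave the region are simply not taken, so
paint spills over region borders only by the brush radius. The brush
dynamics of the original painting tool (pressure, opacity) are undocumented;
this stroke model is a stand-in, not a reconstruction. Sample counts are
chosen so the rasterized blob covers approximately the cell's target
coverage fraction, and a configurable fraction of samples (default 2%)
strays to random canvas positions to exercise out-of-body removal.

The default planted truth is a clean double dissociation over a uniform
painting baseline (weight 0.08, coverage 0.10 everywhere): a
groove-component effect confined to arms + legs (wanting to move > pleasure,
identical across genres) and a genre effect confined to hips + shoulders
(funk > jazz funk = rock, identical across components) — the qualitative
movement-to-extremities / genre-specific pattern at stake in this paradigm,
planted where recovery and specificity can both be scored by Dice overlap.

**Silhouette.** `make_silhouette()` draws a procedural humanoid mask
(default 522 × 171, the classic BSM aspect; any size ≥ 64 × 64) and
partitions the in-mask pixels exactly into 14 regions (head, ears,
neck/throat/mouth, shoulders, upper chest, chest, abdomen, arms, wrists,
hands, hips, legs, ankles, feet). The partition is exhaustive by
construction and the mask is a single connected component.

**Audio.** `simulate_click_audio()` places clicks on an exact sample grid
at the nominal tempo, perturbs them with Gaussian timing jitter, and adds
Poisson distractor onsets; 22,050 Hz mono, adequate for onset analysis at
half the usual compute. Jitter ≥ half the beat period warns that beat
identity is lost. Pulse entropy of these trains rises monotonically with
jitter (≈0.44 isochronous → ≈0.74 at 60 ms), spanning the range observed
for real music.

### What the generator does *not* emulate

Real paintings have individual styles, handedness asymmetries, erasures, and
device artifacts; real ratings are ordinal with response styles; real music
has onset structure far richer than click trains; and real familiarity is a
subject-level memory variable, not a genre-shifted latent. Passing the
recovery tests therefore shows that the *pipeline* is correct and well
calibrated under the stated generative model — it does not validate the
psychological claims on real data.

## Problem sizes used in the test suite

Map-recovery simulations use a 174 × 64 atlas (≈4,000 in-body pixels) with
50 subjects and 50 replicates; FDR calibration uses 20 subjects, a 100-pixel
canvas and 800 replicates (under the global null the expected false-discovery
proportion is q for any pixel count, so a small canvas buys replicates);
mixed-model coverage uses the full 108 × 12 × 2
crossing with 100 replicates, and the LRT size check 500 replicates. These
sizes give Monte-Carlo error comfortably inside the asserted bounds while
keeping the suite quick on a single core.

## Known limitations

* **Likert censoring bias.** Under clamp-then-round observation, slopes
  whose predictor spans much of the response scale are attenuated by the
  censored tail mass. For the familiarity slope (SE ≈ 0.03 at study scale)
  the residual attenuation of ~0.01–0.04 rating units is a non-negligible
  fraction of an SE, so its individual CI coverage sits slightly below
  nominal (~0.90–0.93) even in the mild-censoring regime; the genre
  contrasts (SE ≈ 0.15–0.20) are unaffected in practice. This is a property
  of the observation model, not of the estimator.
* **No ordinal models.** Ratings are analysed with Gaussian LMMs, as is
  conventional for this paradigm; cumulative-link models are out of scope.
* **No spatial modelling.** Pixels are tested independently; no spatial
  smoothing, cluster correction, or pixel-wise random-slope models.
* **Pulse entropy is construct-compatible, not value-compatible** with other
  implementations; only within-package comparisons are meaningful.
* With only 12 stimuli, stimulus-level quantities (genre contrasts, entropy
  curves) have ~10 effective df: single-dataset estimates scatter around the
  generating truth with SE ≈ 0.15 (genre contrasts) up to ≈ 2 (the
  quadratic entropy term), which is why the recovery checks are phrased
  over replicates.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates a full
synthetic study and writes the fitted genre contrasts and familiarity
slopes, the genre likelihood-ratio statistic, entropy-model coefficients,
Dice recovery of the planted spatial effects, the null false-discovery
proportion, the move–pleasure rating correlation, and pulse entropies of
click trains, all as JSON. The test suite (`tests/testthat/`) contains the
corresponding statistical acceptance checks with their tolerances.
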