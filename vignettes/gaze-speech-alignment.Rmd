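---
title: "Aligning gaze and spoken narratives for image region annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning gaze and spoken narratives for image region annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazealign)
```

## The problem

When a person views an image and describes it aloud, their fixations point at
the regions they find important and their words name what those regions
contain. The two streams are not synchronous: a speaker typically fixates an
object some variable fraction of a second before naming it, keeps looking
while formulating, revisits regions, and utters many words that ground in no
region at all. A fixed temporal rule ("the word spoken now belongs to the
region fixated now, or one second ago") therefore mislabels much of the data.

`gazealign` treats the two streams as a *bitext*: the ordered sequence of
fixated region labels is one "language", the ordered sequence of content
words the other, and unsupervised word alignment — IBM Model 1 followed by an
HMM aligner, trained in both directions with agreement — learns which words
translate which regions. Thresholding the alignment posteriors yields
word–region links that are pooled across observers into region annotations,
and scored against sure/possible reference alignments with precision, recall,
and the alignment error rate

$$\mathrm{AER} = 1 - \frac{|A\cap S| + |A\cap P^*|}{|A| + |S|},$$

where $A$ is the output link set, $S$ the sure reference links, and
$P^* = S \cup P$ the sure-plus-possible set.

## From raw data to parallel sentences

**Visual units.** Raw tracker samples are collapsed into fixations
(`read_fixation_log()`), observers with calibration error beyond
`k_sd` standard deviations of the group mean in either direction are dropped
(`qc_filter_observers()`), and the pooled fixations of all observers on one
image are clustered with a flat-kernel mean shift (`mean_shift_cluster()`),
which needs no preset cluster count. The default bandwidth is two degrees of
visual angle — 88 px at the 44 px/degree geometry of a 1680 × 1050 display
subtending 38° × 22° — i.e. roughly foveal scale; clusters whose centroid
falls outside the image (blinks, track losses) are discarded. Each retained
fixation then becomes a visual unit carrying its cluster label, onset, and
duration (`encode_visual_units()`). A k-means segmentation over standardized
RGB + spatial pixel features (`kmeans_segment()`, Lloyd's algorithm,
k-means++-style seeding, `spatial_weight = 1`) and externally supplied label
maps are drop-in alternatives behind the same `region_model()` interface.

**Linguistic units.** Transcripts arrive word-level time-stamped and
POS-tagged (any Penn-style tagger). Adjectives, common/proper nouns, gerunds,
and foreign words are kept; stopwords and task-instruction words ("next")
are removed; and any surface form uttered exactly once across an image's
narratives is removed everywhere, since such words are mostly transcription
errors or idiosyncratic word choices that cannot be grounded reliably.
Singleton counting runs *after* the POS and stopword filters — the
alternative order differs only when a stopword would have shielded a content
word's count, and filtering first keeps the count interpretable as
"groundable utterances". Unit timestamps are token onsets, for symmetry with
fixation onsets.

**Corpus construction.** A sliding window of `T_window = 5` s advanced by
`stride = 0.5` s cuts each trial into overlapping chunks; a unit belongs to a
window iff its onset lies in the half-open interval `[w, w + T)`. Within each
window, runs of identical region labels merge into one unit (duration
summed), and the visual side is truncated to
`round(beta * n_linguistic)` units — by longest duration (`alpha =
"longest"`, ties to the earlier unit), earliest, or random. The whole-trial
pair is appended to the corpus after merging but *without* balancing
(`full_pair_balance = FALSE`): balancing is defined per window, and
truncating the decoded full pair to the (short) linguistic length would
silently remove visited regions from the decodable space and cap attainable
recall. The 0.5 s stride is chosen so that thirty ~22 s trials yield on the
order of a thousand training pairs per image.

## The aligner

Both directions (regions→words and words→regions) are trained with the
staged schedule `m1_iters = 2` iterations of IBM Model 1 followed by
`hmm_iters = 2` of the HMM aligner, with posterior decoding at
`delta = 0.1`. Every source sentence carries a NULL token so non-grounded
words can stay unaligned.

* **Model 1** is the standard EM: uniform initialization, E-step posteriors
  proportional to `t(word | region)` under a uniform alignment prior,
  M-step renormalization of expected counts (with `1e-12` additive smoothing
  against zero divisions).
* **The HMM aligner** makes transition probabilities depend on the signed
  jump between successive source positions, bucketed at
  `max_jump = 5` (larger jumps share the boundary buckets), with NULL states
  that remember the last real position and are entered with probability
  `p_null` (initialized at 0.2, re-estimated). Emissions initialize from the
  Model 1 table. One numerical subtlety: the bucketed jump distribution has
  position-dependent row normalizers near sequence edges, so the familiar
  count-ratio update is not an exact M-step and can reduce the likelihood.
  The jump update here instead maximizes the expected complete log-likelihood
  directly — the objective is concave in the log-parameters, and L-BFGS-B
  started from the current parameters cannot decrease it — giving a
  generalized EM whose corpus log-likelihood is non-decreasing by
  construction (and asserted in the tests). `p_null` also governs the
  initial distribution, so initial-state occupancy enters its count update.
* **Agreement training** couples the two directions: at each E-step the
  directional posterior matrices are multiplied elementwise (one transposed)
  and renormalized per row before counts are collected in both models. The
  NULL column has no transposed counterpart and keeps its directional value
  before renormalization. This is the heuristic product combination;
  likelihood monotonicity is only guaranteed (and only asserted) for
  independent directional training.
* **Decoding** computes the same agreement-combined posterior for a pair and
  emits every (word, region) cell at or above `delta`, allowing one-to-many
  links both ways. Image-level output pools each observer's decoded
  whole-trial pair into a set of distinct (word, region) links, keeping the
  maximum posterior per link.

## Evaluation

Temporal baselines mirror the intuitions the aligner is meant to beat:
`baseline_simultaneous()` links each word to the visual unit active at its
onset, `baseline_delayed()` to the unit active a fixed `delay = 1` s earlier.
In fixation gaps the most recent preceding unit is used (configurable to
strict non-alignment); words before the first fixation stay unaligned.
Baselines are pooled over observers exactly like the framework output so all
methods are scored identically.

Reference alignments drawn as labeled pixel regions are projected onto the
model's label space (`project_reference()`): a cluster maps to a region if a
strict majority of its fixations fall inside; a segment maps to the region
with the largest pixel overlap provided it covers at least half the segment
and strictly beats every other region (exact ties map to nothing and are
reported as uncovered). `compute_metrics()` implements the formulas above,
with the conventions: empty output gives vacuous precision 1, recall 0; an
empty sure set makes recall undefined (`NA` with a warning). Internally
$P^* \supseteq S$ is enforced so sure links are never penalized.

`aggregate_labels()` ranks each region's linked words by utterance frequency
— descending by default, since the most frequent name is what one wants on
the region; the ascending variant described for some visualizers is
available via `order = "increasing"` — with ties broken by maximum posterior,
then lexicographically.

## The synthetic observer

`simulate_trial()` and `simulate_dataset()` generate co-registered scanpaths
and narratives with known ground truth, emitting the exact file formats the
production readers consume. A scene (`make_scene()`) has 14 spatially
separated regions — the upper range of the roughly-a-dozen gaze clusters a
complex everyday scene yields — each with a Gaussian fixation footprint
(σ = 30 px), a salience weight (uniform floor plus a gamma-distributed
preference, so interest is uneven but no region is ignored), and a name
lexicon: a dominant name plus one shared synonym (probability 0.15).

An observer's gaze follows a salience-weighted visit chain without immediate
self-transitions; fixation durations are lognormal with mean 250 ms;
narratives run ~22 s at ~2.5 words/s with a 0.58 s silent preview. A region
is named on its first visit with probability 0.5; naming visits dwell longer
(about three extra fixations). The word onset follows the visit onset by a
Gaussian eye–voice lag (mean 0.9 s, SD 0.3 s). A naming uses the scene
lexicon except with probability 0.43, when the observer substitutes a
personal one-off pseudo-word — modelling the lexical diversity of real
narratives ("lady"/"woman"/"female"), and exercising the per-image singleton
filter, which removes exactly such words. Filler words are drawn from the
stopword vocabulary at the speech rate so the linguistic filters have
something to do. The generator guarantees by construction that every
region's dominant name is uttered at least twice by at least two observers
(topping up, when needed, at an observer's longest visit to the region, with
the visit dwell extended and all later events shifted so onsets stay
monotone); without that floor the singleton filter could erase ground truth
that no method could then recover. Ground-truth references put
(dominant name, region) pairs in $S$ and (synonym, region) pairs in $P$,
expressed in the pipeline's own cluster-label space so references and output
are directly comparable.

What the generator deliberately does *not* emulate: image content (regions
are spatial distributions, not pixels — the k-means path is exercised on toy
rasters); saccade kinematics; transcription errors; and, by default,
non-groundable *content* words. A configurable `abstract_rate` can inject
scene-level nouns ("picture", "thing") at arbitrary times, but the default
is 0 because such words break the generator's contract that every content
word has exactly one generating region; with the knob on, they depress
precision and can displace sparsely-uttered dominant names from the learned
lexicon — a realistic stressor, but then the ground truth no longer defines
the right answer for them. Consequently, passing tests show that the method
recovers a recoverable signal under lexical diversity and a variable
sub-second lag; they do not show robustness to abstract language or ASR
noise on real recordings.

One property of these conditions is worth stating plainly: because the lag
is tightly concentrated (SD 0.3 s) and naming dwells are longer than the
mean lag, a *simultaneous* matcher is close to ceiling here — most words are
uttered while the named region is still being fixated. The discriminating
comparison under these conditions is against the 1-second-delay matcher,
which the framework beats on essentially every image in both recall and AER;
with real recordings, where the lag is longer-tailed and planning
decouples speech from gaze, neither temporal rule holds up, which is the
method's motivation.

## Problem sizes and numerical choices

The shipped validation uses 20 images × 10 observers (≈ 78 fixations and
≈ 50 tokens per trial, ≈ 450 corpus pairs per image) for the simulation
study, 4 × 8 for the zero-noise control, brute-force enumeration oracles up
to 5 × 5 tokens for the aligner, and 100 random toy corpora for the EM
monotonicity property — sizes at which the oracles are exact and a full run
completes in a few minutes on one core. Mean shift iterates to a 1e-3 px
shift tolerance with single-linkage mode merging at half the bandwidth, and
orders cluster labels by centroid so labelling is independent of input
order. Rounding of the visual-linguistic target length is half-away-from-
zero. All randomness flows through explicit seeds; training itself is
deterministic given the corpus order, and corpus, alignment, and metrics
files are byte-identical across reruns with the same seed.

## Known limitations

* The agreement combination is the heuristic product, not the exact joint
  objective; directional likelihoods can oscillate under it.
* Reference projection needs either fixations (mean shift) or a label map;
  a polygon-only model with no pixel support cannot be projected.
* The simulator's filler stream makes type–token ratios lower than in rich
  natural narratives; TTR statistics from `narrative_stats()` are most
  meaningful on real transcripts.
* Lemmatization and synonym merging are out of scope: "bears" and "bear"
  are distinct linguistic units.

## A minimal run

```{r example, eval = FALSE}
ds  <- simulate_dataset(n_images = 2, n_observers = 6, seed = 1)
ev  <- evaluate_dataset(ds)
ev$summary        # macro precision / recall / AER per method
ev$improvement    # images on which the framework strictly improves
head(ev$lexicon)  # argmax_w t(w | region) vs the generating name
```

The same pipeline is scriptable stage by stage from a shell through the
`cmd_*()` functions or `inst/cli/gazealign`, with every stage reading its
predecessor's serialized outputs and writing a manifest.
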