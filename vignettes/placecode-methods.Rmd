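---
title: "Methods: place and speed coding analysis for CA1 calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: place and speed coding analysis for CA1 calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(placecode)
```

# Scope

`placecode` analyzes one-photon (miniscope) calcium imaging of hippocampal
CA1 populations recorded while a mouse freely explores a linear enclosure.
The pipeline starts from extracted df/F traces, body-point pose coordinates,
and per-cell spatial footprints; video processing, motion correction, and
source extraction are upstream and out of scope. Two cell populations are
considered throughout: glutamatergic pyramidal cells (CAMK2A-labeled,
sparse, fast calcium transients) and GABAergic interneurons (VGAT-labeled,
denser activity, slower transients).

Because raw recordings of this kind are rarely deposited, the package ships
a synthetic-session generator with complete ground truth. Every analysis
stage is validated against that ground truth or against an analytic oracle;
the test suite is the package's evidence that each estimator recovers what
it claims to recover.

# Data model and timebase

Miniscope video is captured at 30 frames/s and temporally downsampled by a
factor of four during preprocessing, so the neural timebase is fixed at
7.5 Hz and 30 Hz behavioral pose is block-averaged onto it (four behavior
frames per neural sample). A `session` holds the cells x samples df/F
matrix, the aligned pose table (nose, ear, tailbase xy in cm), footprints,
and metadata. Samples excised around a mid-session manipulation
(`removed_interval`) are excluded from every statistic.

Coordinates run along the track length with the origin at the left wall.
The tailbase point defines the animal's position and the speed used for
classification and decoding; the data do not dictate which tracked point is
"the" position, and the tailbase is the most stable of the three. Pose and
speed are smoothed with a centered moving average of 0.5 s; at 7.5 Hz that
is 3.75 samples, rounded to a 4-sample (~0.53 s) window. Translational
movement is defined as nose AND tailbase speed strictly above 3 cm/s;
boundary ties are excluded.

Cells enter the analysis only if their trace variance is at least 10% of
the maximum variance among non-outliers; outliers are variances above
Q3 + 1.5 IQR across cells, with quartiles taken by the nearest-rank
convention so the fence is meaningful for small populations. Outlying cells
are themselves kept whenever they pass the 10% rule - the fence only stops
them from inflating the reference maximum.

# Activity maps and place coding

Activity maps bin the enclosure into 3.5 x 3.5 cm pixels, accumulate df/F
over movement-masked samples, and divide by occupancy, giving mean activity
per visited bin. Smoothing uses a 5 x 5-bin Gaussian kernel (sd 0.85 bins =
2.98 cm) whose weights are renormalized over in-bounds occupied bins, so
edges and occupancy holes do not leak mass. An exact conservation identity
(unsmoothed map x occupancy sums to the total masked df/F) is asserted in
the tests for every session.

Spatial information is the mutual information, in bits, between 1-D
position (3.5 cm bins along the track length) and df/F binned by Sturges'
rule, `ceiling(1 + log2(n))` bins over the movement-masked samples, with
the top bin edge closed. Zero-probability cells contribute nothing.

The place-cell null circularly permutes the full trace by constant
increments `round(k T / 100)`, `k = 1..100`, recomputing MI after masking.
The final shift equals the series length, i.e. the identity: the observed
statistic is a member of its own null. With the strict `>` rule against the
95th percentile this makes the test exact - the probability that one of 100
exchangeable values strictly exceeds the type-7 95th percentile of the set
is exactly 5%. (Dropping the identity shift, a tempting convention, makes
the test anticonservative at about 5.9%; we verified both rates by
simulation at 4000 null cells.) Cells with fewer than 100 masked samples
are flagged unclassifiable.

Place fields are 4-connected components of smoothed-map bins exceeding the
map mean by more than 1.5 SD (mean and SD over occupied bins). Field size
is bin area x bin count; width is the x-extent from first to last column
spanned; the field center is the x-center of the maximum bin, and the
primary field is the one with the highest peak. Because the threshold
adapts to the map, detected widths track the underlying tuning width only
while fields are narrow relative to the track: on a 70 cm track the
relationship is monotone up to a tuning sd of roughly 5 cm and saturates
beyond, which is worth remembering when interpreting absolute widths.

# Remapping analyses

Mid-session manipulations split a session into two 10-min halves around the
excised interval. Each half is analyzed independently (its own movement
mask, maps, MI nulls, fields).

For map comparisons, 2-D maps are flattened by taking the maximum over
occupied bins in each column (a 3 x 20 map becomes a length-20 profile).
When the enclosure is rescaled (70 to 35 or 70 to 105 cm), the second-half
profile is linearly interpolated onto the first half's grid at matched
relative positions before the Spearman correlation over pairwise-complete
bins. Chance is the 95th percentile of a pooled null built from 1000
iterations in which every second-half profile is circularly shifted by a
shared per-iteration offset; sharing the offset preserves across-cell
structure (independent offsets are available via an argument).

Rotation analysis divides the track into thirds. Only cells that are place
cells in the first half enter; middle-third centers are excluded as
uninterpretable. A cell "rotates" if its second-half primary center lies in
the opposite outer third and is "non-rotating" if it stays in the same
outer third; cells that lose their field (or land in the middle third) in
the second half form a separate "lost" category that stays in the
denominator of the reported percentages. For recovering a generator's
rotation probability this denominator is biased low by the lost fraction,
so `analyze_half_pair()` also reports the conditional estimator
`rotate / (rotate + non_rotate)`, which is unbiased when field loss is
unrelated to the remap label; the recovery tests use it.

Width change (second half minus first half, of the primary field, on each
half's own bin grid) is reported only for cells independently classified as
place cells in both halves.

# Speed coding

To decouple speed from place tuning, each trace is first regressed on
position encoded as one-hot 3.5 cm bins (a Gaussian identity-link linear
model whose fit is exactly the per-bin mean); one-hot encoding removes
arbitrary, e.g. unimodal, position tuning that a single linear-in-x term
could not absorb. The speed statistic is the Spearman correlation of the
residual with speed over all non-excised samples, against a null of 100
constant-increment circular shifts of the speed vector (identity included,
as above, making each 5% tail exact under exchangeability): above the 95th
percentile is a positive speed cell, below the 5th a negative one.

One bias is worth documenting: the position regression removes the
sample-level association between speed and position only in the observed
alignment, not in the shifted null members. The effect is an overfitting
term that scales like the number of position bins over the effective sample
size, making the test slightly conservative on short sessions (empirically
~0.087 total two-tail rate at 8-min sessions, ~0.094-0.097 at the standard
20-min length, against a nominal 0.10). Calibration checks therefore use
full-length sessions; with many short sessions the test errs on the safe
side.

Encoding consistency is checked by computing each cell's df/F-speed
Spearman r separately within two partitions - left/right halves of the
track, or first/second 10-min halves - and correlating the two per-cell
r-vectors across cells.

Speed decoding separates the timeline into alternating 60 s blocks with
10 s guards; odd blocks train a Gaussian linear model of instantaneous
speed on the position-regressed traces, withheld even blocks are scored by
the Spearman correlation of actual and predicted speed over the
concatenated test samples. All samples (not only movement-masked ones)
enter, since masking would fragment the 60 s blocks. The statistic averages
over 100 random cell subsets of a fixed size (default 32, the smallest
per-animal cell count in the motivating experiments); the chance threshold
is the 95th percentile of the same pipeline run on circularly permuted
speed. Rank-deficient fits drop aliased coefficients. Sessions whose path
length falls more than 1 SD below the cohort mean are flagged for
exclusion.

# Population events

A deliberately simple event-extraction stand-in (thresholded positive first
differences at 3 robust SDs of the differenced trace, adjacent hits merged)
replaces spike deconvolution while preserving its downstream contract - a
binary event raster. Population events are samples where the coactivity
count meets or exceeds the mean plus 4 SD; contiguous supra-threshold
samples merge into one event (both merged and raw sample counts are
reported, merged primary). Event speed profiles report the mean running
speed during events and the cumulative percentage of events below each
1 cm/s speed bin.

# Cross-day matching and stability

Footprint matching is a documented, deterministic stand-in for
probabilistic coregistration. Sets are first registered by an integer
translation chosen as the mode of the centroid displacement field (the
shift aligning the most centroid pairs within 4 px), then refined by the
median residual displacement over nearest-centroid pairs; the total shift
is bounded by the declared search radius. Correlating summed footprint
images, the more obvious choice, fails under heavy turnover because most
blobs have no partner - the displacement-mode estimator is robust to that.
Candidate pairs within 8 px centroid distance are scored by the
intersection-over-union of half-maximum masks (evaluated at the four
integerizations of the fractional shift, best kept) and accepted greedily
in descending IoU, one-to-one, requiring IoU >= 0.3.

Matching is validated the way an experimentalist would: the same physical
cell should show a similar mean transient amplitude (and peak-to-noise
ratio) across days, so the Spearman correlation of those quantities across
matched pairs is compared with a pair-shuffled 95th-percentile chance.
Turnover is matched pairs over the mean of the two sessions' cell counts
(per-session denominators also reported, since the natural denominator is
ambiguous). Across-day stability reports per-matched-cell flattened-map
correlations (day-i place cells), and population-level correlations of MI
and of the residual df/F-speed r across days, each against pair-shuffled
chance.

Peak statistics use local maxima with topographic prominence of at least 5
robust noise SDs, where the noise scale is `1.4826 x MAD(diff(trace)) /
sqrt(2)`. Referencing the raw trace SD instead (another common convention)
raises the bar for exactly the busiest cells and systematically undercounts
interneuron-like transients - with it, the denser VGAT-like archetype shows
a *lower* detected peak rate than the CAMK2A-like one, inverting the
configured ordering; the differenced-MAD reference is insensitive to the
transients themselves and restores it. Width is measured at half
prominence; the peak-to-noise ratio divides the mean peak amplitude by the
MAD-based noise SD of the trace outside peak windows.

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume - and
only that.

* **Trajectory**: a bout-structured 1-D walk (running bouts, mean 4 s,
  target speeds 8-25 cm/s; pauses, mean 2 s) with reflective walls and an
  Ornstein-Uhlenbeck transverse wander, at 7.5 Hz for 20 min. Defaults give
  60-85% of samples above the 3 cm/s threshold and occupancy covering at
  least 90% of spatial bins.
* **Archetypes**: baseline transient rates 0.11 (CAMK2A-like) and 0.17
  (VGAT-like) peaks/s with decay constants 1.0 and 1.9 s, chosen so
  rendered peak widths bracket the 0.77 vs 1.34 s regime characteristic of
  the two populations; tuned-cell fractions default to the published
  proportions for each type (place: 0.51/0.27; speed +: 13.8%/33.8%;
  speed -: 32.4%/14.6%; across-day survival: 0.47/0.17).
* **Place tuning**: exactly `round(fraction x n)` cells get 1-D Gaussian
  fields, centers uniform, tuning sd uniform on 4-8 cm, a peak rate gain of
  6 and an out-of-field floor of 0.15 - place cells fire predominantly
  in-field (~40x contrast), without which the 1.5-SD field rule detects
  only single-bin fields.
* **Speed tuning**: linear rate gain, `1 + slope (v - 10)/10`, clipped at
  zero (clips counted); the data constrain no particular functional form,
  so linearity is our choice.
* **Rendering**: Bernoulli onsets at `rate x dt` (one event per 133 ms bin
  at most, exactly bookkept in the `latent_events` attribute), convolved
  with a single-exponential transient with per-event amplitude jitter, plus
  Gaussian noise (sd 0.1 against mean amplitude 1, giving peak-to-noise
  ratios near 10, typical of curated miniscope data).
* **Manipulations**: 180-degree rotation of a linear track is modeled as
  mirroring along x. Each place cell carries a remap label - rotate
  (mirror), stable (keep), random (redraw) - and rescaling multiplies
  centers and widths by the length ratio (`scale_with_track`) or keeps them
  (`fixed`). A 22 s noise-only gap with frozen pose is excised at the
  junction, mirroring the experimental interruption.
* **Multi-day**: cells survive with `p_survive`, keeping identity, speed
  tuning, and footprint (jittered <= 2 px/axis/day); log amplitudes regress
  toward the mean with correlation `amp_rho` (default 0.8); surviving place
  cells keep their field with `p_place_stable_day`, otherwise it is
  redrawn; replacements appear at fresh sites. Footprints are Gaussian
  blobs (sd 5.5 px, half-maximum radius ~6.5 px, soma scale) at dart-thrown
  positions with >= 12 px separation - irregular placement matters, since
  any lattice-like regularity lets a wrong global shift align many cells at
  once and breaks registration at low survival.
* **Population events**: optional injection of synchronous frames for a
  participating subset (default 60%) at low- or high-speed samples,
  emulating the speed regimes in which pyramidal and interneuron synchrony
  concentrate.

What the generator does **not** emulate: 2-D place fields, theta-phase or
sequence structure, biophysical calcium dynamics, slow drift, and
cross-contamination between neighboring sources. Passing tests therefore
show that the estimators recover the structure they target under realistic
noise, rates, and sampling - not that they are robust to every artifact of
real recordings.

# Numerical choices and degenerate inputs

* All percentile rules use R's default type-7 quantiles; permutation nulls
  include the identity shift (see above).
* Position and df/F values on the top bin edge go to the last bin; partial
  edge bins are kept (a 9 cm width gives 3 transverse bins of 3.5, 3.5,
  2 cm).
* Sub-seeds for per-cell and per-iteration randomness derive from one
  master seed by a fixed linear rule, so results are stable under
  reordering and fully reproducible; pipeline outputs are byte-identical
  across runs with equal seeds.
* Flat traces yield zero peaks (flagged); noiseless traces fall back from
  the MAD to the SD of the differenced trace for the prominence scale.
* Constant position degrades the position regression to mean-centering,
  with a warning; a single occupied position bin gives MI 0 with a warning;
  empty split partitions and unknown manipulation labels are errors that
  name the offending component.

# Validation sizes

The test suite validates each stage at fixed, documented problem sizes:
calibration of the place and speed nulls at 4000 white-noise cells (20 x
200 on 8-min sessions for place; 80 x 50 on 20-min sessions for speed,
where session length matters, see above); place-cell and field-center
recovery pooled over 5 default 50-cell sessions; rotation recovery at 150
place cells x 10 seeds per rotation probability (0.2/0.5/0.8) on 10-min
halves, with 20 control seeds; rescale direction at 40 place cells x 20
seeds per condition; decoding contracts at 20 seeds; matching accuracy at
20 seeds of 100 cells, turnover at 6 seeds x 150 cells per survival level,
amplitude persistence at 5 seeds x 200 pairs. `scripts/acceptance.R`
regenerates the headline quantities on fresh synthetic sessions from a
caller-supplied seed.

# Known limitations

* The MI estimator is the plug-in (maximum-likelihood) estimator and is
  upward-biased at small sample counts; the permutation null carries the
  same bias, so classification is calibrated even though absolute MI values
  are not bias-corrected.
* Detected field widths saturate for fields wider than about a fifth of the
  track (adaptive threshold; see above), and the calcium transient tail
  smears maps by a few centimeters in the running direction, which is the
  main residual error in field-center recovery (~0.8-2 cm median).
* The speed-cell test's small conservative bias on short sessions is
  inherent to regressing position out of the statistic but not the null.
* The footprint matcher assumes rigid translation; rotation and
  non-rigid deformation are out of scope, as is probabilistic match
  confidence.
* Group-level summaries call standard nonparametric tests (Wilcoxon,
  Fisher, Benjamini-Hochberg) and define the FDR family as the tests within
  one report section; other family choices are defensible.
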