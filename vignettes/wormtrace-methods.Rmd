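---
title: "Methods: calcium-trace extraction and response classification for trapped neuron pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-trace extraction and response classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormtrace)
```

## The analysis problem

`wormtrace` re-implements, as a tested and reusable pipeline, the image
analysis used to quantify stimulus-evoked calcium responses (GCaMP3) in
paired *C. elegans* sensory neurons — I2 in the head, PHA in the tail —
recorded in microfluidic traps while H2O2 or blue light is perfused. A
recording is a Z-stack time series (10–15 planes, 10 µm spacing, one stack
every 2 s, 350 time points) with the stimulus applied for 100 frames after
an initial baseline of about 40 frames. The animal is held by pillars but
not immobilized: the field drifts slowly and occasionally jumps when the
animal twitches. The two somata of a neuron pair are the objects of
interest; their brightness differs between left and right members and
changes several-fold during a response, which is what defeats plain
thresholding and motivates every stage below.

The pipeline is: maximum-intensity Z projection; whole-field registration
to the first frame by integer-shift cross-correlation; trainable pixel
segmentation (a decision tree over a gaussian/median/range filter bank,
trained on ~10 sparsely labelled frames); per-frame component extraction
and two-object tracking by global distance minimization; per-neuron mean
fluorescence, background subtraction and dF/F0 normalization; pooling
across animals after synchronization to stimulus onset; and a three-level
response triage (high / moderate / absent). Around it sit the static-image
ROI quantification used for reporter-induction comparisons and the
statistical decision tree used for group comparisons.

## Registration

Frames are aligned to the first frame of the series with integer shifts
only. The score for a candidate shift is the zero-normalized
cross-correlation: both images are mean-subtracted over the full frame and
the correlation is normalized by the product of their L2 norms, so it lies
in [-1, 1] and the denominator does not depend on the shift. The search is
exact: a zero-padded FFT computes the full correlation surface (padding at
least as wide as the gate, so no circular wrap reaches a gated lag), and
the reported shift provably attains the exhaustive-search maximum — the
test suite re-derives it by direct summation. Ties are broken toward the
smallest `|dy| + |dx|`, then smallest `dy`, then `dx`.

Sub-pixel refinement is deliberately omitted: downstream quantities are
means over ~100-pixel components and are insensitive to sub-pixel error.
Defaults: `max_shift = 20` px, low-confidence flag below a normalized
score of 0.3, zero fill for vacated pixels (excluded from background
estimation through a validity mask). A constant frame cannot be registered
and is flagged degenerate at shift (0, 0).

## Pixel segmentation

Each frame is described by a filter bank — the frame itself, Gaussian
blurs (sigma 1, 2, 4 px), median filters (3, 5 px windows) and local range
(max − min, 3 and 5 px windows) — and a CART decision tree (`rpart`,
depth ≤ 8, ≥ 20 pixels per leaf, complexity 1e-4) classifies every pixel
as neuron or background. Labels use the sparse-scribble convention
(0 background, 1 neuron, 255 ignored), so ~10 partially annotated frames
suffice.

Two implementation notes. First, filters run at camera-count scale with
replicated borders; the Gaussian is a cached separable dense-operator
convolution, the 3×3 median an exact 9-input min/max network, and the
range filter a separable running max/min — each checked against
brute-force sliding-window oracles in the tests. Second, trees learn
*absolute* intensity thresholds, so a classifier shown only baseline
frames inflates its masks several-fold when a soma brightens during a
response, which dilutes the extracted mean and roughly halves the
recovered peak dF/F0. The labelling protocol therefore spreads training
frames over the recording *and* the early response (five across the movie,
five at onset + 1..8 frames) and labels the periphery of each soma — a
few-pixel background ring — alongside its interior. This mirrors how
annotators actually scribble in trainable-segmentation tools and is what
makes sub-10% peak recovery possible; it is a property of the training
data, not a change to the classifier.

Masks are reduced to 8-connected components; components under 5 px are
dropped and the expected number (two, for a neuron pair) of largest
components is kept. A global Otsu threshold is retained as the comparison
baseline; on scenes with a linear background gradient and bleaching it is
measurably worse than the trained classifier (the package's validation
quantifies the margin rather than asserting it).

## Tracking and identity

Per frame, track heads are matched to detected components by a globally
optimal gated one-to-one assignment: maximum number of matches first, then
minimum total Euclidean centroid distance, found by exact branch-and-bound
enumeration (object counts here are tiny; an LAP solver would be
overkill). Unmatched heads coast on their last centroid and record a gap;
a gap run longer than `max_gap = 10` frames terminates and flags the
track. Unmatched detections may open candidate tracks only during the
first `init_window = 10` frames, and the two longest-coverage tracks are
retained. A movie in which no initialization frame shows the expected two
components is flagged as a tracking failure and excluded from pooling —
the automated counterpart of recordings that could not be quantified
because of uncontrolled movements; excluded movies are listed in the run
manifest, never silently dropped.

Retained pairs are named `left`/`right` by median column. The naming is
image-frame, not anatomical: trapped animals occasionally face the other
way, so anatomical sides require operator input.

## Traces, normalization, pooling, classification

The raw trace is the mean intensity over the tracked component's pixels;
the per-frame background is the median outside all components dilated by
3 px, excluding registration padding. Gaps up to `max_gap` frames are
filled by linear interpolation; longer gaps stay missing. With background
subtraction on (the default), `F0` is the mean of the pre-onset frames,
`dff = (F - F0)/F0`, and the baseline noise `sigma` is the SD of
pre-onset dff. dF/F0 with a full pre-stimulus baseline is the
field-standard normalization and makes traces scale-invariant: rescaling
a movie's intensities leaves dff unchanged.

Pooling re-indexes each trace to `offset = frame - onset` and averages per
offset (mean, SD, n; offsets with fewer than two traces are dropped), so
responses from recordings with different baseline lengths align at
offset 0.

Response triage replaces a visual call with an auditable rule on the peak
dff inside the stimulus window extended by `lag_allow = 15` frames:
*absent* below `max(3 * sigma, 0.2)`, *high* at or above `0.8`, otherwise
*moderate*. The thresholds are configuration, are recorded in every call,
and were fixed before the validation suite was run; amplitudes near a
band edge are intrinsically ambiguous, which is why the synthetic
benchmark builds its classes at 0, 0.5 and 1.6. High/moderate/absent
triage of this kind has traditionally been done by eye, so responder
fractions from visually scored datasets are not reproduction targets for
this package; the validation instead measures agreement with synthetic
ground truth.

For light recordings (single Z, 10 frames/s, immobilized animals) there is
no tracking: mean intensity inside hand-drawn polygon ROIs (anterior
neurite, posterior neurite, soma) is normalized the same way with the
light-onset frame as the synchronization point.

## Static-image ROI quantification

For reporter-induction comparisons the measurement is the
background-subtracted mean pixel intensity on a maximum projection, with
the ROI either a polygon (rasterized by the even-odd pixel-center rule,
chosen for cross-implementation determinism) or a threshold superlevel
set. When no background ROI is drawn the background is the median outside
the 3 px-dilated mask. Adding a constant to the whole image leaves the
result unchanged.

## Statistics

Group comparisons follow a fixed decision tree. A sample is treated as
normal when n > 30, or when both Shapiro-Wilk and Anderson-Darling fail
to reject at 0.05 (either test rejecting routes to the rank branch; the
Anderson-Darling test needs n ≥ 8 and is skipped below that). Two normal
groups: unpaired two-tailed t test, Welch variant when a two-sided F-ratio
test rejects variance homogeneity at 0.05 — the homogeneity trigger is
stated by the procedure but not its test, so the F test is this package's
choice. Otherwise Mann-Whitney (exact when sizes permit and no ties,
tie-corrected normal approximation otherwise). Three or more groups:
one-way ANOVA with Bonferroni pairwise t tests (pooled SD), or
Kruskal-Wallis followed by Dunn's tie-corrected z tests with Bonferroni
adjustment — written out in full because no post-hoc Dunn implementation
ships with the environment's packages; it is oracle-tested against
first-principles rank arithmetic. Stars: ns > 0.05, then *, **, ***, ****
at 0.05, 0.01, 0.001, 0.0001. Every result records its decision path.

## The synthetic-scene generator

Raw recordings of this kind are rarely redistributable in numeric form,
so every stage is validated on a generator that emulates the acquisition
and emits
exact ground truth: per-frame integer shifts, per-neuron masks, noiseless
traces, response classes and the background series.

A soma is an isotropic Gaussian blob (scale `radius_px`, default 3 px);
its ground-truth mask is the footprint above 10% of peak, and the blob is
scaled so the noiseless in-mask mean equals `B * (1 + A * k(t)) *
bleach(t)` exactly — ground-truth traces are then read back from the
rendered noiseless projection, so generator and oracle agree by
construction. The transient kernel is a normalized
rise-times-decay double exponential; the kinetic presets (fast: rise
2.5 s, decay 6 s; slow: rise 4 s, decay 15 s) reproduce the qualitative
contrast between an I2-like photoresponse completing within 10–15 s and a
PHA-like one taking roughly 30 s on the 2 s frame grid; they are package
choices, not fitted sensor constants. Whole-field
motion is a reflected Gaussian random walk (bounded at ±10 px) with
occasional uniform integer twitch jumps, rounded to integer shifts; the
linear background plane translates with the field, so registration is
exactly recoverable. Z planes get a Gaussian defocus weight peaking at the
central plane — sufficient because the analysis consumes max projections;
no PSF or worm-body rendering is attempted. Noise is applied in the order
bleach → Poisson shot noise → Gaussian read noise (default SD 4 counts) →
clip and quantize to uint16. A scene's seed fully determines its output.

What passing tests on this generator do **not** show: robustness to
non-rigid body deformation, out-of-focus drift in Z, autofluorescent gut
structures, or somata that overlap — real failure modes that the original
study handled by excluding unquantifiable movies visually.

## Validation problem sizes and numerical choices

The packaged validation (`tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) uses: 50 frames with shifts spanning ±10 px for
registration (gate 12); one 350-frame gradient-plus-bleaching movie for
segmentation, scored as pooled per-pixel F1 on held-out frames against
both the classifier and per-frame global Otsu; five two-neuron movies plus
1000 random ≤4-object instances for tracking optimality; amplitudes
{0.2, 0.5, 1, 2} × 10 seeds at 96×96/150 frames for peak recovery; a
60-movie suite (20 per class) at the full acquisition geometry — 128×128,
350 frames, onset 40, 100-frame stimulus, rendered with 2 Z planes — for
end-to-end class agreement, run with the package-default feature bank and
tree settings (the full bank is load-bearing: with fewer scales the tree
places its soma boundary inconsistently across brightness levels, which
inflates F0 and dilutes recovered peaks by roughly a quarter); 1000 Gaussian
null replicates at n = 20 for the type-I rate of the full two-group
procedure; and a two-movie manifest-rerun for bit-identical determinism.
All randomness in a run flows from a single root seed recorded in the
manifest.

Remaining numerical conventions: coordinates are 0-based (row, col) with
time = frame × frame interval; pixel data are unsigned 16-bit on disk
(plain multi-page TIFF + JSON sidecar, T-major page order) and bit-exact
on round trip; filter borders replicate the edge pixel; assignment and
correlation ties break deterministically as described above.
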