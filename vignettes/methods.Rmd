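---
title: "Grading facial motor impairment from landmark video and speech: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading facial motor impairment from landmark video and speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic cohort does and does not emulate, and the
numerical and design choices made where the problem left the design open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The clinical problem and the modelling stance

Post-stroke dysarthria impairs articulation; the same lesions frequently
cause central facial paralysis — reduced and asymmetric facial
expressivity. Grading severity from speech alone fails exactly where it
matters most (severely affected patients produce little usable speech),
so the package treats facial motion as a compensatory measurement
channel and fuses three per-clip feature blocks — facial action unit
statistics (FAUF, 35-d), a graph embedding of the landmark geometry
(DFLGF, 128-d), and an 88-slot acoustic functional vector — into one
251-d vector classified into four severity classes.

The unit of analysis is a *clip*: a 2–6 s segment at 30 fps covering one
emotional expression (happy, sad, angry, or neutral), represented by a
stream of 68 facial landmarks. The package deliberately starts *after*
landmark detection: any 68-point detector can feed it, and none of the
scientific content below depends on which one.

## 2. Stage models and parameters

### Frame and clip quality control

A grayscale frame's luminance histogram `H(b)` (256 bins, conservation
`sum(counts) = W*H` is a tested invariant) yields the bright-pixel
fraction `p_high` above `t_high` and dark fraction `p_low` below
`t_low`. A frame is overexposed when `p_high > 0.05` and underexposed
when `p_low > 0.10`, both strictly. Defaults: `t_high = 250`;
`t_low = 50`, a choice of ours — the dark band has no canonical
threshold, and 50 mirrors 250's distance from the gray extremes; it is
configurable. Exposure is assessed on five equally spaced frames per
clip, and one flagged frame fails the clip: clip-level review is the
operational decision, frames are only evidence. Clips outside 2–6 s or
with more than ten occluded frames are dropped (occlusion flags are an
input column; automatic occlusion detection is out of scope). Color
input is converted by the BT.601 luma transform.

### Alignment

Eye centers are the midpoints of the eye-corner landmarks (36, 39) and
(42, 45); the face is rotated by the negative eye-line angle about the
inter-ocular midpoint, scaled so the inter-ocular distance is 0.4 of the
200 px canvas, and translated so the eye midline sits at (100, 80). The
0.4 fraction is a convention of ours (only the 200 px output size is
canonical); it leaves the jaw inside the canvas for every face the
generator produces. Verification angles: φ = eye line vs horizontal,
γ = nose bridge (landmarks 27→30) vs vertical, both folded into
(−90°, 90°]. Alignment is idempotent and exact on landmarks; images are
resampled by bilinear inverse warping. Grayscale normalization is a
min–max stretch to [0, 255].

Region index sets follow the 0-based iBUG-68 convention — brows 17–26,
eyes 36–47, nose 27–35, mouth 48–67, whole face 17–67. Printed variants
that overrun the standard groups (mouth ending at 68, brows at 28)
appear in parts of the literature; since the eye range 36–47 anchors the
iBUG convention unambiguously, we default to the canonical sets and make
every region overridable in `face_regions()`.

### Motion-amplitude keyframes

The neutral reference set takes five equally spaced frames
(`round(k*(T-1)/4)`) of the subject's first neutral clip (ties broken by
clip id, deterministically) and averages their region reference lengths
into `L0`. Averaging over the five frames, rather than trusting a single
reference frame, suppresses detector jitter in the baseline. Each
frame's region score is `|L_t - L0| / L0` and the overall amplitude is
the mean of the four regions; the series is smoothed by a centered
moving average with reflect padding, and the first and last 30% of
frames are excluded from candidacy (the middle 40% is eligible).

The smoothing window defaults to **9 frames (0.3 s at 30 fps)**. The
choice is driven by the structure of the noise: with landmark jitter of
σ = 0.5 px the absolute-value form of the score has a folded-noise floor
of ≈ 0.02, while weak expressions in severely affected patients peak
around 0.035. A window of 5 leaves the apex estimate wandering several
frames on such clips; 9 suppresses the floor's fluctuations by a further
√(9/5) while remaining short against the ≈ 0.5 s rise of an expression.
The window is a parameter everywhere it appears.

Keyframe selection takes the five highest smoothed local peaks among
candidates, enforcing a minimum index gap (`max(3, 5%)` of the clip) so
the five frames do not collapse onto one peak's shoulder, breaking ties
toward the earlier frame, and filling from the next-highest candidates
when fewer than five local peaks exist. Apex prediction quality is the
mean absolute frame error against annotation.

### Action unit features

Appearance features are HOG vectors over the aligned 200 px face:
12 × 12 cells × 31 unsigned orientation bins = 4464 values, each cell
L2-normalized; only the total dimensionality is canonical, the grid
factorization is ours. PCA (default target 1379 components, capped by
sample count) plus per-component standardization reduces them.
Geometric features concatenate the aligned coordinates, the four region
reference lengths, and the six pairwise anchor-center distances (146
values). Per-AU linear support vector regressors predict intensity on
the 0–5 FACS scale (clipped) and linear SVMs predict presence;
single-class presence targets and zero-variance intensity targets fall
back to constant models. Linear kernels are a deliberate choice: the
drive-to-displacement map of the synthetic cohort is affine, and convex
linear fits keep the stage fast and reproducible.

The 35-d FAUF holds 18 intensity slots and 17 presence slots. The 18/17
partition is declared in `au_slots()` (intensities carry AU28, presence
does not) and any other split can be configured — the counts, not the
membership, are the fixed part of the contract. Per-clip FAUF is the mean over
the clip's five keyframes; presence means read as occurrence
probabilities.

Group statistics aggregate FAUF to subject × emotion means and compare
severity groups per (emotion, slot) with two-sided Mann–Whitney rank-sum
tests over all pairs, Bonferroni-corrected within each (emotion, slot)
family and flagged at α = 0.05 and 0.01. Rank-sum replaces a paired
test because severity groups are independent samples of different
subjects; the test family is configurable.

### Landmark graphs and the graph encoder

Each region's landmarks are triangulated by an incremental
Bowyer–Watson construction. The empty-circumcircle property — no input
point strictly inside any triangle's circumcircle — is the defining
invariant and is tested against an independent brute-force enumerator on
a thousand fuzzed point sets. Numerical choices worth recording: the
in-circle test is the 3 × 3 determinant form (circumcenter distances
cancel catastrophically for slivers), triangles are kept counterclockwise
so the determinant's sign is meaningful, and the three construction-time
"super" vertices are treated symbolically as points at infinity in the
in-circle predicate — a finite super triangle of any size loses hull
slivers whose circumradius exceeds it. Exact duplicates are perturbed by
1e-6 px (seeded) or rejected, per configuration; fully collinear regions
are an error.

Edges carry Euclidean distances. For propagation the distances are
converted to Gaussian affinities `exp(-d^2 / sigma^2)` with σ the median
edge length — propagating raw distances would invert proximity
semantics — and symmetrically normalized with self-loops. Node features
are the region-centered aligned coordinates (scaled by 1/100). The
encoder is two propagation layers (2 → 16 → 32, ReLU), global max
pooling, and a fully connected 32 → 128 map: 4,816 parameters.

The encoder is *trained*: a linear softmax head is attached to the
embedding, the full chain is optimized by Adam under cross-entropy on
single-frame graphs labelled with severity, and the head is discarded.
Training data come from a cohort generated with a seed disjoint from any
evaluation cohort (default `encoder_seed + 1000`, 6 subjects per class ×
6 clips × 3 frames = 432 graphs), the same pre-trained-extractor
paradigm as the AU models: the encoder never sees evaluation subjects or
labels, and downstream embeddings remain deterministic. A frozen random
encoder is available (`gcn_encoder()` without training) and is
measurably weaker — an untrained random projection discards most of the
asymmetry signal that distinguishes severity classes.

Per-clip DFLGF is the mean of the five keyframe embeddings; the whole
face graph is the default input, with per-region embeddings available
for the region ablation.

### Acoustic features

The 88-slot schema follows the extended Geneva minimalistic parameter
set's functional layout (v02 naming): F0 and loudness carry ten
functionals each; jitter, shimmer, HNR, the two harmonic differences,
nine formant descriptors and the voiced spectral family carry
mean/normalized-σ pairs; five unvoiced means, six temporal rates, the
equivalent sound level, and all-frame spectral flux and MFCC 1–4 pairs
complete the 88. Externally computed CSVs are ingested against this
contract (missing slots are an error naming them; duplicated clip ids
keep the last row). The built-in extractor — 25 ms frames, 10 ms hop,
autocorrelation F0 with parabolic interpolation, RMS energy, FFT
spectral moments and slopes — fills the slots it can compute honestly
and derives the rest (formant proxies, cepstral stand-ins) from the same
descriptor algebra on the available tracks; it is an approximation for
synthetic audio, documented as such, and not bit-compatible with the
external toolbox.

### Fusion and the classifier

Blocks concatenate in FAUF → DFLGF → acoustic order: 251-d full, 163-d
visual-only, 88-d acoustic-only. The classifier is a fully connected
network with hidden sizes 128/64/32 and a 4-way softmax (descriptions of
this architecture as "4 hidden layers 128/64/32/4" count the output
layer), totalling 42,724
parameters on the fused input — 47,540 with the graph encoder, under the
50,000 budget. Training: Adam at learning rate 0.01, minibatches of 32,
cross-entropy, all inputs standardized with training-fold statistics.

At cohort scale (160 training clips) the network needs regularization
that a clinical-scale study, with an order of magnitude more clips,
would scarcely need. The defaults — decoupled weight decay 0.01, hidden dropout 0.2,
input Gaussian noise 0.2, input dropout 0.2, input-layer L1 of 3e-3,
label smoothing 0.1, cosine learning-rate decay over 200 fixed epochs —
were chosen by standard small-sample practice; two deserve explanation.
*Early stopping is off by default*: a 16-sample validation loss is so
noisy that patience-based stopping restores near-initial weights and
costs real accuracy; a fixed schedule with weight decay is the stabler
estimator (validation-based stopping remains available). *Modality
dropout* (0.5) zeroes whole feature blocks per training sample with
inverted rescaling: it is the standard multimodal device that forces the
fusion to degrade gracefully to its single channels, and without it the
acoustic block's uninformative slots act as memorization shortcuts that
cost the fused model several accuracy points relative to visual-only.

Evaluation follows the repeated stratified holdout protocol: five 80/20
splits with seeds 0–4, per-split accuracy and macro-averaged F1, means
over splits, and the pooled row-normalized confusion matrix. Baselines:
an RBF SVM with C = 4 and γ = 0.25 (the reference configuration; on
standardized 251-d inputs this γ is far above 1/p and the baseline is
accordingly weak, which we report rather than repair) and a 500-tree
random forest. `ablation_harness()` reproduces the region, feature-set
and channel comparison grids.

## 3. What the synthetic cohort emulates — and what it does not

`generate_cohort()` is first-class, tested code, not a fixture. Given a
seed it deterministically produces clips of 2–6 s at 30 fps across the
four emotions and four balanced severity classes (default: 5 subjects
per class × 10 clips = 200 clips, every subject with at least one
neutral clip). Each emotional clip drives a recipe of action units —
happy: AU6/AU12/AU25; angry: AU4/AU7/AU23; sad: AU1/AU15/AU4/AU7 —
through hand-specified sparse displacement fields over a canonical
68-point template built from geometric primitives. Severity modulates
the drives: perioral units attenuate stepwise
(1.0 / 0.75 / 0.5 / 0.3 for control / mild / moderate / severe), while
AU4/AU7 under negative emotions follow the non-monotonic clinical
pattern (1.0 / 0.65 / 0.45 / 0.7; severe above moderate). A Gaussian
rise–peak–fall envelope (σ = 7% of the clip) places a recorded apex in
the middle 40% of the clip. Patients additionally carry a static
right-sided mouth-corner droop (0 / 1.5 / 2.8 / 4 px, subject σ 0.3) —
resting asymmetry is the clinical hallmark of central facial paralysis
and is what makes neutral clips informative at all. Landmark jitter
(σ = 0.5 px), per-clip and per-frame rotation jitter (σ = 2°, 0.5°),
and subject-level amplitude effects (5%) provide nuisance variation.
Acoustic vectors are generated directly in feature space: independent
unit-variance noise on all 88 slots, a per-subject offset, and a class
shift of 0.85 σ per severity step on 12 spread-out slots.

The displacement-field magnitudes and class separations were calibrated
so that the *measured* per-channel accuracies of the full pipeline sit
at the operating point this class of instrument reaches on clinical data
(acoustic ≈ 0.78, visual ≈ 0.89, fused ≈ 0.92 at this cohort size) —
the generator is meant to emulate a dataset on which the method
demonstrably operates at that level, and both directions of the calibration were
exercised (the visual channel was *weakened* when a trained encoder made
it overshoot). The AU fields concentrate realistic motion on the eight
anchor landmarks that the amplitude measure can see (mouth corners, eye
corners, nose points), because region lengths are blind to everything
else.

What passing tests on this cohort do **not** show about real data: the
generator has no identity variation in face shape (severity, not
identity, is the only stable subject trait), no detector-specific error
structure (jitter is isotropic Gaussian, real landmark detectors fail
anisotropically and systematically under pose), no co-articulation
between speech and face, no occlusions, and acoustic features that are
Gaussian by construction rather than derived from pathological speech.
Results on the cohort validate the *machinery* — formulas, invariances,
recovery of planted effects at realistic signal-to-noise — not clinical
performance.

## 4. Degenerate inputs and tie-breaking

Coincident anchor landmarks, zero-length pose segments, all-collinear
regions and zero reference lengths raise errors naming the degeneracy.
Duplicate triangulation points are jittered (seeded) or rejected.
Flat amplitude series select the earliest candidates. Constant images
yield zero HOG vectors; zero-variance PCA input falls back to zero
scores with a warning; silent audio zeroes the voiced slots and flags
the result. All stochastic components take explicit seeds, and rerunning
any stage with the same configuration reproduces its artifacts
byte-for-byte.

## 5. Problem sizes used by the tests

The test suite and acceptance script run entirely on generated data: the
end-to-end check uses the default 200-clip cohort with the 432-graph
encoder pre-training cohort; the apex-recovery property uses two default
cohorts (320 emotional clips); the Delaunay oracle check uses 1000
fuzzed point sets of up to 25 points; unit tests use cohorts of 16–60
clips. These sizes were chosen so the full pipeline remains a
minutes-scale desk computation while keeping every class and emotion
populated.

## 6. Known limitations

* The classifier's accuracy at n = 200 clips has meaningful split-level
  variance (±3 points across cohort seeds); conclusions about channel
  orderings near ties should use more clips.
* The built-in acoustic extractor is a stand-in; for real recordings use
  an external functional extractor and `ingest_egemaps()`.
* The AU models are trained on the synthetic cohort's recorded drives;
  on real data one would substitute a FACS-trained AU toolkit's output
  via the same `vacp_au` interface.
* Manual occlusion review is replaced by a flag column; the package does
  not detect occlusions.
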