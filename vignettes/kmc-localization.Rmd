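---
title: "Grid-box lesion localization with Monte Carlo-trained networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-box lesion localization with Monte Carlo-trained networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmcloc)
```

## The model

Each grayscale image is partitioned into a 7×7 grid of 49 boxes, and a
network emits one score per box; the training target of a box is 1 when
the binary lesion mask contains at least one nonzero pixel inside it.
This trades pixel-level precision for a compact, directly supervised
formulation: no region proposals, no decoder, one output node per box.

The fully-connected family takes the image reduced to *r* × *r* pixels
(r ∈ {20, 30, 40, 60, 80}), divided by 255, flattened row-major. Hidden
nodes use the bipolar sigmoid `2 / (1 + exp(-x)) - 1`, output nodes the
logistic `1 / (1 + exp(-x))`; each node computes the weighted sum of the
previous layer plus its bias. Hidden depth is 1–3 and the first hidden
width 49, 98 or 196; layers beyond the first reuse the first layer's
width, which matches every printed configuration of the family (e.g.
49–49–49) — the 45-model sweep is the cross product of these choices.

The convolution variant is deliberately *tree-structured*: each 3×3
filter reads exactly one activation map (4 filters on the input, then 4
per map in the next two blocks: 4 + 16 + 64 = 84 filters, 756 kernel
weights, 84 biases), with RELU and 4×4 max-pooling after each block.
With a 256×256 input the final 64 maps of 4×4 flatten (map-major,
row-major within a map — the order is a free choice, fixed for
reproducibility) to 1024 inputs for a fully-connected head of one or two
49-node hidden layers. This per-map wiring, not the usual
summed-across-channels convolution, is what the 84-filter parameter
count implies, and the test suite pins it down by checking that zeroing
one first-block filter silences exactly its 16 third-block descendants.

## The training procedure

The Kim–Monte Carlo algorithm is a greedy derivative-free random search
over the unified pool of all weights and biases (convolution filters
included):

* initialization: weights uniform in [−0.2, +0.2], biases uniform in
  [0, +0.2];
* a *selection event* draws `ceiling(ratio * V)` distinct parameters,
  then makes 30 perturbation attempts: independent uniform increments in
  [−0.1, +0.1] at the selected indices, a bias that would become
  negative is flipped to its absolute value, and the candidate is kept
  only when the mean squared training error over the *full* training set
  strictly decreases;
* a *session* is 10 cycles with the selection ratio decaying
  geometrically from 15% to 1.5%.

Within an event, accepted attempts compound (each attempt perturbs the
current parameters at the same index set); rejected attempts are
reverted. Ties reject: accepting equal-error candidates would allow
drift along plateaus without progress. Together with the non-negative
bias initialization, the flip rule keeps every bias non-negative at
every accepted state — an invariant the tests assert over whole
sessions.

The printed constants of the schedule — 10 cycles, 15% → 1.5%, a
session ratio total of 900%, 30 attempts per event — do not uniquely
determine the event counts. The reading adopted here fixes each cycle's
ratio sum at 900%/10 = 90%, i.e. `n_events_c = round(0.9 / ratio_c)`,
giving 6 events in the first cycle, 60 in the last, 246 in total (about
7,400 error evaluations per session), and a session ratio sum within
[850%, 950%]. All four constants are exposed in `kmc_control()` and the
schedule is a single swappable function (`cycle_schedule()`).

The training error is the mean squared error over samples × 49 outputs.
Only "average training error" is prescribed; MSE is the conventional
choice for sigmoid outputs and makes sanity values exact (a zeroed
network outputs 0.5 everywhere, so all-zero targets give error 0.25).

Reproducibility: one R RNG stream is seeded once per session and
consumed sequentially — the selection draw of each event, then the
perturbation draws of its attempts — so a session is bit-identical given
(network, data, control, seed). The synthetic generator instead derives
one substream per image (`seed + image index`), so any single image can
be regenerated in isolation.

## Evaluation

All (image, box) pairs of the evaluated set form one pooled ROC
population. The AUC is computed as the Mann–Whitney concordance (ties
count ½), which equals the trapezoidal area under the empirical ROC; the
suite cross-checks it against exhaustive pair enumeration and against
pROC. The operating cutoff maximizes the Youden index over the distinct
observed scores, with ties broken toward the smallest (most sensitive)
cutoff; predictions are positive when the score *strictly* exceeds the
cutoff, matching the overlay rule. Ratios with empty denominators (which
degenerate synthetic cases can produce) are reported as `NaN` with a
warning, never as silent zeros. Because the cutoff is selected on the
evaluated set itself, the reported sensitivity/specificity are mildly
optimistic; the report should be read as an operating-point summary of
the ROC, not as an independent validation.

## The synthetic generator

The generator emulates what expert-marked radiographs provide to the
method: a structured grayscale background, a conspicuous lesion region,
and an exact binary mask. Defaults (chosen once; all overridable in
`synth_config()`):

| parameter | default | rationale |
|---|---|---|
| `image_size` | 512 px | source resolution of the emulated study images |
| `lesion_probability` | 1 | every study image contains a lesion |
| `lesion_count_range` | 1–2 | isolated lesions, limited overlap |
| `lesion_axis_range` | 10–24% of side | lesions span several grid boxes |
| `intensity_shift` | +80 gray levels | 10× the noise sd; see below |
| `background_kind` | gradient + blobs | smooth vertical gradient (60–190) plus 4–8 Gaussian blobs of amplitude ±15 |
| `noise_sd` | 8 gray levels | i.i.d. pixel noise, clipped to [0, 255] |

Lesions are filled axis-aligned ellipses (a pixel is lesion iff its
center satisfies the ellipse inequality), so masks are exact by
construction. The contrast default deserves a note: what is under test
is the fixed optimization budget of the training algorithm, not
radiographic realism (explicitly a non-goal — no ribs, no anatomy, no
imaging physics). The lesion must therefore be clearly detectable
against the background texture: +80 gray levels is 10× the noise sd and
about 5× the blob amplitude, comfortably above the ≥3× noise-sd
learnability floor the generator guarantees. Passing the learning tests
on this task shows that the trainer can extract a detectable signal
under its budget; it does *not* show that the method reaches any
particular performance on real radiographs, where contrast is lower,
backgrounds are anatomical, and labels are imperfect.

## Numerical choices

* **Grid boundaries.** For side `s`, boundary k sits at
  `round(k * s / 7)` (half-up), intervals half-open — an exhaustive,
  disjoint tiling for any side ≥ 7, not only multiples of 7. The
  rendered overlay rectangles use the same function, so drawn extents
  and target boxes can never disagree.
* **Resolution reduction.** Exact area-average (block-mean) resampling,
  implemented as a pair of sparse row/column weight matrices. It is
  linear (so it commutes with the /255 normalization, a tested
  property), preserves the input range, and is trivially
  oracle-checkable; interpolation kernels with ringing would be none of
  these.
* **Sigmoid overflow.** Arguments to `exp` are clamped to ±500, where
  both sigmoids already saturate exactly in double precision.
* **Serialization.** Model JSON stores shapes plus row-major values at
  17 significant digits, which round-trips IEEE doubles exactly.
* **Degenerate evaluation.** A constant scorer yields AUC ½ and a
  maximal Youden index of 0; `evaluate_model()` flags this cutoff as
  degenerate rather than reporting it silently.

## Problem sizes

The test suite and the acceptance script run the study at reduced scale,
chosen so the full pipeline stays comfortably interactive on one CPU:
196×196-pixel images (the grid and resampling are size-agnostic), 200
training and 60 test images for the learning checks (three seeds of the
20×20/49 network; the held-out pool is 60 × 49 = 2,940 boxes), 50 images
for the trainer-invariant checks, and a two-architecture sweep
({20, 30} × width 49 × depth 1) for the end-to-end check. The
full-scale study (512×512 images, 800/200 split, all 45 architectures,
plus the convolution variants) runs with the same code via
`synth_config()`, `enumerate_sweep()` and `run_sweep()`.

## Limitations

* Grid-box supervision makes a box positive for a single lesion pixel;
  boxes barely clipped by a lesion edge carry almost no intensity signal
  and bound the attainable pooled AUC below 1 even for an ideal scorer.
* The greedy accept rule cannot escape local minima; performance under
  the fixed 900% budget depends on task contrast, and no early stopping
  or validation-based selection is provided (by design — the procedure
  under study has none).
* The cutoff is chosen on the evaluated set (see above).
* The synthetic backgrounds are smooth fields, not anatomy; conclusions
  transfer to real radiographs only qualitatively.
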