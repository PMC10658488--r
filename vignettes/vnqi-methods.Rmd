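---
title: "Scoring engineered vascular networks by predicted tissue oxygenation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring engineered vascular networks by predicted tissue oxygenation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vascularized microphysiological systems (vMPS, "organ-on-chip" devices) rely
on self-assembled capillary networks to oxygenate the tissue they carry, yet
network quality is usually reported through simple morphological metrics —
vessel coverage, total length, branchpoint counts — that relate only loosely
to the physiological function that matters, oxygen delivery. `vnqi`
implements a scoring approach that closes this gap: a pair of chained neural
networks is trained to map six standard morphological metrics of a binary
vessel mask onto the tissue oxygen concentration that a physics-based
transport model computes for the same mask. The chained model's output, the
vascular network quality index (VNQI), is a single number on `[0, 1]` — from
poorly to fully oxygenated tissue — that can be evaluated from morphology
alone, at negligible cost, once training is done.

Four stages are involved, each an exported module:

1. a seeded **generator** of synthetic vasculogenesis-like binary masks
   (`generate_mask()`, `generate_cohort()`),
2. **morphometrics** reducing a mask to six scalar features
   (`measure_morphology()`),
3. an **oxygen oracle** — a steady-state reaction–diffusion solver — that
   labels each mask with normalized intravascular and extravascular oxygen,
   OXY~V~ and OXY~T~ (`solve_oxygen()`, `summarize_oxygen()`),
4. the **model harness**: chained training, baseline architectures, and the
   evaluation suite (`fit_chain()`, `fit_baseline()`, `predict_vnqi()`,
   `compare_architectures()`, `stability_analysis()`, `learning_curve()`).

`run_pipeline()` chains all of it behind one master seed and writes a hashed
manifest, so any reported number is reproducible bit for bit.

## The synthetic cohort: what it emulates and what it does not

Real vMPS cohorts derive their diversity from wet-lab determinants —
endothelial cell source and density, matrix stiffness, growth-factor
supplementation. No public image set accompanies that protocol, so the
package ships a generator whose knobs are one-to-one analogs of those
determinants: `n_seed_points` (cell density), `connect_prob` and the
k-nearest-neighbour proximity graph (propensity to form connected networks),
`diameter_mean`/`diameter_sd` and `dropout_frac` (matrix effects on lumen
calibre and network sparsity), and `spanning_bias` (anchorage to the two
lateral media channels). Masks default to 256 × 256 pixels at 4 µm/pixel — a
1 × 1 mm field of view, the scale at which such networks are usually imaged —
and are strictly binary by construction (no anti-aliasing), so the
morphometrics are well defined.

Cohorts are drawn by sampling each knob uniformly from the ranges in
`default_cohort_jitter()`. The ranges were calibrated once so that a default
100-mask cohort spans vessel coverage from below 0.05 to above 0.4 — sparse,
fragmented nets up to dense spanning ones — and were then left alone; they
are part of the study conditions, not a tuning dial.

What the generator does **not** emulate: vasculogenesis dynamics, 3D lumen
geometry, immunostaining appearance, segmentation noise. Passing tests on
synthetic cohorts therefore demonstrate that the method recovers the
morphology-to-oxygen mapping when the masks are clean and the oracle is the
ground truth; they do not certify performance on segmented microscopy
images, where mask errors propagate into both features and labels.

## Morphometrics conventions

The six features are the ones a standard vessel-architecture tool reports:
vessel coverage (area fraction), total vessel length, segment count,
branchpoint count, mean segment length, mean segment diameter. Published
tools do not pin down every low-level convention, so this package fixes
them explicitly:

* Zhang–Suen thinning to a one-pixel, 8-connected skeleton; terminal spurs
  shorter than `spur_len_px = 5` pixels are pruned (skeletonization
  artifacts at stroke ends), configurable.
* Skeleton pixels of degree ≠ 2 are nodes; *adjacent* degree ≥ 3 pixels are
  merged into a single branchpoint node at their centroid, because thinning
  renders one anatomical junction as a small pixel cluster.
* Segment length sums skeleton steps with diagonal steps weighted √2 ×
  pixel pitch.
* Segment diameter is twice the Euclidean distance transform of the mask
  sampled along the segment's skeleton pixels, times the pitch. On an ideal
  bar of width *w* this convention reads *w* + 1 pixels (the transform
  counts to the first background pixel); all tests carry the corresponding
  ±1 px tolerance.
* Four further metrics often reported by morphology tools (vessel length
  density, mean tortuosity, mean valency, maximum diffusion distance) are
  deliberately not computed; the six above are the model's input contract.

These conventions are validated against closed-form values on a library of
constructed shapes (bars, crosses, combs, grids) and against brute-force
degree censuses of the skeleton.

## The oxygen oracle

Ground-truth labels come from a deterministic finite-difference model of
steady oxygen transport on the mask's own pixel grid:

$$\nabla \cdot (D(x)\nabla c) - k(x)\,c = 0,$$

with piecewise-constant coefficients by pixel class — `D_vessel`,
`k_vessel` inside the lumen, `D_tissue`, `k_tissue` in the gel — Dirichlet
`c = c0 = 1` on the two lateral edges (the media channels of the chip
geometry) and zero flux on the others. The five-point stencil uses
harmonic-mean interface diffusivities; eliminating the Dirichlet unknowns
leaves a symmetric positive-definite sparse system solved directly
(CHOLMOD). Defaults: `D_tissue` = 10³ µm²/s, `D_vessel` = 10⁵ µm²/s,
`k_tissue` = 10⁻² s⁻¹, `k_vessel` = 10⁻³ s⁻¹. The ratios, not the absolute
values, carry the behaviour: vessels are low-resistance conduits with weak
endothelial consumption, so spanning, dense networks raise tissue oxygen —
with a tissue penetration depth $\sqrt{D_\mathrm{tissue}/k_\mathrm{tissue}}
\approx 316\ \mu m$ against a 1 mm gel width, avascular regions are
markedly hypoxic. Oxygen may enter both through gel faces and through
vessel lumens touching them; the model does not restrict entry to perfused
lumens.

First-order (linear) consumption was chosen over Michaelis–Menten kinetics
so that an exact closed form exists for the avascular slab,
$c(x) = c_0 \cosh(\lambda(x - L/2))/\cosh(\lambda L/2)$ with
$\lambda = \sqrt{k/D}$, which serves as an independent oracle: the numeric
field must match it within 1% at the default resolution, and the error must
shrink under grid refinement. Two structural invariants are asserted on
every solve: the discrete maximum principle (field in `[0, c0]`; round-off
is clamped) and monotonicity of tissue oxygen under vessel addition.

OXY~V~ and OXY~T~ are the area averages of the field over vessel and
non-vessel pixels, divided by `c0`; an empty pixel class reports 0 by
convention.

## The chained model

NN1 regresses OXY~V~ on the six standardized metrics. NN2 regresses OXY~T~
on the metrics plus OXY~V~ — trained with the *oracle* OXY~V~ (teacher
forcing), chained onto NN1's prediction at inference. VNQI is the chained
output clipped to `[0, 1]`; only the final output is clipped. The rationale
for the chain is physiological: OXY~V~ summarizes how much oxygen the
network itself carries, which is the proximate driver of tissue delivery,
so routing morphology through a predicted OXY~V~ gives NN2 a physically
meaningful intermediate feature while keeping the deployed model free of
any transport computation.

Training choices that the underlying studies leave open are fixed here as
package defaults:

* **Architecture search.** Auto-ML tools choose depth and width with an
  unstated budget. This package substitutes a seeded random search over
  single-hidden-layer perceptrons (`nnet`) with widths {4, 8, 16, 32, 64}
  and weight decay {10⁻⁴, 10⁻³, 10⁻²}, budget 10 per network, candidates
  ranked by MSE on an inner 20% validation split and the winner refit on
  the full training set. Single-hidden-layer networks are universal
  approximators and are ample for a 6-to-1 smooth regression at n = 500;
  the search, the inner split, and the weight initialization all derive
  from one spec seed, so a fit is a pure function of (data, spec).
* **Standardization.** Feature means and standard deviations are computed
  on the training set only and stored with the model; the OXY~V~ input of
  NN2 is standardized with the same training statistics whether it is the
  oracle value (training) or NN1's output (inference).
* **Splits.** 80/20, seeded shuffle, training size `ceiling(0.8 n)`; all
  five architectures in a comparison share one split. Correlation rankings
  are computed over all samples (train + test), matching how the index is
  meant to be used downstream.
* **Metrics.** R² = 1 − SSE/SST, MAE, MSE, RMSE; residuals are measured −
  predicted. R² is reported as missing (with a warning) when the target has
  zero variance rather than forced to 0.

The four baseline architectures — multi-output (OXY~V~ and OXY~T~ jointly),
single-output OXY~V~, single-output OXY~T~, and OXY~T~ from morphology plus
the *true* OXY~V~ — are trained under the identical protocol by
`fit_baseline()`; the last of these is the ceiling the chain aims for, and
the single-output OXY~T~ network is the floor it must beat. The
multi-output baseline is scored on its pooled residuals across both
outputs.

## Evaluation suite and problem sizes

The package's own evaluation harness mirrors how such a model should be
audited, and the test suite runs all of it at the default study scale of a
500-sample cohort (80/20 split, so held-out n = 100):

* **Architecture comparison** (`compare_architectures()`): one table, five
  rows, R²/MAE/MSE/RMSE each.
* **Correlation ranking** (`pearson_ranking()`): Pearson r of each metric
  and of VNQI against measured OXY~T~, optionally per experimental group.
  No multiplicity correction is applied to these descriptive tables.
* **Repartitioning stability** (`stability_analysis()`): ten seeded
  repartitionings, mean ± sd of each accuracy metric for NN1 and for NN2
  (teacher-forced, as trained). The sd's are expected to sit near zero; the
  suite asserts ≤ 0.03 with a reduced search budget of 4.
* **Learning curve** (`learning_curve()`): chained validation MAE versus
  training size over a fixed validation split; the curve should plateau by
  300 samples (the basis for considering 500 sufficient).

Smoke-scale invariant tests (maximum principle over 100 masks,
superset-pair monotonicity, sweeps) run on 96 × 96 masks; all
accuracy-bearing analyses use the default 256 × 256 geometry.

## Numerical and degenerate-input choices

* Empty masks are valid everywhere: zero metrics, OXY~V~ = 0 by convention,
  an empty graph rather than an error.
* Non-binary rasters are rejected with an error, never silently thresholded.
* Pure skeleton cycles (rings with no junction) are registered as self-loop
  segments on a synthetic node so their length is counted; tiny self-loops
  (≤ 3 pixels) at junctions are discarded as thinning fuzz.
* The linear solver verifies its relative residual (tolerance 10⁻⁸) and
  errors on failure rather than returning an unconverged field.
* Seeds: one master seed fans out to every stage through a fixed counter
  hash (`derive_seed()`), keeping all derived seeds in the 32-bit range;
  reruns reproduce identical CSV hashes.

## Known limitations

* VNQI is trained against a 2D, first-order-kinetics transport model;
  absolute values are only as physiological as that oracle. Relative
  ranking of networks is the intended use.
* The morphometrics assume clean binary masks; segmentation artifacts
  (holes, speckles) will surface as spurious segments despite spur pruning.
* The chained model's advantage over the morphology-only baseline depends
  on how much OXY~V~ mediates the morphology–OXY~T~ relationship in the
  cohort at hand; on cohorts where the six metrics already saturate the
  predictable variance the two architectures converge.
* Single-hidden-layer networks were deliberately preferred to deep stacks;
  if the feature–label relationship were less smooth (e.g., raw-image
  inputs), the search space would need widening.
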