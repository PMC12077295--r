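---
title: "Detecting antibodies in cryo-EM maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting antibodies in cryo-EM maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cryoab)
```

## The problem

Interpreting a cryo-EM reconstruction of an antibody–antigen complex starts
with a deceptively simple question: how many antibody fragments does the map
contain, and where are they? Answering it by hand (rigid docking, visual
inspection) is slow and error-prone, especially below ~4 Å resolution where
sequence-tracing tools stop working. `cryoab` treats the question as **3D
object detection with a strong shape prior**: antibody variable regions (the
Fv of a Fab, or a single-domain VHH) are structurally so conserved that any
instance is well approximated by a *rigid placement of one fixed template*.
Detection then amounts to predicting a small set of rigid transforms
`(R, T)` — six numbers per antibody — instead of thousands of atomic
coordinates.

## Map conventions

A `density_grid` is a node-centered lattice: node `(i, j, k)` (0-based) sits
at `origin + (i, j, k) * voxel` Å. Maps are preprocessed the way curated
corpora are built: crop around the region of interest with a 25 Å margin
(`crop_to_structure`, rounding outward to whole nodes so the margin is never
shrunk), resample to 2 Å voxels (`resample_grid`, trilinear; the resampled
lattice is the largest one that fits inside the source extent, so constants
survive exactly and no values are invented beyond the data), and normalize by
zeroing negative density and dividing by the maximum (`normalize_grid`).
MRC/CCP4 reading honors the axis-permutation fields and prefers the `ORIGIN`
record over start indices when it is non-zero, matching what visualization
tools do.

## Pose encoding

The template is stored centered, with the unit vector `u_z` pointing from its
center of mass toward the CDR tips. A placement `(R, T)` is encoded as:

* **direction** `p = R u_z` — where the antibody binds. Because canonical
  antigen binding happens through the CDRs, this vector is the physically
  meaningful, easier-to-learn part of the rotation;
* **residual angle** `theta` — the in-plane rotation about `p`, with the
  fixed convention `R = R_axis(p, theta) · R_min(u_z -> p)`, where `R_min`
  is the minimal rotation taking `u_z` onto `p`. The convention is
  self-consistent and exactly round-trippable, which is all training needs;
  the antipodal degeneracy `p = -u_z` is resolved by a fixed 180° rotation
  about the template x-axis. `theta` is regressed as
  `(cos theta, sin theta)` to avoid the branch cut;
* **translation** `T = cell_corner + T_loc`: an 8 Å occupancy grid (4 input
  voxels per cell) is overlaid on the map; the owner cell is
  `floor((T - origin)/8)` and `T_loc` is the offset inside it. This keeps
  every regressed quantity small and makes the encoding translation
  covariant.

Together with a Fab/VHH indicator this fills 10 channels per cell
(`encode_poses` / `decode_cell`); ground truth marks only the single owner
cell. The round trip is exact to floating point, which the tests assert for
thousands of random poses.

## Network

`fθ` is a fully convolutional 3D UNet (`unet_config`): `depth` encoder levels
of two 3×3×3 convolutions (instance normalization, leaky ReLU 0.1), 2× max
pooling between levels, channel widths `base_channels · 2^level`, and a
decoder that upsamples (nearest-neighbor + skip concatenation) only until the
output sits at one cell per `stride = 4` input voxels, where a 1×1×1 head
emits the 10 channels; occupancy and class pass through sigmoids. Inputs of
arbitrary size are zero-padded to a multiple of `2^depth` and the prediction
cropped back to `ceiling(extent / stride)` cells, so one trained model serves
any map size. Everything — convolutions (im2col + GEMM in C++), pooling,
upsampling, instance norm — has a hand-derived backward pass, verified
against finite differences in the test suite.

Training augmentation applies one of the 8 axis-aligned proper rotations (the
subgroup generated by 90° rotations about z and the 180° rotation about x —
"the eight rotations of a grid" is ambiguous since the full proper cubic
group has 24 elements; this subgroup is the documented choice) and crops
whole cells from the sides. `augment_example` implements the conventional
0–3-cell crop; `train_detector` defaults to at most 1 cell per side
(`crop_max = 1`) because on ~10-cell desk-scale maps a 3-cell crop frequently
removes an antibody's owner cell while leaving most of its density visible,
i.e. manufactures mislabeled examples, whereas on corpus-scale maps 3 cells
is proportionally tiny. Rather than rotating channels individually, the
augmentation decodes the target to poses, transforms map and poses rigidly,
and re-encodes — consistency of all vector channels is then automatic.

## Loss

`L_tot = L1 + L2 + λ_s Σ_A (L3 + L4 + L5 + L6)` with `γ = 4`, `λ = 30`,
`λ_s = 0.2`, `λ_n = 2.5`:

* **L1** — weighted binary focal loss over the occupancy channel,
  `-[λ y (1-p)^γ log p + (1-y) p^γ log(1-p)]`, handling the extreme
  imbalance (a handful of occupied cells among thousands). Written this way
  the loss is non-negative and minimized at the target; probabilities are
  clamped to `[1e-7, 1-1e-7]` before logs.
* **L2** — debiased Sinkhorn divergence
  `S_ε(a,b) = OT_ε(a,b) - ½OT_ε(a,a) - ½OT_ε(b,b)` between the two occupancy
  channels viewed as probability measures on cell centers (squared Euclidean
  cost, default entropic scale `ot_blur = 8` Å — one cell). A pointwise loss
  cannot tell "one cell off" from "opposite side of the map"; the transport
  term gives every cell a gradient proportional to its distance from real
  antibody mass, and in practice concentrates the prediction into a single
  blob per object. `1e-8` is added to every cell before normalization so an
  all-zero prediction stays a valid measure. The implementation is
  log-domain; on a regular grid the squared-Euclidean kernel factorizes, so
  each softmin is one exp-shift plus three small per-axis GEMMs, with the
  entropic scale annealed from the grid diameter down to `ot_blur` by
  `ot_scaling = 0.5` and a row-shifted fallback when the scale is tiny. The
  gradient is the converged dual potential difference `f_ab - p_aa`, chained
  through the mass normalization; a finite-difference test pins it down.
* **L3–L5** — at ground-truth cells only: mean squared error on `T_loc`, and
  `1 - <v, target> + (||v|| - 1)²` for the direction (3D) and angle (2D)
  vectors. The norm penalty keeps regressed vectors near unit length without
  a numerically unstable normalization; the documented side effect is that
  the loss's minimum over colinear vectors sits at norm 1.5 (value −0.25),
  not at the unit target — harmless in practice and asserted as a bound in
  the tests rather than "fixed".
* **L6** — focal loss on the VHH-vs-Fab probability with `λ_n = 1000/400`,
  the VHH:Fab ratio of curated corpora.

For a map with no antibodies the transport term is dropped (an empty target
is not a probability measure) and L1 alone supervises the occupancy.

## Non-maximal suppression by persistence

At 8 Å cells, two adjacent cells cannot both contain an antibody center, so
clusters of high occupancy are duplicates of one detection.
`persistence_components` computes 0-dimensional superlevel-set persistence
with 6-connectivity: sweeping a threshold down from the maximum, each local
maximum births a component; when components meet at a saddle the younger
(lower-born) dies — the elder rule — recording `lifetime = birth - death`;
the global survivor dies at the grid minimum so a single peak still gets a
usable finite lifetime. Lifetimes combine *how confident* a peak is with
*how separated* it is from stronger peaks, which is exactly the ranking a
detector wants. Ties are broken lexicographically by cell index, making the
output fully deterministic. Selection is either `num` (top-k, when the count
is known) or `thresh` (all lifetimes > 0.2, the fully automatic default).
Non-maximal cells generate zero-length bars, which are not components and
are dropped — except that a constant grid still reports its single
component. The implementation is checked against an independent
threshold-sweep flood-fill oracle, including births, deaths and seeds.

## Evaluation

Predictions and ground truth are paired by minimum-total-distance assignment
on center-of-mass distances (Hungarian algorithm via `clue::solve_LSAP` on a
sentinel-padded square matrix; an exhaustive permutation search is the test
oracle), *then* thresholded: pairs closer than 10 Å are true positives.
`f1_scores` reports both the antibody-pooled F1 and the per-system average
(a system with many antibodies should not dominate); a system with neither
truth nor predictions counts as F1 = 1, the sensible true-negative
convention. For matched pairs the harness also reports center distance,
placement RMSD (template transformed by both poses, no re-superposition),
the angle between binding directions, and the wrapped residual-angle error.

## Synthetic data

`simulate_map` is pure scaffolding — it stands in for a curated experimental
corpus so that every module is exercisable without downloads — and is
labeled as such. It emulates: rigid placements of a deterministic
pseudo-template (two ~25 Å lobes along `u_z` for the Fv, laterally offset so
the in-plane angle is identifiable; one lobe for VHH; ~200/100
pseudo-atoms), Haar-uniform rotations, uniform positions with a hard-core
separation, antigen-like decoy blobs, Gaussian-smeared density
(`σ = resolution / 2.355`, the FWHM convention; default σ 3.4 Å ≈ 8 Å
resolution), additive Gaussian noise scaled to the peak, and the standard
normalization. Defaults: 2 Å voxels, antibody counts drawn from a Poisson
with mean 2.25 truncated to 0–6 (the corpus statistic), VHH fraction 0.3.
Two deliberate realism choices:

* **Separation.** The no-collision requirement is ≥ 20 Å, but two rigid
  ~25 Å domains cannot interpenetrate; the default minimum separation is
  their ~30 Å contact distance.
* **Decoys.** Decoy blobs reuse the lobe shape at scales drawn away from 1
  (0.55–0.8 or 1.25–1.5): negatives should be non-trivial but must not be
  congruent to the VHH template, otherwise the occupancy labels become
  unlearnable by construction.

What the generator does **not** emulate: CTF and Fourier-space noise
correlations, resolution anisotropy, conformational heterogeneity, partial
occupancy, and real antigen architecture. Passing the end-to-end test
therefore shows that the pipeline — encoding, network, loss, NMS, decoding,
matching — is implemented coherently and can be trained; it does not certify
performance on experimental maps.

## The desk-scale recovery experiment

The headline self-check (`scripts/acceptance.R`, also a test) trains the
detector from scratch and measures recovery on held-out maps:

* maps: 78 Å cubes (40³ voxels, 10³ cells), 1–2 antibodies each (VHH
  fraction 0.3), 0–1 decoys, σ = 4 Å, noise 5% of peak, 50 training and 20
  held-out maps;
* model: depth 3, 8 base channels — the smallest UNet whose receptive field
  at the 8 Å output stride comfortably covers a ~50 Å antibody;
* training: Adam, 60 epochs with a stepped learning-rate decay
  (2e-3 → 1e-3 → 3e-4 → 1e-4), rotation augmentation with 1-cell crops,
  one map per step;
* evaluation: fully automatic `thresh(0.2)` detection, Hungarian matching
  at 10 Å.

These sizes were chosen so the whole experiment runs in minutes on one CPU
while leaving the task non-trivial (multiple objects, decoys, noise,
arbitrary orientations). The map extent is deliberately a multiple of the
cell size and of the network's padding unit, so no compute is spent on
padding.

## Numerical choices and degenerate inputs

* Probability clamp `1e-7` before all logarithms; the Sinkhorn guard mass
  `1e-8`; instance-norm variance floor `1e-5`.
* Sinkhorn convergence: potentials (including the debiasing ones) iterated
  to a sup-norm tolerance of `1e-9` for loss values, relaxed to `0.1`
  inside the training loop where only stochastic gradients matter (relative
  gradient error ~1e-3 at half the cost).
* An all-non-positive map normalizes to all zeros rather than dividing by
  zero; an all-zero prediction is still a valid transport measure thanks to
  the guard mass; a constant occupancy grid yields exactly one persistence
  component of lifetime 0.
* Degenerate decoded cells (zero-norm direction) raise an error rather than
  silently normalizing noise.
* Rectangular assignment problems are padded with a large sentinel cost;
  sentinel pairs are reported as unmatched.
* All randomness (simulation, initialization, example order, augmentation)
  flows through R's RNG, so a seed reproduces a run bit-for-bit.

## Known limitations

* The synthetic density model is far simpler than experimental maps; no
  claim about real-map accuracy follows from the desk-scale experiment.
* The template is rigid: strongly bent Fv elbows or non-canonical VHH
  shapes would be found (occupancy) but placed with higher RMSD.
* Persistence NMS assumes one center per basin; two antibodies closer than
  about one cell diagonal would merge (physically impossible at 8 Å cells).
* Training at one map per step with instance normalization is the
  conventional small-memory choice, not a tuned optimum; hyper-parameters
  live in `unet_config` / `loss_weights` / `train_detector` arguments and
  are deliberately few.
* No local rigid refinement of placements is performed after decoding; the
  reported poses are the network's regression. A refinement hook would slot
  naturally between decoding and PDB emission.
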