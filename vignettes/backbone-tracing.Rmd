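---
title: "Tracing protein backbones in cryo-EM density maps"
author: "cryotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing protein backbones in cryo-EM density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryotrace)
```

## The problem

A cryo-EM reconstruction is a 3D grid of electron-density values. At
2.5-4.5 Å resolution the polypeptide backbone is visible as a tube of
elevated density, but individual atoms are not resolved, so placing
the Cα atom of each residue — the first step toward an atomic model —
is a hard interpretation problem. `cryotrace` implements a
segmentation-then-tracing approach: a cascade of three small 3D
convolutional networks classifies every voxel (secondary-structure
class, backbone, Cα), a tabu-search path walker chains high-confidence
Cα positions into traces, graph-based pruning removes side-chain and
shortcut artifacts, detected α-helices are re-idealized about their
screw axis, and the result is scored against ground truth with
one-to-one Cα matching metrics.

The package covers the full simulate → train → predict → trace →
refine → score loop at desk scale. It does not attempt sequence
assignment (mapping residue identities onto the trace), B-factor-aware
simulation, or large-scale benchmark accuracy, which would require
training on a corpus of thousands of experimental-quality structures.

## Simulated data

Training and test maps are simulated from atomic models as sums of
identical isotropic Gaussians, one per atom, evaluated on a 1 Å grid:

$$\rho(x) = \sum_a \exp\left(-\frac{\lVert x - x_a\rVert^2}{2\sigma^2}\right),
\qquad \sigma = \frac{\text{resolution}}{\pi\sqrt{2}}.$$

The σ convention makes the Fourier amplitude of a point source fall to
1/e at spatial frequency 1/resolution; it is one of several
conventions in circulation, so `simulate_density()` records it in the
map attributes and accepts an explicit `sigma` override. Label volumes
are generated geometrically rather than by simulating filtered
sub-models: a voxel is Cα-positive within 1.0 Å of a Cα atom and
backbone-positive within 1.2 Å of any N/Cα/C atom, which gives clean
binary cross-entropy targets that do not depend on the simulation
resolution. Voxels that are neither helix- nor sheet-labeled fall into
the loop/turn class of the 3-class group, so the three SSE targets
partition every voxel.

### The synthetic protein generator

`generate_synthetic_protein()` builds self-avoiding Cα chains from a
segment plan (helix/strand/loop lengths). Helices follow ideal
geometry — rise 1.5 Å per residue, radius 2.3 Å, angular advance
1.149 rad per Å of axis (≈98.7° per residue, the canonical α-helix
pitch; this makes consecutive Cα-Cα distances exactly 3.80 Å and keeps
the generator consistent with the helix idealizer below). Strands
advance 3.5 Å per residue with an alternating 0.8 Å zig-zag; loops
are rejection-sampled smooth random walks with 3.8 Å steps, retried
until no two non-consecutive Cα come within 3.0 Å. Pseudo C and N
atoms are interpolated at thirds between consecutive Cα so the
backbone class has realistic support between Cα positions.

What the generator does *not* emulate: side-chain density, B-factor
variation, map anisotropy, solvent noise, and the local resolution
heterogeneity of experimental maps. Tests passing on these fixtures
therefore demonstrate the correctness of the pipeline machinery —
segmentation targets, tracing, refinement, scoring — not experimental-
map accuracy.

## Normalization and cubing

`preprocess_map()` applies the three value transforms in order:
voxels below the user threshold are zeroed; remaining values are
divided by the median of the positive values (after thresholding the
global median would typically be zero); values are capped at the 98th
percentile of the positive values. The percentile is computed as an
order statistic (quantile type 1), which makes the transform exactly
idempotent. Experimental maps are first resampled to 1 Å voxels by
trilinear interpolation (`resample_to_unit_voxel()`), which is exact
on linear fields and therefore testable against an analytic ramp.

Maps of arbitrary size pass through the network as overlapping 64³
cubes whose corners advance with stride 50, i.e. a 7-voxel margin on
every face; only each cube's central 50³ core contributes to the
stitched output, so cube boundaries never create seams
(`split_into_cubes()` / `stitch_cubes()` are exact inverses). The
training-set builder stores per-sample volumes (density plus the five
label volumes, with resolution/rotation attributes) in a single
serialized file using R's native format; the documented layout mirrors
one group per sample. Axis-aligned rotation augmentation
(0°/90°/180°/270° about z) is applied jointly to density and labels.

## The cascaded network

Three four-layer 3D CNNs run in cascade: the SSE stage sees the
density (1 channel); the backbone stage sees density plus the three
SSE probabilities (4 channels); the Cα stage sees density, SSE and
backbone probabilities (6 channels). Every stage uses filters
32/64/64/n with n its class count, stride 1 and zero padding, so
output volumes are congruent with the input. Layers 2-3 are dilated
(rate 2) and followed by leaky-ReLU with slope 0.1; kernels are 5³
for the SSE and backbone stages and 4³ for the Cα stage. Softmax
heads yield per-class confidences; the 3-class SSE probabilities sum
to one per voxel and the two-class heads are reported as their
positive-class probability.

Training choices the architecture description leaves open, fixed here
as package defaults: Adam with learning rate 1e-4 and batch size one
cube; the joint loss is the sum of the three per-voxel cross-entropies
with inverse-frequency class weights computed from the dataset
(Cα-positive voxels are rare — about 0.5% of a typical cube — and an
unweighted loss collapses to the background class); gradients flow
end-to-end through the forwarded probability maps so all three stages
train simultaneously (a `stop_gradient` flag isolates them). Both
channels of each two-class head are forwarded to later stages.
Convolutions are evaluated as shifted-volume GEMMs in single
precision via the BLAS, which keeps desk-scale training (tens of
optimizer steps on 32³ cubes) in the minutes range on one CPU; the
test suite verifies the kernels against an independent direct
convolution and numeric gradients.

The package trains at toy scale only (small synthetic proteins, 32³
sample cubes). The tests assert trainability — the loss halves within
30 steps and a single sample can be overfit — not generalization.

One geometric caveat: the cascade's one-sided receptive field is
30-36 voxels (three stages of two dilated layers each), which exceeds
the 7-voxel cube overlap. Stitched confidence maps therefore carry
mild cube-boundary artifacts — an approximation inherited from the
cube scheme itself. The invariance tests reflect this: translation
equivariance is asserted exactly per stage (beyond its own 12-voxel
receptive field) and padding invariance for the full cascade in the
deep interior of an uncubed volume.

## Oracle confidence maps

`oracle_confidence()` produces the confidence maps an ideal network
would emit, directly from ground-truth coordinates: Gaussian splats
(σ = 0.8 Å) at Cα positions normalized so the voxel nearest each atom
reads exactly 1, the same over N/Cα/C for the backbone map, and
one-hot SSE labels by nearest residue where backbone confidence is
appreciable (uniform 1/3 elsewhere). The 0.8 Å width keeps Cα peaks
at bonding distance (≥2.8 Å) separable as distinct local maxima.
Everything downstream of the network — walking, graph refinement,
helix idealization, metrics — is developed and tested against this
oracle, decoupling those stages from training quality.

## Path walking

Candidate Cα positions are the 26-neighborhood local maxima of the Cα
confidence map at or above 0.50 confidence, thinned by non-maximum
suppression at 1.5 Å and refined to the confidence-weighted centroid
of their neighborhood (sub-voxel placement is necessary: at 1 Å voxel
quantization alone the RMSD floor would be ≈0.5 Å). Walking starts
from the highest-confidence unvisited candidate and repeatedly scores
candidates inside the 2.8-4.2 Å step band:

score = w_conf · Cα(candidate) + w_bb · (mean backbone confidence
along the step) − w_dist · |d − 3.8|/3.8 − w_angle · max(0, cos θ −
cos 150°),

with defaults (1.0, 0.5, 1.0, 0.5); θ is the pseudo-bond angle at the
current position, so the last term penalizes near-backtracking only.
Candidates below 0.50 Cα confidence or 0.40 mean backbone confidence
are rejected outright (the two display thresholds used for the
confidence maps). Accepted positions mark a permanent 2.0 Å exclusion
(tabu) neighborhood; a walk ends when no admissible candidate remains
or the best candidate is already visited, then continues in the
opposite direction from the seed before the next seed is selected.
Ties break lexicographically by voxel index, making the tracer fully
deterministic. An optional helix-radius bonus (reward candidates whose
offset from the local trace axis is 1.8-2.8 Å in high helix-confidence
regions) is implemented but disabled by default (`w_helix = 0`)
pending calibration on experimental maps.

## Graph refinement

Traces become an undirected graph (nodes = Cα, edges = trace bonds)
and four passes run in order, each to a fixed point:

1. **Path combination** — endpoints within 3.0 Å of another node are
   merged onto it (the endpoint's coordinate is reassigned), fusing
   neighboring traces.
2. **Side-chain removal** — at each junction (degree ≥ 3), each branch
   is walked to its end or the next junction; the unique shortest
   branch is removed when its depth is ≤ 3 nodes and all others are
   strictly deeper. Depth counts nodes beyond the junction; a terminal
   junction is not counted. For degree-4 junctions the same rule
   applies (remove the unique shortest qualifying branch).
3. **Loop removal** — parallel branch paths joining the same two
   junctions form a loop (typically a shortcut across a helix); the
   mean density inside a 1 Å-radius cylinder along each path decides,
   and the lower-density path's interior is deleted. Exact ties remove
   the longer path; a path whose cylinder contains no voxel scores
   −∞.
4. **Dead-end removal** — branches of depth ≤ 2 that end in a
   degree-1 node are deleted. The two terminal stretches of a simple
   path have no junction anchor and are never touched.

All passes only merge or delete, so node and edge counts are
monotonically non-increasing, and each pass is idempotent — both
properties are asserted in the test suite.

## Helix idealization

An ideal α-helix about a straight vertical axis is
$(2.11\sin(1.149\,t),\; 2.11\cos(1.149\,t),\; t)$ up to an initial
shift and rotation: radius 2.11 Å, angular pitch 1.149 rad/Å, Cα
placed every 1.5 Å of axis travel. Three implementation decisions
deserve note:

* **Phase parameters.** The shift/rotation pair (s, r) enters as a
  phase, θ = 1.149·(t − s) + r, which preserves the constant radius.
  (Applying them additively to the Cartesian components, as a literal
  reading of the printed formula would, destroys the helix shape.) On
  this reading s and r are redundant — both shift the phase — but both
  are retained and optimized jointly for fidelity to the stated
  procedure; the optimum is a ridge and the optimizer simply lands
  somewhere on it.
* **Handedness.** Natural α-helices are right-handed. The local frame
  at axis position t takes z along the tangent and the offset
  $2.11(\cos\theta\,\hat y_{loc} - \sin\theta\,\hat x_{loc})$, which
  winds counterclockwise about the tangent (right-handed) and anchors
  t = s = r = 0 at local (0, 2.11, 0). A sign-literal implementation
  of the printed equations would produce a left-handed helix that
  cannot fit real (or synthetic) helices.
* **Screw axis.** The axis is estimated as the polyline of sliding
  window-4 centroids (one turn ≈ 3.6 residues, so the window nearly
  cancels the radial component), smoothed twice with a 3-point moving
  average; the end centroids, which retain helical wobble, are
  re-anchored by a quadratic fit (in arclength) through the nearest
  interior centroids, and the axis is extrapolated by half a window
  span so its ends line up with the terminal residues. On an ideal
  straight helix the estimated axis stays within ~0.05 Å of truth;
  on an arc of 30 Å curvature radius within ~0.12 Å.

Helix runs are detected on the refined graph (a node is helix-labeled
when the mean helix confidence within 2 Å beats sheet and loop; runs
shorter than 6 nodes are left alone), refitted, and spliced back,
reconnecting to the flanking nodes by nearest endpoints. The fit
minimizes the mean distance from placed atoms to the original
prediction over a 0.05-step grid in s and r followed by a Nelder-Mead
polish, keeping whichever is better — deterministic, and the test
suite asserts the returned optimum never loses to a grid candidate.

## Metrics

Matching is greedy in trace order: each predicted Cα claims the
nearest unclaimed native Cα within 3 Å. This mirrors the established
map-to-model evaluation convention (and therefore reads slightly
favorable RMSDs compared with optimal assignment); an exhaustive
maximum-matching oracle in the test suite confirms the greedy count
equals the optimum in ≥95% of small random instances and never
exceeds it. Reported quantities: RMSD over matched pairs; %Cα within
3 Å, with the native count as denominator (a completeness measure —
the predicted-denominator variant is also emitted); the
false-positive count (predictions farther than 3 Å from *every*
native Cα — deliberately not "unmatched", since a prediction can sit
next to a native atom already claimed by a neighbor); and the error
rate, false positives divided by total predictions. An empty
prediction yields 0%, an absent RMSD and a zero error rate, with a
warning.

## Problem sizes and determinism

The shipped tests and the acceptance script use desk-scale problems
chosen as the package's own study conditions: 120-residue synthetic
proteins for end-to-end runs, 10 training samples of 32³ voxels and
30 optimizer steps for the trainability check, 150³ volumes for the
cube pipeline, and 50 random instances for the matching comparison.
Every stochastic step (generator, dataset builder, training order,
weight initialization) is seeded explicitly; the tracing and
refinement stages are deterministic by construction, and re-running
the pipeline with identical inputs reproduces the output PDB byte for
byte.

## Known limitations

* The network is validated for trainability at toy scale; no trained
  weights ship with the package, and network-mode predictions on real
  maps require training on a realistic corpus first.
* Binarized label maps use fixed radii (1.0/1.2 Å) rather than
  resolution-dependent soft labels.
* The loop-removal density cylinder samples voxel centers only; maps
  with voxels much coarser than 1 Å should be resampled first (the
  pipeline does this automatically).
* Sequence assignment, full-atom reconstruction and dust/outlier
  cleaning of experimental maps are out of scope.
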