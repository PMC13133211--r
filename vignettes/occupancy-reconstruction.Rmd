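---
title: "Single-view skeletal reconstruction: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-view skeletal reconstruction: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Recovering a patient's 3D bone geometry from a single planar radiograph
is ill-posed: one projection integrates away depth. Two complementary
ideas make it tractable. First, an *implicit occupancy field*: instead
of predicting a voxel grid or mesh directly, a network learns the
function $o : \mathbb{R}^3 \to \{0,1\}$ that says whether a point lies
inside bone, conditioned on the radiograph. The surface is the decision
boundary of that field at a threshold $\tau$ and can be extracted at
any resolution. Second, *template refinement*: a part-labelled skeletal
template is non-rigidly registered onto the coarse reconstruction, with
motion coherence measured along the template surface rather than
through space, so that anatomically distinct parts (adjacent ribs) can
move independently.

`skelrec` implements this pipeline end to end at desk scale. Clinical
CT is replaced by procedurally generated watertight phantoms with
closed-form inside/outside oracles, so every stage is testable against
an independent ground truth — which is the point of the package: a
fully checked, self-contained reimplementation of the methodology, not
a clinical model.

## The occupancy model

For a projection image $x$ with encoding $c = \mathrm{Enc}(x)$, query
points $p_j$ and labels $o_j$, the decoder predicts logits
$\ell_j = f_\theta(p_j, z, c)$ and the occupancy probability is
$\hat o_j = \sigma(\ell_j)$. Training minimises the negative ELBO

$$L = \frac{1}{|B|}\sum_{i \in B}\Big[\mathrm{KL}\big(q_\phi(z_i \mid p_i, o_i, c_i)\,\|\,\mathcal N(0, I)\big) + \frac{1}{T}\sum_{j=1}^{T}\mathrm{BCE}(\ell_{ij}, o_{ij})\Big],$$

with one reparameterised latent sample per step and the BCE computed in
the numerically stable logit form. Adam is used with the conventional
settings ($\eta = 10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$); small overfitting experiments benefit from a
higher initial rate decayed linearly (`lr`, `lr_final` in
`train_config()`).

Architecture, and the choices made where the design was open:

* **Encoder.** A 4-stage hierarchical convolutional backbone:
  a 4×4-stride-4 patchify stage followed by three 2×2-stride-2 stages
  with channel widening, global average pooling and a linear head to
  the image code (1024-d at full scale). The stages use plain strided
  convolutions rather than inverted-bottleneck blocks: at the widths a
  CPU run can afford, the bottleneck adds cost without capacity. All
  widths are configurable so tests run a tiny variant on 64×64 inputs.
* **Conditioning.** Each decoder block modulates its hidden features
  with a per-channel scale $\gamma(c)$ and shift $\beta(c)$ generated
  from the image code. We deliberately do *not* normalise with batch
  statistics: a field query must give the same answer whether a point
  is evaluated alone or in a batch of 10^5 (the batching-consistency
  contract, tested to 1e-5), and batch moments would couple queries.
  Conditioning-generated scale/shift without moments (FiLM) preserves
  exactly the "scale and shift from the conditioning features" role.
* **Decoder.** 5 residual dense blocks of hidden width 256 (tiny
  variants scale this down), each conditioned twice, with a single
  linear logit head. Query points enter through a linear lift; the
  latent code enters additively through a silent-at-init linear map.
* **Variational encoder.** A pointwise MLP on (point, label) pairs,
  mean-pooled over the point set (permutation invariance), concatenated
  with the image code, with linear heads for the posterior mean and
  log-variance. It is used only in training; at inference the latent is
  fixed at the prior mean, making `infer_field()` deterministic.
* **Latent dimension** is not architecture-critical; default 64
  (tests use 8). The KL term quickly quiets the latent and the decoder
  leans on the image code, which is what the conditioning test
  verifies.

All gradients are hand-derived matrix algebra, checked against central
finite differences to 1e-4 relative error across every parameter
family. Training is bit-reproducible under a fixed seed in a fixed
BLAS configuration: all randomness (subset draws, latent noise,
initialisation) flows from R's RNG.

## Supervision

Meshes are centred and isotropically scaled into the unit box
(`normalize_mesh()`, padding 0.05 by default so marching cubes has
boundary headroom). Supervision pools are 100,000 points (desk-scale
runs use 20,000) drawn uniformly over the *padded cube*, not the mesh
bounding box — negatives near the boundary stabilise training — and
labelled once by ray-parity: a point is inside iff a ray crosses the
watertight surface an odd number of times. Grazing rays are real with
axis-aligned geometry, so each point votes over 3 pseudo-random ray
directions seeded by its index. The labels agree with closed-form
membership on ≥ 99.9% of 100,000 points for every analytic phantom,
and with an independent generalized-winding-number oracle on random
points. Training steps redraw a fresh 2,048-point subset per sample
each step (the redraw-vs-fix choice is not pinned down by convention;
redrawn subsets decorrelate steps and cost nothing since labels are
precomputed).

Voxel grids record two masks: the conservative convention (occupied =
cube intersects surface OR centre inside) used for supervision grids,
and the centre-inside mask whose occupied volume converges to the mesh
volume with error $O(\mathrm{pitch})$, used for volumetric IoU. The
conventions differ materially — the surface shell inflates a sphere's
volume by ≈ 18% at 32³ — which is why both are kept and the report
records which pitch was used.

## Projection simulation

The conditioning images are parallel-beam line integrals: each pixel
ray accumulates its exact interior chord length (crossing depths are
sorted and paired — no sampling error), the view rotates about the
vertical axis, and intensity is displayed bone-bright as
$I = 1 - L/L_{\max}$ with $L_{\max}$ the box diagonal. Parallel
geometry was chosen over cone-beam: the source geometry is not pinned
down by the reference pipeline, the parallel beam preserves every
property downstream stages rely on, and it is analytically testable —
sphere chords match $2\sqrt{r^2 - d^2}$ to 2% and summed chords
reproduce mesh volume (Cavalieri) to 2% at 256². CLAHE (clipped
per-tile histogram equalisation with bilinear remapping between tiles)
is available for contrast enhancement; it preserves intensity range
and local rank order. Detector-style part bounding boxes are obtained
by forward-projecting each part's vertices — the ground-truth stand-in
for a 2D detector, which is out of scope.

## Isosurface extraction

`mise_extract()` evaluates the field on a coarse corner lattice
(default 32 per axis), marks *active* cells (corners straddling
$\tau$) plus their face neighbours (protects thin rib-like structures
at coarse resolution), recursively subdivides only those to the final
resolution (default 128), and closes the active set so that every
final-level cell that straddles $\tau$ is fully evaluated. Unevaluated
corners inherit their coarse ancestor's value, which lies on the
correct side by construction. The result is *identical* — the same
triangle set — to dense marching cubes at the final resolution for
fields resolved at the coarse level, at a fraction of the queries
(~10^5 vs 2.1 × 10^6 for typical phantoms); that equivalence is an
acceptance criterion, not a hope.

The marching-cubes core pairs cut edges on each cube face, resolving
4-cut ambiguous faces with the bilinear asymptotic decider (a function
of the shared face values only, hence consistent between neighbouring
cubes), traces the pairs into closed polygons, orients them against
the local field gradient and fan-triangulates. Isosurface vertices are
welded by global lattice-edge identity, so closed isosurfaces give
watertight meshes by construction rather than by luck.

$\tau = 0.2$ (not 0.5) biases the boundary outward, trading a little
over-inclusiveness for completeness of thin structures — the
occupancy-network convention this design follows.

Post-processing: quadric edge-collapse simplification (pass-based
greedy with a growing error threshold; collapses violating the
manifold link condition or flipping normals are rejected, so
watertightness survives — a sphere simplified 20k → 2k faces changes
volume by < 1%), then optional gradient refinement moving vertices
along a central-finite-difference field gradient with a damped,
step-capped Newton update; iterations that would increase the mean
residual $|f(v) - \tau|$ back off, making the residual non-increasing
by construction.

## Registration

The refinement stage treats template vertices as Gaussian-mixture
centroids drifting onto the coarse reconstruction (coherent point
drift): E-step responsibilities under an isotropic GMM with a uniform
outlier component (weight $w$), M-step solving the
coherence-regularised displacement system
$(\mathrm{diag}(P\mathbf 1)G + \lambda\sigma^2 I)W = PX -
\mathrm{diag}(P\mathbf 1)Y$ and re-estimating $\sigma^2$. The
coherence kernel is $G_{ij} = \exp(-d_{ij}^2 / 2\beta^2)$ with $d$
either Euclidean or geodesic along the template's edge graph
(igraph shortest paths; exact polyhedral geodesics are out of scope
and the graph approximation converges under refinement). Geodesic
distance is infinite between disconnected components, so cross-part
coupling is exactly zero: one rib pair can articulate without dragging
its spatial neighbours, which is the behaviour that separates the
geodesic kernel from classic CPD on articulated anatomy — and the
package's articulated-phantom test shows the geodesic kernel beating
the Euclidean one strictly on the displaced part.

Numerical choices that mattered in practice:

* **Kernel width units.** $\beta$ is expressed in units of the
  source's RMS radius (default $\beta = 2$), the canonical CPD scaling
  of normalising the data before using order-1 widths. An initial
  design measured $\beta$ in mean-edge-lengths; that makes the kernel
  narrower than any anatomical feature, the regulariser
  $\lambda\sigma^2$ vanishes as $\sigma^2$ anneals, and the
  displacement field degenerates to per-vertex motion that chases
  outliers (measured error with 20% outliers: 0.13 box units — worse
  than the deformation being recovered). Coherence must live at the
  shape scale, not the tessellation scale.
* **Variance initialisation.** The classic init (mean pairwise
  source–target distance) assumes arbitrary misalignment. The pipeline
  always rigidly pre-aligns with ICP first, and with the wide init the
  annealing phase lets curve-like parts slide tangentially along
  themselves (a rib arc maps onto itself under arc-length shift almost
  for free). `gbcpd_nonrigid()` therefore initialises $\sigma^2$ at
  the post-alignment residual scale (mean squared nearest-neighbour
  distance plus a small floor), after which the identity-target
  invariant holds to 1e-13.
* **PSD clipping and low rank.** Geodesic Gaussian kernels are not
  guaranteed positive semi-definite; eigenvalues are clipped at zero.
  Above 800 source vertices a rank-50 truncated eigendecomposition
  with a Woodbury solve keeps the M-step affordable; the truncation
  error bound (discarded spectrum) is verified against the full
  eigendecomposition in tests.
* **Multi-component parts.** The spec-level contract wants template
  parts connected, but the stand-in anatomy legitimately uses parts
  made of several closed components (a capsule stack for the spine,
  two arcs per rib pair). By default each component simply becomes its
  own coherence unit; `strict = TRUE` restores the hard error.

The per-iteration negative log-likelihood is recorded and checked
non-increasing (tolerance 1e-8) on all fixture runs — EM can in
principle wobble once $\sigma^2$ enters the regulariser, so this is a
monitored property, not an assumed one.

## Metrics

The evaluation suite reports volumetric IoU on a common voxel grid
(centre-inside masks; pitch in mesh units, 1/64 for unit-normalized
inputs, recorded in the report), Chamfer-L1 as the *sum* of the two
directed mean nearest-neighbour L1 distances (the printed convention;
a `halved` flag covers the other convention), F-score at t = 0.02,
one-directional normal consistency $\frac{1}{|P|}\sum |n_P \cdot
n_G(\mathrm{nn})|$, and per-axis mean absolute errors after ICP
alignment with nearest-neighbour correspondence (topology-mismatched
meshes have no vertex correspondence; nearest neighbour is the only
well-defined reading). Chamfer and F-score use exact L1/L2 nearest
neighbours from a kd-tree and are verified against $O(n^2)$ brute
force to 1e-12. Surface sampling is area-weighted with shared seeds
across the pair, so the identity pair reports exactly
(IoU 1, Chamfer 0, F-score 1, NC 1).

One interpretive note: under independent random orientations the
expected |cosine| between two unit normals is exactly 0.5. An NC value
near 0.5 therefore carries no alignment information — that is the
floor, reproduced by the suite to ±0.02 — and reported NC values
should always be read against it.

## What the phantoms do and do not establish

The generator produces watertight, part-labelled, pairwise-disjoint
shapes with closed-form membership: icosphere-based spheres and
ellipsoids, parametric tori, lat-long capsules, and a toy thorax
(capsule-stack spine plus bent-capsule rib pairs with seeded jitter
and collision-checked regeneration). Known deformations — rigid
translation, a smooth quadratic bend capped at
magnitude × bbox-diagonal, rigid single-rib articulation — come with
exact per-vertex ground truth for registration tests.

Phantom defaults define the test world: unit-box scale, rib tube
radius ≈ 0.025, arc radius ≈ 0.28, 140° arcs, deformation magnitudes
0.05–0.06 box units (a few rib diameters — large enough to be
non-trivial, small enough to stay anatomically plausible). The
end-to-end learning test overfits 8 phantoms (ellipsoids, capsules and
spheres in varied poses — convex-ish, bone-like shapes; a genus-1
torus is deliberately not in the training mix) on 64×64 views with a
tiny network for ≤ 2,000 steps and requires mean IoU ≥ 0.85 at 32³
plus verified conditioning: every reconstruction must match its own
ground truth strictly better than any swapped one.

A green suite therefore establishes that the machinery is correct and
that the conditional field genuinely uses its image input. It does
*not* establish clinical performance: the phantoms have binary
density, no soft-tissue background, no projection superposition of
overlapping bones, no detector physics, and the training regime is
overfitting, not generalisation. The train/validation/test split
machinery (phantom-level, mirroring patient-level splitting) is
exercised by the pipeline tests, but generalisation numbers at desk
scale would be meaningless and are not claimed.

## Known limitations

* Parallel-beam only; no cone-beam geometry or polychromatic physics.
* Graph geodesics overestimate surface geodesics on coarse meshes
  (≈ 5–8% on an icosphere at the tested resolutions), and are not
  monotone under subdivision; the kernel width absorbs this at the
  scales used.
* Marching cubes resolves face ambiguities with the asymptotic
  decider but, like all single-cube triangulators, can produce
  degenerate-quality (not degenerate-topology) fans for extreme
  fields.
* The CPD outlier component is uniform over the target's convex
  region; structured clutter is not modelled.
* Training is single-threaded deterministic matrix algebra — fine for
  the desk-scale experiments it exists for, not a GPU training stack.
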