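# skelrec

Single-view 3D skeletal shape reconstruction in R: a conditional
neural **occupancy field** (image → continuous inside/outside
probability over 3D space) trained with amortised variational
inference, **multiresolution isosurface extraction** to turn the field
into a watertight mesh, and **template refinement** by coherent point
drift with a *geodesic* coherence kernel, so anatomically distinct
parts (adjacent ribs) can move independently during non-rigid
registration.

The package is aimed at methods work, not clinical use: every stage is
exercised on procedurally generated watertight phantoms (spheres,
ellipsoids, tori, capsules, a part-labelled toy thorax) with
closed-form inside/outside oracles, so reconstruction accuracy,
isosurface correctness and registration behaviour are all verifiable
against independent ground truth on a laptop-class CPU.

## The model in brief

For an image $x$ with encoding $c = \mathrm{Enc}(x)$ and query points
$p_j$, a conditioned decoder predicts logits
$\ell_j = f_\theta(p_j, z, c)$, occupancy probabilities
$\hat o_j = \sigma(\ell_j)$, and training minimises the negative ELBO

$$L = \tfrac{1}{|B|}\textstyle\sum_i \big[\mathrm{KL}(q_\phi(z_i \mid p_i, o_i, c_i)\,\|\,\mathcal N(0,I)) + \tfrac1T \sum_j \mathrm{BCE}(\ell_{ij}, o_{ij})\big]$$

with Adam ($\eta = 10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$). Supervision labels come from ray-parity tests
against the watertight phantom surface (100k-point pools, 2,048-point
subsets per step). Meshes are recovered from the field by
marching cubes at threshold $\tau = 0.2$ inside a coarse-to-fine
active-voxel scheme (32³ → 128³ by default) that is provably identical
to dense extraction for resolved fields. Refinement registers a
part-labelled template onto the coarse mesh with CPD whose Gaussian
kernel is evaluated on surface geodesic distances — infinite, hence
zero coupling, between disconnected parts.

Evaluation follows the standard mesh-reconstruction suite: voxelized
IoU, Chamfer-L1 (sum of both directed mean nearest-neighbour L1
distances), F-score at t = 0.02, normal consistency, and per-axis mean
absolute errors after ICP alignment.

## Worked example: articulated registration

One rib pair of a toy thorax is displaced rigidly; a geodesic-kernel
registration recovers it while classic Euclidean-kernel CPD, which
couples the ribs through space, cannot follow the articulation as
precisely:

```r
library(skelrec)

th <- make_toy_thorax(n_rib_pairs = 3, n_vertebrae = 4, jitter = 0, seed = 2)
th
#> part_mesh: 4 parts (spine, rib_pair_01, rib_pair_02, rib_pair_03), 2560 faces total

deformed <- deform_known(th, "part_articulation", magnitude = 0.06, seed = 5)
deformed$moved_part
#> [1] "rib_pair_03"

fit_geo <- gbcpd_nonrigid(th, deformed$mesh$mesh$vertices, pre_align = FALSE)
fit_geo
#> deformation_field: 1300 vertices, geodesic kernel (rank 50), 40 EM iters,
#>   sigma2 5.88e-11, converged

fit_euc <- cpd_nonrigid(th$mesh, deformed$mesh$mesh$vertices,
                        kernel = "euclidean")
ids <- part_vertex_ids(th, deformed$moved_part)
err <- function(fit) mean(sqrt(rowSums(
  (fit$mesh$vertices[ids, ] - deformed$mesh$mesh$vertices[ids, ])^2)))
c(geodesic = err(fit_geo), euclidean = err(fit_euc))
#>   geodesic  euclidean
#>    0.00037    0.02101
```

The displaced rib pair is recovered to 0.0004 box units (the rib tube
radius is 0.025) by the geodesic kernel — 50× better than the
Euclidean kernel, whose spatial coherence drags neighbouring structure
along. The registered mesh scores near-perfectly against the deformed
ground truth:

```r
evaluate_pair(fit_geo$mesh, deformed$mesh$mesh,
              n_samples = 20000, pitch = 1 / 64, seed = 1)
#> metrics_report (pitch 0.01562, t 0.02, 20000 samples):
#>   IoU 0.9983 | Chamfer-L1 0.00097 | F-score 1.0000 | NC 0.9955
#>   maxe 0.00003  maye 0.00010  maze 0.00001
```

An end-to-end coarse reconstruction (phantoms → supervision →
projection → training → field → mesh → metrics) is one call:

```r
res <- run_x2b(default_config(seed = 1))     # ~10 min on one CPU
mean(sapply(res$reports, `[[`, "iou"))
```

and `run_x2br()` adds the template-registration refinement. The
`skelrec` CLI (`exec/skelrec`) exposes every stage:
`gen-phantoms`, `gen-occupancy`, `render`, `train`, `infer`,
`extract`, `register`, `evaluate`, `run-recon`, `run-refine`.

## Scope

Phantom data only: no DICOM/CT ingestion, no detector training, no
cone-beam geometry, no claims about clinical radiographs. See the
methods vignette (`vignettes/occupancy-reconstruction.Rmd`) for the
model, the numerical choices and what a green test suite does and does
not establish.
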