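Package: skelrec
Title: Single-View Skeletal Shape Reconstruction with Neural Occupancy
    Fields and Non-Rigid Registration
Version: 0.1.0
Authors@R:
    person("skelrec", "developers", email = "skelrec@example.org",
           role = c("aut", "cre"))
Description: Reconstructs watertight 3D bone-like surfaces from a single
    simulated radiograph. Provides procedural phantom generation
    (watertight part-labelled meshes), occupancy supervision (ray-parity
    inside/outside labelling, voxelization, uniform point pools),
    parallel-beam radiograph simulation with CLAHE contrast enhancement,
    a conditional occupancy-field network trained by amortised
    variational inference, multiresolution isosurface extraction with
    marching cubes, quadric mesh simplification and gradient refinement,
    rigid ICP plus coherent point drift registration with Euclidean or
    geodesic coherence kernels, and a reconstruction-metric suite
    (voxelized IoU, Chamfer-L1, F-score, normal consistency, per-axis
    errors).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
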