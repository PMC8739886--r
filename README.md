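# surfgnn

Graph-neural-network cortical parcellation in R.

surfgnn labels every vertex of a triangulated cortical surface with a
discrete areal label, learned from resting-state functional-connectivity
features of training subjects. It is aimed at researchers who have
surface-mapped fMRI data and subject-level training parcellations and want
to map *new* subjects — and at methodologists who want a transparent,
dependency-light implementation of graph neural networks on surface meshes
with exact, testable gradients.

## The models

Parcellation is node classification on the mesh graph G = (V, E) with
per-vertex features X ∈ ℝ^(N×F). Four classifiers are provided:

- **baseline** — vertex-wise feed-forward network (no adjacency);
- **GCN** — first-order spectral graph convolution, per layer
  σ(Â H W) with Â = D̃^(−1/2)(A + I)D̃^(−1/2);
- **GAT** — multi-head graph attention: per head,
  α[i,j] = softmax_j LeakyReLU(a₁·Wh_i + a₂·Wh_j) over j ∈ N(i) ∪ {i},
  update h′_i = Σ_j α[i,j] W h_j; heads concatenate in hidden layers and
  average in the output layer;
- **JKGAT** — GAT with jumping-knowledge aggregation of all layer
  embeddings (concatenation, max-pooling, or a bidirectional LSTM that
  learns per-vertex layer-attention weights summing to 1).

Features are regionalized connectivity (vertex-to-atlas-region Pearson
correlations, R ∈ ℝ^(N×K)) or dual-regression component loadings, plus
Laplacian spectral coordinates and scalar maps. Training uses vertex-wise
cross-entropy, Adam (weight decay 5e-4, explicit L2 5e-3), graph
mini-batches with gradient accumulation, and validation-loss early
stopping. A test-time spatial prior restricts each vertex to labels seen
at that vertex in training. Evaluation covers accuracy, areal Dice
reproducibility, boundary-distance error profiles, functional (SVD) and
scalar (variance-ratio) homogeneity, consensus maps, mean probability
maps, and bootstrap standard errors. Forward/backward passes are written
in plain matrix algebra and checked against finite differences.

A synthetic cortex generator (icosphere mesh, geodesic Voronoi parcels,
parcel-structured noisy time series, scalar maps, multi-subject cohorts)
makes the whole pipeline runnable and testable without any imaging data.

## Worked example

```r
library(surfgnn)

synth <- synthetic_config(mesh_subdivisions = 2, num_parcels = 5,
                          num_subjects = 8, timepoints = 120, snr = 3,
                          boundary_jitter = 0, seed = 42)
cohort <- make_cohort(synth)
cohort$mesh
#> <surface_graph> 162 vertices, 320 faces, 480 edges

ds <- cohort_dataset(cohort, n_train = 4, n_val = 2, n_test = 2)
ncol(ds$dataset$samples[[1]]$features)   # 4 atlas regions + 3 spectral + 4 scalars
#> [1] 11

spec  <- model_spec("gat", num_classes = 5)   # 3 layers, 32 channels, 4 heads
model <- train(spec, ds$dataset,
               training_config(max_epochs = 30, patience = 30, seed = 42))
model
#> <trained_model> gat, depth 3, 11 -> 5 classes, 20904 parameters

prior  <- build_prior(lapply(ds$dataset$samples[ds$dataset$split == "train"],
                             `[[`, "labels"))
report <- evaluate_model(model, ds, cohort, prior = prior)
report
#> <evaluation_report> mean accuracy 100.00% (SE 0.000) over 2 samples
#>   functional homogeneity 99.54%
```

The attention network recovers the planted 5-parcel map exactly on both
held-out subjects; the predicted parcels explain 99.5% of the
functional-connectivity variance (first singular component per parcel).

A command-line front end mirrors the same pipeline
(`inst/cli/surfgnn.R`, subcommands `simulate`, `features`, `train`,
`predict`, `evaluate`, `run`); meshes, label maps and metrics read and
write both plain-text tables and ASCII GIFTI (`.surf.gii`, `.label.gii`,
`.func.gii`).

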