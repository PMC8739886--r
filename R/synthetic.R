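#' Synthetic cohort configuration
#'
#' Bundles the generator settings for a self-contained synthetic "study":
#' a closed icosphere cortex, a ground-truth parcellation, parcel-structured
#' noisy BOLD-like time series, scalar maps, and a coarse anatomical atlas
#' for regionalized connectivity features.
#'
#' @param mesh_subdivisions icosphere subdivision level (vertex count
#'   10 * 4^s + 2).
#' @param num_parcels number of ground-truth parcels P (>= 2).
#' @param num_subjects subjects in the cohort.
#' @param sessions_per_subject repeated scanning sessions per subject.
#' @param timepoints time points per session.
#' @param snr ratio of parcel-signal SD to vertex-noise SD (> 0).
#' @param boundary_jitter rounds of per-subject boundary label perturbation
#'   (0 = all subjects share the template parcellation).
#' @param num_atlas_regions regions in the coarse atlas used to regionalize
#'   connectivity (defaults to roughly two thirds of `num_parcels`).
#' @param radial_noise_sd SD of radial perturbation of mesh vertices, which
#'   breaks the spectral degeneracy of a perfect sphere.
#' @param seed integer seed driving every random draw.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(mesh_subdivisions = 3L, num_parcels = 8L,
                             num_subjects = 20L, sessions_per_subject = 1L,
                             timepoints = 200L, snr = 3,
                             boundary_jitter = 0L,
                             num_atlas_regions = max(2L, ceiling(num_parcels * 2 / 3)),
                             radial_noise_sd = 0.02, seed = 1L) {
  stopifnot(num_parcels >= 2L, timepoints >= 2L, snr > 0, num_subjects >= 1L,
            sessions_per_subject >= 1L, boundary_jitter >= 0L)
  structure(
    list(
      mesh_subdivisions = as.integer(mesh_subdivisions),
      num_parcels = as.integer(num_parcels),
      num_subjects = as.integer(num_subjects),
      sessions_per_subject = as.integer(sessions_per_subject),
      timepoints = as.integer(timepoints),
      snr = snr,
      boundary_jitter = as.integer(boundary_jitter),
      num_atlas_regions = as.integer(num_atlas_regions),
      radial_noise_sd = radial_noise_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Icosphere surface mesh
#'
#' Repeated 4-to-1 triangle subdivision of a unit icosahedron, with vertices
#' re-projected to the sphere after every round; vertex count is
#' 10 * 4^s + 2. Optional radial noise perturbs each vertex along its normal,
#' breaking the eigenvalue degeneracies of the perfectly symmetric sphere so
#' that spectral coordinates are stable.
#'
#' @param subdivisions subdivision level s >= 0 (s = 0 is the icosahedron).
#' @param radial_noise_sd SD of multiplicative radial jitter (0 disables).
#' @param seed RNG seed for the jitter.
#' @return a `surface_graph`.
#' @export
make_mesh <- function(subdivisions = 3L, radial_noise_sd = 0, seed = 1L) {
  stopifnot(subdivisions >= 0L)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  s <- 0L
  while (s < subdivisions) {
    res <- subdivide_once(v, f)
    v <- res$vertices
    f <- res$faces
    s <- s + 1L
  }
  if (radial_noise_sd > 0) {
    set.seed(seed)
    v <- v * (1 + stats::rnorm(nrow(v), sd = radial_noise_sd))
  }
  surface_graph(v, f)
}

subdivide_once <- function(v, f) {
  midpoint_of <- new.env(hash = TRUE)
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  get_mid <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    idx <- midpoint_of[[key]]
    if (is.null(idx)) {
      m <- (verts[[a]] + verts[[b]]) / 2
      m <- m / sqrt(sum(m^2))
      verts[[length(verts) + 1L]] <<- m
      idx <- length(verts)
      midpoint_of[[key]] <- idx
    }
    idx
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  r <- 0L
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
    newf[r + 1L, ] <- c(a, ab, ca)
    newf[r + 2L, ] <- c(b, bc, ab)
    newf[r + 3L, ] <- c(cc, ca, bc)
    newf[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(vertices = do.call(rbind, verts), faces = newf)
}

#' Geodesic Voronoi parcellation of a surface graph
#'
#' Seeds are placed by farthest-point sampling in hop distance; parcels are
#' grown by simultaneous breadth-first expansion from all seeds, which makes
#' every parcel a connected subgraph by construction.
#'
#' @param g a connected `surface_graph`.
#' @param num_parcels number of parcels P (1 <= P <= N).
#' @param seed RNG seed (chooses the first sample point).
#' @return a `label_map` with labels 1..P and no unlabeled vertices.
#' @export
make_parcellation <- function(g, num_parcels, seed = 1L) {
  n <- g$n_vertices
  stopifnot(num_parcels >= 1L, num_parcels <= n)
  set.seed(seed)
  seeds <- sample.int(n, 1L)
  while (length(seeds) < num_parcels) {
    d <- geodesic_hops(g, seeds)
    seeds <- c(seeds, which.max(d))
  }
  labels <- integer(n)
  labels[seeds] <- seq_along(seeds)
  A <- g$adjacency
  while (any(labels == 0L)) {
    for (p in seq_along(seeds)) {
      frontier <- as.logical(A %*% (labels == p) > 0) & labels == 0L
      labels[frontier] <- p
    }
  }
  label_map(labels, num_classes = num_parcels)
}

#' Parcel-structured synthetic time series
#'
#' Every parcel receives an independent unit-variance Gaussian latent signal;
#' each vertex observes its parcel's latent plus white Gaussian noise with
#' SD 1/snr, so within-parcel vertex correlations rise with `snr`.
#'
#' @param labels a `label_map` over the mesh vertices.
#' @param timepoints number of time points t >= 2.
#' @param snr signal-SD to noise-SD ratio (> 0).
#' @param seed RNG seed.
#' @return an N x t numeric matrix.
#' @export
make_time_series <- function(labels, timepoints = 200L, snr = 3, seed = 1L) {
  stopifnot(timepoints >= 2L, snr > 0)
  set.seed(seed)
  n <- length(labels$labels)
  classes <- sort(unique(labels$labels[labels$labels != labels$unlabeled_code]))
  latent <- matrix(stats::rnorm(length(classes) * timepoints), length(classes))
  rownames(latent) <- classes
  ts <- matrix(stats::rnorm(n * timepoints, sd = 1 / snr), n)
  lab <- labels$labels
  labeled <- lab != labels$unlabeled_code
  ts[labeled, ] <- ts[labeled, ] + latent[as.character(lab[labeled]), , drop = FALSE]
  ts
}

#' Generate a full synthetic cohort
#'
#' Builds the mesh, a template ground-truth parcellation, a coarser atlas for
#' regionalized connectivity, per-subject label maps (template boundaries
#' optionally jittered), per-subject-per-session time series, and four
#' parcel-structured scalar maps (thickness/curvature/sulc/myelin analogues,
#' parcel-level means shared across the cohort plus per-subject noise).
#'
#' @param cfg a `synthetic_config`.
#' @return a `synthetic_cohort`: list with `mesh`, `template_labels`, `atlas`,
#'   `subject_labels` (list), `time_series` (list of lists, one matrix per
#'   session), `scalars` (list of named N x 4 matrices) and `config`.
#' @export
make_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  mesh <- make_mesh(cfg$mesh_subdivisions, cfg$radial_noise_sd, seed = cfg$seed)
  template <- make_parcellation(mesh, cfg$num_parcels, seed = cfg$seed + 1L)
  atlas <- make_parcellation(mesh, cfg$num_atlas_regions, seed = cfg$seed + 2L)

  scalar_names <- c("thickness", "curvature", "sulc", "myelin")
  set.seed(cfg$seed + 3L)
  parcel_means <- matrix(stats::rnorm(cfg$num_parcels * 4L), cfg$num_parcels,
                         dimnames = list(NULL, scalar_names))

  subject_labels <- vector("list", cfg$num_subjects)
  time_series <- vector("list", cfg$num_subjects)
  scalars <- vector("list", cfg$num_subjects)
  for (s in seq_len(cfg$num_subjects)) {
    sub_seed <- cfg$seed + 100L * s
    subject_labels[[s]] <- jitter_boundaries(mesh, template, cfg$boundary_jitter,
                                             seed = sub_seed)
    time_series[[s]] <- lapply(seq_len(cfg$sessions_per_subject), function(k) {
      make_time_series(subject_labels[[s]], cfg$timepoints, cfg$snr,
                       seed = sub_seed + k)
    })
    set.seed(sub_seed + 90L)
    sc <- parcel_means[subject_labels[[s]]$labels, , drop = FALSE] +
      matrix(stats::rnorm(mesh$n_vertices * 4L, sd = 1 / cfg$snr), mesh$n_vertices)
    colnames(sc) <- scalar_names
    scalars[[s]] <- sc
  }

  structure(
    list(mesh = mesh, template_labels = template, atlas = atlas,
         subject_labels = subject_labels, time_series = time_series,
         scalars = scalars, config = cfg),
    class = "synthetic_cohort"
  )
}

# Per-subject areal-topology variation: each round flips a random subset of
# boundary vertices to a neighbouring parcel's label. Vertices farther than
# `rounds` hops from a template boundary can never change.
jitter_boundaries <- function(g, labels, rounds, seed = 1L) {
  if (rounds == 0L) return(labels)
  set.seed(seed)
  lab <- labels$labels
  A <- g$adjacency
  trip <- Matrix::summary(methods::as(A, "TsparseMatrix"))
  for (r in seq_len(rounds)) {
    diff_edge <- lab[trip$i] != lab[trip$j]
    boundary <- unique(trip$i[diff_edge])
    flip <- boundary[stats::runif(length(boundary)) < 0.5]
    for (v in flip) {
      nb <- trip$j[trip$i == v]
      cand <- unique(lab[nb][lab[nb] != lab[v]])
      if (length(cand)) lab[v] <- cand[sample.int(length(cand), 1L)]
    }
  }
  label_map(lab, num_classes = labels$num_classes,
            unlabeled_code = labels$unlabeled_code)
}
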