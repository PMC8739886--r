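# Shared fixtures, all built in code.

# surface_graph from an explicit edge list (for path/star/toy graphs that
# are not triangulations)
graph_from_edges <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L, byrow = TRUE)
  adj <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                              j = c(edges[, 2], edges[, 1]),
                              x = 1, dims = c(n, n))
  adj <- methods::as(adj > 0, "CsparseMatrix")
  diag(adj) <- FALSE
  structure(
    list(vertices = cbind(seq_len(n), 0, 0), faces = matrix(integer(0), 0, 3),
         adjacency = Matrix::drop0(adj), n_vertices = n),
    class = "surface_graph"
  )
}

path_graph <- function(n) {
  graph_from_edges(n, as.vector(rbind(seq_len(n - 1L), seq.int(2L, n))))
}

star_graph <- function(leaves) {
  graph_from_edges(leaves + 1L, as.vector(rbind(1L, seq.int(2L, leaves + 1L))))
}

# irregular mesh: icosphere plus a few extra edge subdivisions would change
# faces; instead join two fused triangles strips — use a small random
# triangulated "fan" that is connected and asymmetric
fan_mesh <- function(k = 8L) {
  # triangle fan around a hub plus an extra rim vertex to break symmetry
  verts <- rbind(c(0, 0, 0), cbind(cos(seq_len(k)), sin(seq_len(k)), 0.1 * seq_len(k)))
  faces <- cbind(1L, seq.int(2L, k), seq.int(3L, k + 1L))
  surface_graph(verts, faces)
}

rand_label_map <- function(n, C, seed, unlabeled_frac = 0) {
  set.seed(seed)
  lab <- sample.int(C, n, replace = TRUE)
  if (unlabeled_frac > 0) lab[stats::runif(n) < unlabeled_frac] <- 0L
  label_map(lab, num_classes = C)
}

tiny_model_dataset <- function(arch = "gat", n_graphs = 4L, seed = 5L) {
  g <- make_mesh(1L, radial_noise_sd = 0.02, seed = seed)
  labels <- make_parcellation(g, 3L, seed = seed)
  set.seed(seed)
  samples <- lapply(seq_len(n_graphs), function(i) {
    ts <- make_time_series(labels, 40L, snr = 4, seed = seed + i)
    reg <- regional_mean_series(ts, labels)
    conn <- connectivity_features(ts, reg)
    list(graph = g, features = conn$values, labels = labels)
  })
  surf_dataset(samples, c("train", "train", "validation", "test")[seq_len(n_graphs)])
}
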