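#' Build a surface graph from a triangulated mesh
#'
#' Converts a triangle mesh (vertex coordinates plus face index triples) into
#' the undirected vertex-adjacency graph used by every other component: two
#' vertices are adjacent exactly when they share an edge of some triangle.
#'
#' @param vertices numeric matrix, N x 3 vertex coordinates (mm).
#' @param faces integer matrix, M x 3 vertex indices (1-based).
#' @return A `surface_graph` object: a list with elements `vertices`, `faces`,
#'   `adjacency` (sparse symmetric logical N x N, empty diagonal) and
#'   `n_vertices`.
#' @examples
#' g <- surface_graph(diag(3), matrix(c(1, 2, 3), 1))
#' Matrix::rowSums(g$adjacency)  # every vertex of a lone triangle has 2 neighbours
#' @export
surface_graph <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns (x, y, z)")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) == 0L) stop("`faces` is empty: a mesh needs at least one triangle")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns (triangles)")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n)) {
    bad <- faces[faces < 1L | faces > n][1L]
    stop(sprintf("face index %d out of range [1, %d]", bad, n))
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]
  if (any(degen)) stop(sprintf("%d degenerate face(s) with repeated vertex indices", sum(degen)))

  # each triangle contributes its three undirected edges
  i <- c(faces[, 1], faces[, 2], faces[, 3])
  j <- c(faces[, 2], faces[, 3], faces[, 1])
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  adj <- methods::as(adj > 0, "CsparseMatrix")  # logical, symmetric
  diag(adj) <- FALSE
  adj <- Matrix::drop0(adj)

  structure(
    list(vertices = vertices, faces = faces, adjacency = adj, n_vertices = n),
    class = "surface_graph"
  )
}

#' @export
print.surface_graph <- function(x, ...) {
  cat(sprintf(
    "<surface_graph> %d vertices, %d faces, %d edges\n",
    x$n_vertices, nrow(x$faces), Matrix::nnzero(x$adjacency) / 2
  ))
  invisible(x)
}

vertex_degrees <- function(g) {
  as.numeric(Matrix::rowSums(g$adjacency))
}

#' Test whether a surface graph is connected
#'
#' @param g a `surface_graph`.
#' @return TRUE if every vertex is reachable from vertex 1.
#' @export
is_connected <- function(g) {
  all(is.finite(geodesic_hops(g, 1L)))
}

#' Symmetric normalized graph Laplacian
#'
#' Computes L = I - D^(-1/2) A D^(-1/2), whose eigenvalues lie in [0, 2] with
#' smallest eigenvalue 0 for a connected graph.
#'
#' @param g a `surface_graph`.
#' @return a sparse symmetric N x N `Matrix`.
#' @export
normalized_laplacian <- function(g) {
  deg <- vertex_degrees(g)
  if (any(deg == 0)) {
    stop(sprintf("isolated vertex (zero degree) at index %d", which(deg == 0)[1L]))
  }
  dinv <- 1 / sqrt(deg)
  A <- methods::as(g$adjacency, "dMatrix")
  L <- Matrix::Diagonal(g$n_vertices) - Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
  Matrix::forceSymmetric(L)
}

#' Spectral position coordinates from the mesh Laplacian
#'
#' Eigenvectors of the normalized graph Laplacian form an intrinsic coordinate
#' system of the surface, invariant to rotation and translation of the mesh.
#' The constant eigenvector (eigenvalue 0) carries no positional information
#' and is excluded; the d eigenvectors with the smallest strictly positive
#' eigenvalues are returned in ascending eigenvalue order. Solver sign
#' ambiguity is fixed by requiring each column's largest-magnitude entry to be
#' positive (ties broken by the earliest such entry).
#'
#' @param g a connected `surface_graph`.
#' @param d number of eigenvectors to retain (default 3).
#' @return A `spectral_coords` object: list with `eigenvectors` (N x d,
#'   unit-norm columns) and `eigenvalues` (ascending, positive).
#' @export
spectral_coordinates <- function(g, d = 3L) {
  n <- g$n_vertices
  if (d >= n) stop("`d` must be smaller than the number of vertices")
  if (!is_connected(g)) {
    stop("graph is disconnected: repeated zero eigenvalues make the leading eigenvectors ill-defined")
  }
  L <- as.matrix(normalized_laplacian(g))
  eig <- eigen(L, symmetric = TRUE)
  # eigen() returns descending order; reverse to ascending
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  # drop the single (numerically) zero eigenvalue of the connected graph
  keep <- seq.int(2L, 1L + d)
  vals <- vals[keep]
  vecs <- vecs[, keep, drop = FALSE]
  vecs <- canonical_sign(vecs)
  vecs <- sweep(vecs, 2L, sqrt(colSums(vecs^2)), "/")
  structure(list(eigenvectors = vecs, eigenvalues = vals), class = "spectral_coords")
}

canonical_sign <- function(vecs) {
  for (k in seq_len(ncol(vecs))) {
    idx <- which.max(abs(vecs[, k]))
    if (vecs[idx, k] < 0) vecs[, k] <- -vecs[, k]
  }
  vecs
}

#' Align subject spectral coordinates to a template
#'
#' Eigendecomposition determines eigenvectors only up to sign, and near-equal
#' eigenvalues can swap order across subjects. This reorders and sign-flips
#' the subject's eigenvector columns against a template by solving the
#' assignment problem (Hungarian algorithm) on the cost matrix
#' `cost(i, j) = 1 - |r(template_i, subject_j)|`, with the sign of each
#' matched column chosen so that its correlation with the template column is
#' positive.
#'
#' @param template,subject `spectral_coords` with equal N and d.
#' @return list with `aligned` (a `spectral_coords`), `permutation` (subject
#'   column matched to each template column), `signs` (+1/-1 per template
#'   column) and `cost` (total assignment cost).
#' @export
align_spectral <- function(template, subject) {
  Tm <- template$eigenvectors
  S <- subject$eigenvectors
  if (!all(dim(Tm) == dim(S))) stop("template and subject must have equal N and d")
  if (any(apply(Tm, 2, stats::sd) == 0) || any(apply(S, 2, stats::sd) == 0)) {
    stop("zero-variance eigenvector column: correlation undefined")
  }
  r <- stats::cor(Tm, S)            # d x d, rows = template columns
  cost <- 1 - abs(r)
  perm <- hungarian(cost)
  signs <- ifelse(r[cbind(seq_along(perm), perm)] >= 0, 1, -1)
  aligned <- sweep(S[, perm, drop = FALSE], 2L, signs, "*")
  list(
    aligned = structure(
      list(eigenvectors = aligned, eigenvalues = subject$eigenvalues[perm]),
      class = "spectral_coords"
    ),
    permutation = perm,
    signs = signs,
    cost = sum(cost[cbind(seq_along(perm), perm)])
  )
}

# O(n^3) Hungarian algorithm (Jonker-Volgenant style augmenting paths on a
# square cost matrix). Returns, for each row, the assigned column.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j+1] = row assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) assignment[p[j + 1]] <- j
  assignment
}

#' Breadth-first hop distances to a vertex set
#'
#' Geodesic distance measured in mesh edges (hops) from each vertex to the
#' nearest source vertex. Used both for boundary-distance error profiles and
#' for geodesic Voronoi parcel construction.
#'
#' @param g a `surface_graph`.
#' @param sources integer vertex indices (1-based), non-empty.
#' @return numeric N-vector of hop counts; `Inf` for unreachable vertices.
#' @export
geodesic_hops <- function(g, sources) {
  sources <- as.integer(sources)
  if (length(sources) == 0L) stop("`sources` must be non-empty")
  if (any(sources < 1L | sources > g$n_vertices)) stop("source index out of range")
  A <- g$adjacency
  dist <- rep(Inf, g$n_vertices)
  dist[sources] <- 0
  frontier <- logical(g$n_vertices)
  frontier[sources] <- TRUE
  k <- 0
  while (any(frontier)) {
    k <- k + 1
    reached <- as.logical(A %*% frontier > 0)
    frontier <- reached & !is.finite(dist)
    dist[frontier] <- k
  }
  dist
}
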