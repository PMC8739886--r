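# Layer primitives with explicit forward caches and hand-derived backward
# passes. All tensors are dense base-R matrices; neighborhood aggregation
# goes through sparse Matrix products.

leakyrelu <- function(x, slope = 0.2) {
  ifelse(x > 0, x, slope * x)
}

dleakyrelu <- function(x, slope = 0.2) {
  ifelse(x > 0, 1, slope)
}

# grouped sum of a vector by integer index, dense length-n result
rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# numerically stable softmax over edge scores grouped by center vertex
segment_softmax <- function(e, ei, n) {
  m <- tapply(e, factor(ei, levels = seq_len(n)), max)
  ex <- exp(e - as.numeric(m)[ei])
  denom <- rowsum_vec(ex, ei, n)
  as.numeric(ex / denom[ei])
}

# renormalized propagation operator D~^(-1/2) (A + I) D~^(-1/2)
gcn_propagator <- function(g) {
  A <- methods::as(g$adjacency, "dMatrix") + Matrix::Diagonal(g$n_vertices)
  d <- 1 / sqrt(Matrix::rowSums(A))
  Matrix::Diagonal(x = d) %*% A %*% Matrix::Diagonal(x = d)
}

# directed edge list (center i, neighbor j) including self-edges, the
# attention neighborhood N_i  U {i}
gat_edges <- function(g) {
  trip <- methods::as(methods::as(g$adjacency, "dMatrix"), "TsparseMatrix")
  n <- g$n_vertices
  list(ei = c(trip@i + 1L, seq_len(n)), ej = c(trip@j + 1L, seq_len(n)), n = n)
}

#' Graph convolution layer
#'
#' One spectral graph convolution of polynomial order 1: each vertex mixes
#' its own (self-loop) signal with its direct neighbors through the
#' renormalized propagation operator, then applies a shared linear
#' projection and pointwise nonlinearity.
#'
#' @param H numeric N x k input matrix.
#' @param g a `surface_graph`.
#' @param W k x k' projection matrix.
#' @param b optional length-k' bias.
#' @param activation `"leakyrelu"` or `"linear"`.
#' @param negative_slope LeakyReLU slope.
#' @return N x k' output matrix.
#' @export
gcn_layer <- function(H, g, W, b = NULL, activation = c("leakyrelu", "linear"),
                      negative_slope = 0.2) {
  activation <- match.arg(activation)
  H <- as.matrix(H)
  if (nrow(H) != g$n_vertices) stop("H row count must equal the vertex count")
  if (nrow(W) != ncol(H)) {
    stop(sprintf("shape mismatch: H has %d columns but W has %d rows", ncol(H), nrow(W)))
  }
  fw <- gcn_fwd(gcn_propagator(g), H, W,
                b %||% numeric(ncol(W)),
                linear = activation == "linear", slope = negative_slope)
  fw$out
}

gcn_fwd <- function(Ahat, H, W, b, linear = FALSE, slope = 0.2) {
  pre <- as.matrix(Ahat %*% (H %*% W))
  pre <- sweep(pre, 2L, b, "+")
  out <- if (linear) pre else leakyrelu(pre, slope)
  list(out = out, cache = list(Ahat = Ahat, H = H, W = W, pre = pre,
                               linear = linear, slope = slope))
}

gcn_bwd <- function(cache, dout) {
  dpre <- if (cache$linear) dout else dout * dleakyrelu(cache$pre, cache$slope)
  back <- as.matrix(cache$Ahat %*% dpre)   # Ahat is symmetric
  dW <- crossprod(cache$H, back)
  dH <- back %*% t(cache$W)
  db <- colSums(dpre)
  list(dH = dH, dW = dW, db = db)
}

#' Graph attention layer (multi-head)
#'
#' For every head, each vertex attends over its neighborhood (itself plus
#' direct neighbors): the raw attention score for the pair (i, j) is
#' `LeakyReLU(a1 . W h_i + a2 . W h_j)`, normalized by a softmax over the
#' neighborhood of i, and the vertex update is the attention-weighted sum of
#' the projected neighbor features. Hidden layers concatenate head outputs;
#' the final layer averages them.
#'
#' @param H numeric N x k input matrix.
#' @param g a `surface_graph`.
#' @param W k x k' x M array (or k x k' matrix for M = 1) of per-head
#'   projections.
#' @param a1,a2 k' x M matrices (or length-k' vectors): attention weights on
#'   the center and neighbor projections (the two halves of the
#'   concatenation-based attention vector).
#' @param mode `"concat"` (N x M k') or `"average"` (N x k').
#' @param negative_slope LeakyReLU slope of the attention score.
#' @param return_attention also return the per-head edge attention weights.
#' @return output matrix; with `return_attention`, a list `(out, attention)`
#'   where `attention` has columns ei, ej and one weight column per head.
#' @export
gat_layer <- function(H, g, W, a1, a2, mode = c("concat", "average"),
                      negative_slope = 0.2, return_attention = FALSE) {
  mode <- match.arg(mode)
  H <- as.matrix(H)
  if (is.matrix(W)) W <- array(W, c(nrow(W), ncol(W), 1L))
  if (is.null(dim(a1))) a1 <- matrix(a1, ncol = 1L)
  if (is.null(dim(a2))) a2 <- matrix(a2, ncol = 1L)
  edges <- gat_edges(g)
  fw <- gat_fwd(edges, H, W, a1, a2, average = mode == "average",
                slope = negative_slope)
  if (!return_attention) return(fw$out)
  att <- data.frame(ei = edges$ei, ej = edges$ej)
  for (m in seq_len(dim(W)[3])) att[[paste0("head", m)]] <- fw$cache$heads[[m]]$alpha
  list(out = fw$out, attention = att)
}

# Multi-head GAT layer forward. W: kin x kout x M; a1, a2: kout x M.
gat_fwd <- function(edges, H, W, a1, a2, average = FALSE, slope = 0.2) {
  M <- dim(W)[3]
  n <- edges$n
  heads <- vector("list", M)
  outs <- vector("list", M)
  for (m in seq_len(M)) {
    Z <- H %*% W[, , m]
    s1 <- as.numeric(Z %*% a1[, m])
    s2 <- as.numeric(Z %*% a2[, m])
    elin <- s1[edges$ei] + s2[edges$ej]
    epre <- leakyrelu(elin, slope)
    alpha <- segment_softmax(epre, edges$ei, n)
    P <- Matrix::sparseMatrix(i = edges$ei, j = edges$ej, x = alpha, dims = c(n, n))
    outs[[m]] <- as.matrix(P %*% Z)
    heads[[m]] <- list(Z = Z, elin = elin, alpha = alpha, P = P)
  }
  out <- if (average) Reduce(`+`, outs) / M else do.call(cbind, outs)
  list(out = out, cache = list(edges = edges, H = H, W = W, a1 = a1, a2 = a2,
                               heads = heads, average = average, slope = slope,
                               kout = dim(W)[2]))
}

gat_bwd <- function(cache, dout) {
  edges <- cache$edges
  M <- dim(cache$W)[3]
  n <- edges$n
  kout <- cache$kout
  dW <- array(0, dim(cache$W))
  da1 <- matrix(0, kout, M)
  da2 <- matrix(0, kout, M)
  dH <- matrix(0, nrow(cache$H), ncol(cache$H))
  for (m in seq_len(M)) {
    hd <- cache$heads[[m]]
    dout_m <- if (cache$average) dout / M else dout[, (m - 1L) * kout + seq_len(kout), drop = FALSE]
    dZ <- as.matrix(Matrix::crossprod(hd$P, dout_m))
    dalpha <- rowSums(dout_m[edges$ei, , drop = FALSE] * hd$Z[edges$ej, , drop = FALSE])
    gsum <- rowsum_vec(hd$alpha * dalpha, edges$ei, n)
    depre <- hd$alpha * (dalpha - gsum[edges$ei])
    delin <- depre * dleakyrelu(hd$elin, cache$slope)
    ds1 <- rowsum_vec(delin, edges$ei, n)
    ds2 <- rowsum_vec(delin, edges$ej, n)
    da1[, m] <- as.numeric(crossprod(hd$Z, ds1))
    da2[, m] <- as.numeric(crossprod(hd$Z, ds2))
    dZ <- dZ + outer(ds1, cache$a1[, m]) + outer(ds2, cache$a2[, m])
    dW[, , m] <- crossprod(cache$H, dZ)
    dH <- dH + dZ %*% t(cache$W[, , m])
  }
  list(dH = dH, dW = dW, da1 = da1, da2 = da2)
}

# dense layer: out = act(H W + b)
dense_fwd <- function(H, W, b, linear = FALSE, slope = 0.2) {
  pre <- sweep(H %*% W, 2L, b, "+")
  out <- if (linear) pre else leakyrelu(pre, slope)
  list(out = out, cache = list(H = H, W = W, pre = pre, linear = linear, slope = slope))
}

dense_bwd <- function(cache, dout) {
  dpre <- if (cache$linear) dout else dout * dleakyrelu(cache$pre, cache$slope)
  list(dH = dpre %*% t(cache$W), dW = crossprod(cache$H, dpre), db = colSums(dpre))
}

# inverted dropout; draws from the current RNG stream
dropout_fwd <- function(H, rate, training) {
  if (!training || rate <= 0) return(list(out = H, mask = NULL))
  mask <- matrix((stats::runif(length(H)) >= rate) / (1 - rate), nrow(H))
  list(out = H * mask, mask = mask)
}
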