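# Jumping-knowledge layer aggregation. Every graph layer of a JK network
# emits a per-vertex embedding; the aggregator combines the L embeddings of
# each vertex into one output. Concatenation is a global aggregator;
# max-pooling and the bidirectional-LSTM attention learn vertex-specific
# combinations. The LSTM scores each layer from its forward and backward
# hidden states and softmax-normalizes the scores into per-vertex layer
# attention weights (non-negative, summing to 1 across layers).

sigmoid <- function(x) 1 / (1 + exp(-x))

init_jk_lstm <- function(q, r) {
  list(
    fwd = list(Wx = glorot(q, 4L * r), Wh = glorot(r, 4L * r), b = lstm_bias(r)),
    bwd = list(Wx = glorot(q, 4L * r), Wh = glorot(r, 4L * r), b = lstm_bias(r)),
    u = glorot(2L * r, 1L)
  )
}

lstm_bias <- function(r) {
  b <- numeric(4L * r)
  b[r + seq_len(r)] <- 1       # forget-gate bias starts open
  b
}

# one LSTM direction over the layer sequence; xs = list of L (N x q)
lstm_dir_fwd <- function(xs, par) {
  L <- length(xs)
  n <- nrow(xs[[1]])
  r <- nrow(par$Wh)
  h <- matrix(0, n, r)
  cc <- matrix(0, n, r)
  steps <- vector("list", L)
  hs <- vector("list", L)
  for (l in seq_len(L)) {
    A <- sweep(xs[[l]] %*% par$Wx + h %*% par$Wh, 2L, par$b, "+")
    ig <- sigmoid(A[, seq_len(r), drop = FALSE])
    fg <- sigmoid(A[, r + seq_len(r), drop = FALSE])
    gg <- tanh(A[, 2L * r + seq_len(r), drop = FALSE])
    og <- sigmoid(A[, 3L * r + seq_len(r), drop = FALSE])
    c_prev <- cc
    cc <- fg * c_prev + ig * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- og * tc
    steps[[l]] <- list(ig = ig, fg = fg, gg = gg, og = og, c_prev = c_prev,
                       cc = cc, tc = tc, h_prev = h_prev, x = xs[[l]])
    hs[[l]] <- h
  }
  list(hs = hs, steps = steps, r = r)
}

lstm_dir_bwd <- function(fw, par, dhs) {
  L <- length(fw$steps)
  r <- fw$r
  n <- nrow(dhs[[1]])
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
  db <- numeric(length(par$b))
  dxs <- vector("list", L)
  dh_carry <- matrix(0, n, r)
  dc_next <- matrix(0, n, r)
  for (l in rev(seq_len(L))) {
    st <- fw$steps[[l]]
    dh <- dhs[[l]] + dh_carry
    dog <- dh * st$tc
    dct <- dh * st$og * (1 - st$tc^2) + dc_next
    dig <- dct * st$gg
    dgg <- dct * st$ig
    dfg <- dct * st$c_prev
    dc_next <- dct * st$fg
    dA <- cbind(dig * st$ig * (1 - st$ig),
                dfg * st$fg * (1 - st$fg),
                dgg * (1 - st$gg^2),
                dog * st$og * (1 - st$og))
    dWx <- dWx + crossprod(st$x, dA)
    dWh <- dWh + crossprod(st$h_prev, dA)
    db <- db + colSums(dA)
    dxs[[l]] <- dA %*% t(par$Wx)
    dh_carry <- dA %*% t(par$Wh)
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

jk_lstm_fwd <- function(xs, par) {
  L <- length(xs)
  n <- nrow(xs[[1]])
  f <- lstm_dir_fwd(xs, par$fwd)
  b <- lstm_dir_fwd(rev(xs), par$bwd)
  bw_hs <- rev(b$hs)                       # align backward states with layer order
  r <- f$r
  scores <- matrix(0, n, L)
  for (l in seq_len(L)) {
    scores[, l] <- cbind(f$hs[[l]], bw_hs[[l]]) %*% par$u
  }
  mx <- apply(scores, 1L, max)
  ex <- exp(scores - mx)
  w <- ex / rowSums(ex)                    # per-vertex layer attention
  out <- matrix(0, n, ncol(xs[[1]]))
  for (l in seq_len(L)) out <- out + w[, l] * xs[[l]]
  list(out = out, weights = w,
       cache = list(xs = xs, f = f, b = b, bw_hs = bw_hs, w = w, r = r, par = par))
}

jk_lstm_bwd <- function(cache, dout) {
  xs <- cache$xs
  L <- length(xs)
  n <- nrow(dout)
  r <- cache$r
  w <- cache$w
  par <- cache$par
  dw <- matrix(0, n, L)
  dxs <- vector("list", L)
  for (l in seq_len(L)) {
    dw[, l] <- rowSums(dout * xs[[l]])
    dxs[[l]] <- w[, l] * dout
  }
  ds <- w * (dw - rowSums(w * dw))         # softmax backward, row-wise
  du <- matrix(0, 2L * r, 1L)
  dhf <- vector("list", L)
  dhb <- vector("list", L)
  u1 <- par$u[seq_len(r), 1L]
  u2 <- par$u[r + seq_len(r), 1L]
  for (l in seq_len(L)) {
    du <- du + crossprod(cbind(cache$f$hs[[l]], cache$bw_hs[[l]]), ds[, l, drop = FALSE])
    dhf[[l]] <- outer(ds[, l], u1)
    dhb[[l]] <- outer(ds[, l], u2)
  }
  gf <- lstm_dir_bwd(cache$f, par$fwd, dhf)
  gb <- lstm_dir_bwd(cache$b, par$bwd, rev(dhb))
  gb_dxs <- rev(gb$dxs)
  for (l in seq_len(L)) dxs[[l]] <- dxs[[l]] + gf$dxs[[l]] + gb_dxs[[l]]
  list(dxs = dxs,
       grads = list(fwd = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
                    bwd = list(Wx = gb$dWx, Wh = gb$dWh, b = gb$db),
                    u = du))
}

#' Jumping-knowledge aggregation of layer embeddings
#'
#' Combines the per-vertex embeddings from every hidden layer of a network
#' into a single output embedding, giving each vertex an adaptive effective
#' depth. Three aggregators are supported: `concat` (column-wise
#' concatenation, width L*k), `maxpool` (element-wise maximum across layers),
#' and `lstm` (a bidirectional LSTM reads the layer sequence and produces
#' per-vertex, per-layer attention weights that sum to 1; the output is the
#' attention-weighted sum of the layer embeddings).
#'
#' @param embeddings list of L matrices, all N x k.
#' @param mode `"concat"`, `"maxpool"`, or `"lstm"`.
#' @param lstm for `mode = "lstm"`, the aggregator parameters as produced by
#'   the model initializer; if NULL a fresh parameter set is drawn with
#'   seed 1 (useful for inspection, not training).
#' @param lstm_hidden hidden size of the LSTM when parameters are drawn here.
#' @param return_weights for `"lstm"`, also return the N x L attention
#'   weight matrix.
#' @return the aggregated matrix, or a list `(out, weights)`.
#' @export
jk_aggregate <- function(embeddings, mode = c("concat", "maxpool", "lstm"),
                         lstm = NULL, lstm_hidden = NULL, return_weights = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(embeddings) >= 1L)
  dims <- vapply(embeddings, nrow, 1L)
  if (length(unique(dims)) != 1L) stop("embeddings disagree on N")
  if (mode == "concat") {
    out <- do.call(cbind, embeddings)
    return(if (return_weights) list(out = out, weights = NULL) else out)
  }
  if (mode == "maxpool") {
    out <- Reduce(pmax, embeddings)
    return(if (return_weights) list(out = out, weights = NULL) else out)
  }
  q <- ncol(embeddings[[1]])
  if (is.null(lstm)) {
    r <- lstm_hidden %||% q
    old <- .Random.seed_save()
    set.seed(1L)
    lstm <- init_jk_lstm(q, r)
    .Random.seed_restore(old)
  }
  fw <- jk_lstm_fwd(embeddings, lstm)
  if (return_weights) list(out = fw$out, weights = fw$weights) else fw$out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
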