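#' Model architecture specification
#'
#' Describes one of the four vertex classifiers. `depth` counts all layers
#' including the output layer: for `baseline` and `gcn` the first
#' `depth - 1` layers are hidden (LeakyReLU) and the last is linear to C
#' logits; for `gat` hidden layers concatenate head outputs and the final
#' attention layer maps each head to C and averages heads; `jkgat` stacks
#' `depth` hidden attention layers, aggregates their embeddings with the
#' jumping-knowledge mechanism, and maps to C logits with a linear head.
#'
#' @param architecture `"baseline"`, `"gcn"`, `"gat"`, or `"jkgat"`.
#' @param num_classes number of output classes C.
#' @param depth layer count L (default 3).
#' @param hidden_channels hidden width k per layer (default 32).
#' @param attention_heads heads M per attention layer (default 4).
#' @param dropout feature dropout rate in [0, 1) applied to every layer's
#'   input during training (default 0.1).
#' @param aggregation jumping-knowledge aggregator, `"concat"`, `"maxpool"`
#'   or `"lstm"` (default; jkgat only).
#' @param negative_slope LeakyReLU negative slope (default 0.2).
#' @param lstm_hidden hidden size of the JK bidirectional LSTM (defaults to
#'   `hidden_channels`).
#' @return a `model_spec` object.
#' @export
model_spec <- function(architecture = c("baseline", "gcn", "gat", "jkgat"),
                       num_classes, depth = 3L, hidden_channels = 32L,
                       attention_heads = 4L, dropout = 0.1,
                       aggregation = c("lstm", "concat", "maxpool"),
                       negative_slope = 0.2, lstm_hidden = hidden_channels) {
  architecture <- match.arg(architecture)
  aggregation <- match.arg(aggregation)
  stopifnot(depth >= 1L, num_classes >= 2L, dropout >= 0, dropout < 1,
            hidden_channels >= 1L, attention_heads >= 1L)
  structure(
    list(architecture = architecture, num_classes = as.integer(num_classes),
         depth = as.integer(depth), hidden_channels = as.integer(hidden_channels),
         attention_heads = as.integer(attention_heads), dropout = dropout,
         aggregation = aggregation, negative_slope = negative_slope,
         lstm_hidden = as.integer(lstm_hidden)),
    class = "model_spec"
  )
}

glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

glorot_heads <- function(fin, fout, M) {
  array(stats::runif(fin * fout * M, -sqrt(6 / (fin + fout)), sqrt(6 / (fin + fout))),
        c(fin, fout, M))
}

#' Initialize model weights
#'
#' Uniform fan-based (Glorot) initialization drawn from the current RNG
#' stream, or from `seed` when given.
#'
#' @param spec a `model_spec`.
#' @param input_dim feature count F of the input matrix.
#' @param seed optional integer seed.
#' @return a `trained_model` (untrained weights, empty training log).
#' @export
init_model <- function(spec, input_dim, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  L <- spec$depth
  k <- spec$hidden_channels
  M <- spec$attention_heads
  C <- spec$num_classes
  arch <- spec$architecture
  params <- list()
  if (arch %in% c("baseline", "gcn")) {
    widths <- c(input_dim, rep(k, max(L - 1L, 0L)), C)
    params$layers <- lapply(seq_len(L), function(l) {
      list(W = glorot(widths[l], widths[l + 1L]), b = numeric(widths[l + 1L]))
    })
  } else if (arch == "gat") {
    ins <- c(input_dim, rep(M * k, max(L - 1L, 0L)))
    outs <- c(rep(k, max(L - 1L, 0L)), C)
    params$layers <- lapply(seq_len(L), function(l) {
      list(W = glorot_heads(ins[l], outs[l], M),
           a1 = glorot(outs[l], M), a2 = glorot(outs[l], M))
    })
  } else { # jkgat
    ins <- c(input_dim, rep(M * k, L - 1L))
    params$layers <- lapply(seq_len(L), function(l) {
      list(W = glorot_heads(ins[l], k, M),
           a1 = glorot(k, M), a2 = glorot(k, M))
    })
    q <- M * k
    if (spec$aggregation == "lstm") {
      params$jk <- init_jk_lstm(q, spec$lstm_hidden)
    }
    out_in <- if (spec$aggregation == "concat") L * q else q
    params$out <- list(W = glorot(out_in, C), b = numeric(C))
  }
  structure(
    list(spec = spec, input_dim = as.integer(input_dim), params = params,
         training_log = NULL),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s, depth %d, %d -> %d classes, %d parameters\n",
              x$spec$architecture, x$spec$depth, x$input_dim,
              x$spec$num_classes, length(unlist(x$params))))
  invisible(x)
}

# precompute the architecture's graph operator once per mesh
graph_context <- function(g, architecture) {
  switch(architecture,
         baseline = list(),
         gcn = list(Ahat = gcn_propagator(g)),
         gat = ,
         jkgat = list(edges = gat_edges(g)))
}

#' Forward pass: per-vertex class logits
#'
#' @param model a `trained_model`.
#' @param g the `surface_graph` the features live on (ignored by the
#'   baseline architecture).
#' @param X numeric N x F feature matrix with F equal to the model's input
#'   width.
#' @param train_mode apply feature dropout (draws from the current RNG
#'   stream); evaluation mode (default) is deterministic.
#' @return numeric N x C logit matrix.
#' @export
forward <- function(model, g, X, train_mode = FALSE) {
  forward_full(model, graph_context(g, model$spec$architecture), X, train_mode)$logits
}

forward_full <- function(model, gctx, X, training = FALSE) {
  spec <- model$spec
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("feature width mismatch: model expects F = %d, got %d",
                 model$input_dim, ncol(X)))
  }
  p <- model$params
  L <- spec$depth
  slope <- spec$negative_slope
  caches <- vector("list", L)
  drops <- vector("list", L)
  H <- X
  if (spec$architecture %in% c("baseline", "gcn")) {
    for (l in seq_len(L)) {
      dp <- dropout_fwd(H, spec$dropout, training)
      drops[l] <- list(dp$mask)
      last <- l == L
      fw <- if (spec$architecture == "baseline") {
        dense_fwd(dp$out, p$layers[[l]]$W, p$layers[[l]]$b, linear = last, slope = slope)
      } else {
        gcn_fwd(gctx$Ahat, dp$out, p$layers[[l]]$W, p$layers[[l]]$b,
                linear = last, slope = slope)
      }
      caches[[l]] <- fw$cache
      H <- fw$out
    }
    logits <- H
    return(list(logits = logits, cache = list(caches = caches, drops = drops)))
  }
  if (spec$architecture == "gat") {
    for (l in seq_len(L)) {
      dp <- dropout_fwd(H, spec$dropout, training)
      drops[l] <- list(dp$mask)
      last <- l == L
      fw <- gat_fwd(gctx$edges, dp$out, p$layers[[l]]$W, p$layers[[l]]$a1,
                    p$layers[[l]]$a2, average = last, slope = slope)
      if (!last) {
        caches[[l]] <- c(fw$cache, list(pre_act = fw$out))
        H <- leakyrelu(fw$out, slope)
      } else {
        caches[[l]] <- fw$cache
        H <- fw$out
      }
    }
    return(list(logits = H, cache = list(caches = caches, drops = drops)))
  }
  # jkgat
  embeddings <- vector("list", L)
  for (l in seq_len(L)) {
    dp <- dropout_fwd(H, spec$dropout, training)
    drops[l] <- list(dp$mask)
    fw <- gat_fwd(gctx$edges, dp$out, p$layers[[l]]$W, p$layers[[l]]$a1,
                  p$layers[[l]]$a2, average = FALSE, slope = slope)
    caches[[l]] <- c(fw$cache, list(pre_act = fw$out))
    H <- leakyrelu(fw$out, slope)
    embeddings[[l]] <- H
  }
  if (spec$aggregation == "lstm") {
    agg <- jk_lstm_fwd(embeddings, p$jk)
    Y <- agg$out
    jk_cache <- agg$cache
  } else if (spec$aggregation == "concat") {
    Y <- do.call(cbind, embeddings)
    jk_cache <- NULL
  } else {
    Y <- Reduce(pmax, embeddings)
    jk_cache <- embeddings
  }
  head_fw <- dense_fwd(Y, p$out$W, p$out$b, linear = TRUE)
  list(logits = head_fw$out,
       cache = list(caches = caches, drops = drops, jk_cache = jk_cache,
                    embeddings = embeddings, head = head_fw$cache))
}

backward_full <- function(model, cache, dlogits) {
  spec <- model$spec
  L <- spec$depth
  slope <- spec$negative_slope
  grads <- list()
  if (spec$architecture %in% c("baseline", "gcn")) {
    dH <- dlogits
    glayers <- vector("list", L)
    for (l in rev(seq_len(L))) {
      bw <- if (spec$architecture == "baseline") {
        dense_bwd(cache$caches[[l]], dH)
      } else {
        gcn_bwd(cache$caches[[l]], dH)
      }
      glayers[[l]] <- list(W = bw$dW, b = bw$db)
      dH <- bw$dH
      if (!is.null(cache$drops[[l]])) dH <- dH * cache$drops[[l]]
    }
    return(list(layers = glayers))
  }
  if (spec$architecture == "gat") {
    dH <- dlogits
    glayers <- vector("list", L)
    for (l in rev(seq_len(L))) {
      cc <- cache$caches[[l]]
      if (l < L) dH <- dH * dleakyrelu(cc$pre_act, slope)
      bw <- gat_bwd(cc, dH)
      glayers[[l]] <- list(W = bw$dW, a1 = bw$da1, a2 = bw$da2)
      dH <- bw$dH
      if (!is.null(cache$drops[[l]])) dH <- dH * cache$drops[[l]]
    }
    return(list(layers = glayers))
  }
  # jkgat
  head_bw <- dense_bwd(cache$head, dlogits)
  grads$out <- list(W = head_bw$dW, b = head_bw$db)
  dY <- head_bw$dH
  demb <- vector("list", L)
  if (spec$aggregation == "lstm") {
    jb <- jk_lstm_bwd(cache$jk_cache, dY)
    demb <- jb$dxs
    grads$jk <- jb$grads
  } else if (spec$aggregation == "concat") {
    q <- ncol(cache$embeddings[[1]])
    for (l in seq_len(L)) demb[[l]] <- dY[, (l - 1L) * q + seq_len(q), drop = FALSE]
  } else {
    pooled <- Reduce(pmax, cache$embeddings)
    remaining <- matrix(TRUE, nrow(pooled), ncol(pooled))
    for (l in seq_len(L)) {
      is_max <- (cache$embeddings[[l]] >= pooled) & remaining
      remaining <- remaining & !is_max     # ties routed to the earliest layer
      demb[[l]] <- dY * is_max
    }
  }
  glayers <- vector("list", L)
  dH_carry <- NULL
  for (l in rev(seq_len(L))) {
    cc <- cache$caches[[l]]
    dH <- demb[[l]]
    if (!is.null(dH_carry)) dH <- dH + dH_carry
    dH <- dH * dleakyrelu(cc$pre_act, slope)
    bw <- gat_bwd(cc, dH)
    glayers[[l]] <- list(W = bw$dW, a1 = bw$da1, a2 = bw$da2)
    dH_carry <- bw$dH
    if (!is.null(cache$drops[[l]])) dH_carry <- dH_carry * cache$drops[[l]]
  }
  grads$layers <- glayers
  grads[c("layers", "jk", "out")[c(TRUE, spec$aggregation == "lstm", TRUE)]]
}

# flatten a parameter tree to a vector and back (order-stable)
flatten_params <- function(p) as.numeric(unlist(p, use.names = FALSE))

unflatten_like <- function(skel, v) {
  pos <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    attributes(out) <- attributes(x)
    out
  }
  out <- rec(skel)
  stopifnot(pos == length(v))
  out
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint holds the architecture spec, input width, all weight
#' tensors and the training log; a load followed by [forward()] reproduces
#' logits bit-exactly.
#'
#' @param model a `trained_model`.
#' @param path file path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `trained_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_model")) stop("not a surfgnn model checkpoint")
  model
}
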