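test_that("graph convolution layer propagates over the 1-ring only", {
  # no edges: output is H scaled by the self-loop normalization (identity here)
  g0 <- graph_from_edges(3, integer(0))
  H <- matrix(rnorm(6), 3)
  out <- gcn_layer(H, g0, diag(2), activation = "linear")
  expect_equal(out, H, tolerance = 1e-12)

  # 1-hop receptive field: perturbing u changes v's output iff v in {u} U N(u)
  p5 <- path_graph(5)
  set.seed(1)
  H5 <- matrix(rnorm(10), 5)
  W <- matrix(rnorm(4), 2)
  base <- gcn_layer(H5, p5, W, activation = "linear")
  H5p <- H5; H5p[3, ] <- H5p[3, ] + 1
  pert <- gcn_layer(H5p, p5, W, activation = "linear")
  changed <- rowSums(abs(pert - base)) > 0
  expect_equal(changed, c(FALSE, TRUE, TRUE, TRUE, FALSE))

  # constant signal on a path: renormalized propagation preserves it exactly
  # (A + I normalization makes constant vectors eigenvectors with value 1)
  Hc <- matrix(1, 5, 1)
  outc <- gcn_layer(Hc, p5, matrix(1), activation = "linear")
  Ahat <- as.matrix(surfgnn:::gcn_propagator(p5))
  expect_equal(outc, Ahat %*% Hc %*% matrix(1), tolerance = 1e-12)
  expect_equal(as.numeric(outc), as.numeric(Ahat %*% rep(1, 5)), tolerance = 1e-12)
})

test_that("attention reduces to uniform neighborhood averaging for identical features", {
  g <- star_graph(3)
  H <- matrix(1, 4, 2)  # all nodes identical
  W <- diag(2)
  res <- gat_layer(H, g, W, a1 = c(0.3, -0.2), a2 = c(0.5, 0.1),
                   mode = "concat", return_attention = TRUE)
  att <- res$attention
  deg <- as.numeric(Matrix::rowSums(g$adjacency))
  for (i in seq_len(4)) {
    w <- att$head1[att$ei == i]
    expect_equal(w, rep(1 / (deg[i] + 1), deg[i] + 1), tolerance = 1e-12)
  }
})

test_that("attention weights are a softmax over each neighborhood", {
  g <- make_mesh(1, radial_noise_sd = 0.03, seed = 4)
  set.seed(4)
  H <- matrix(rnorm(g$n_vertices * 3), g$n_vertices)
  W <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  res <- gat_layer(H, g, W, a1 = matrix(rnorm(4), 2), a2 = matrix(rnorm(4), 2),
                   return_attention = TRUE)
  for (h in c("head1", "head2")) {
    sums <- tapply(res$attention[[h]], res$attention$ei, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
    expect_true(all(res$attention[[h]] >= 0))
  }
})

test_that("attention node update matches a hand-evaluated weighted sum on a star", {
  # 3-node star: center 1, leaves 2..3; hand-set projections and attention
  g <- star_graph(2)
  H <- rbind(c(1, 0), c(0, 1), c(1, 1))
  W <- rbind(c(1, 0.5), c(-0.5, 1))
  a1 <- c(0.2, -0.1)
  a2 <- c(0.4, 0.3)
  slope <- 0.2
  out <- gat_layer(H, g, W, a1, a2, mode = "concat", negative_slope = slope)

  # hand evaluation for the center vertex (neighborhood {1, 2, 3})
  Z <- H %*% W
  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  e <- sapply(1:3, function(j) lrelu(sum(a1 * Z[1, ]) + sum(a2 * Z[j, ])))
  alpha <- exp(e) / sum(exp(e))
  expect_equal(out[1, ], as.numeric(alpha %*% Z), tolerance = 1e-12)
})

test_that("jumping-knowledge aggregation honors its three modes", {
  e1 <- matrix(c(1, 4), 1)
  e2 <- matrix(c(5, 2), 1)
  # element-wise max over layers
  expect_equal(jk_aggregate(list(e1, e2), "maxpool"), matrix(c(5, 4), 1))
  # concat width L*k
  embs <- replicate(3, matrix(rnorm(6 * 32), 6), simplify = FALSE)
  expect_equal(ncol(jk_aggregate(embs, "concat")), 96L)
  # single layer: all modes are the identity (lstm weight exactly 1)
  single <- list(matrix(rnorm(8), 4))
  expect_equal(jk_aggregate(single, "concat"), single[[1]])
  expect_equal(jk_aggregate(single, "maxpool"), single[[1]])
  res <- jk_aggregate(single, "lstm", return_weights = TRUE)
  expect_equal(res$weights, matrix(1, 4, 1))
  expect_equal(res$out, single[[1]], tolerance = 1e-12)
  expect_error(jk_aggregate(single, "banana"))
})

test_that("jumping-knowledge LSTM weights are convex per vertex", {
  set.seed(8)
  embs <- replicate(3, matrix(rnorm(10 * 6), 10), simplify = FALSE)
  res <- jk_aggregate(embs, "lstm", return_weights = TRUE)
  expect_true(all(res$weights >= 0))
  expect_equal(rowSums(res$weights), rep(1, 10), tolerance = 1e-6)
})

test_that("baseline logits ignore the graph entirely", {
  set.seed(21)
  g1 <- path_graph(6)
  g2 <- star_graph(5)  # same vertex count, different adjacency
  X <- matrix(rnorm(6 * 4), 6)
  spec <- model_spec("baseline", num_classes = 3, depth = 2, hidden_channels = 5)
  model <- init_model(spec, 4, seed = 3)
  expect_identical(forward(model, g1, X), forward(model, g2, X))
})

test_that("receptive fields are exactly L hops for every graph architecture", {
  p7 <- path_graph(7)
  set.seed(31)
  X <- matrix(rnorm(7 * 3), 7)
  for (arch in c("gcn", "gat", "jkgat")) {
    for (L in 1:3) {
      spec <- model_spec(arch, num_classes = 2, depth = L, hidden_channels = 3,
                         attention_heads = 2, dropout = 0, lstm_hidden = 2)
      model <- init_model(spec, 3, seed = 40 + L)
      base <- forward(model, p7, X)
      Xp <- X
      Xp[7, ] <- Xp[7, ] + 100  # perturb the far end
      pert <- forward(model, p7, Xp)
      # vertices more than L hops from vertex 7 are bit-identical
      far <- which(geodesic_hops(p7, 7L) > L)
      expect_identical(base[far, ], pert[far, ])
      # the perturbed vertex itself must change
      expect_false(isTRUE(all.equal(base[7, ], pert[7, ])))
    }
  }
})

test_that("graph models are permutation equivariant", {
  g <- make_mesh(1, radial_noise_sd = 0.02, seed = 6)
  n <- g$n_vertices
  set.seed(51)
  X <- matrix(rnorm(n * 4), n)
  perm <- sample.int(n)
  gp <- g
  gp$adjacency <- g$adjacency[perm, perm]
  gp$vertices <- g$vertices[perm, ]
  for (arch in c("baseline", "gcn", "gat", "jkgat")) {
    spec <- model_spec(arch, num_classes = 3, depth = 2, hidden_channels = 4,
                       attention_heads = 2, dropout = 0, lstm_hidden = 3)
    model <- init_model(spec, 4, seed = 7)
    out <- forward(model, g, X)
    out_p <- forward(model, gp, X[perm, ])
    expect_equal(out_p, out[perm, ], tolerance = 1e-10)
  }
})

test_that("evaluation-mode forward is deterministic and dropout only acts in training", {
  g <- make_mesh(1, radial_noise_sd = 0.02, seed = 8)
  set.seed(61)
  X <- matrix(rnorm(g$n_vertices * 3), g$n_vertices)
  spec <- model_spec("gat", num_classes = 3, depth = 2, hidden_channels = 4,
                     attention_heads = 2, dropout = 0.5)
  model <- init_model(spec, 3, seed = 9)
  expect_identical(forward(model, g, X), forward(model, g, X))
  set.seed(1); t1 <- forward(model, g, X, train_mode = TRUE)
  set.seed(2); t2 <- forward(model, g, X, train_mode = TRUE)
  expect_false(identical(t1, t2))
})

test_that("model checkpoints round-trip bit-exactly", {
  g <- make_mesh(1, radial_noise_sd = 0.02, seed = 10)
  set.seed(71)
  X <- matrix(rnorm(g$n_vertices * 3), g$n_vertices)
  spec <- model_spec("jkgat", num_classes = 3, depth = 3, hidden_channels = 4,
                     attention_heads = 2, dropout = 0.1, lstm_hidden = 3)
  model <- init_model(spec, 3, seed = 11)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  loaded <- load_model(path)
  expect_identical(forward(model, g, X), forward(loaded, g, X))
  unlink(path)
})

test_that("feature width mismatches are reported with both sizes", {
  g <- path_graph(4)
  model <- init_model(model_spec("gcn", num_classes = 2, depth = 1), 5, seed = 1)
  expect_error(forward(model, g, matrix(0, 4, 3)), "F = 5.*got 3")
})

test_that("analytic gradients match finite differences for all architectures", {
  set.seed(42)
  g <- make_mesh(0)
  n <- g$n_vertices
  X <- matrix(rnorm(n * 4), n)
  lab <- rand_label_map(n, 3, seed = 1)
  for (case in list(list("baseline", "lstm"), list("gcn", "lstm"),
                    list("gat", "lstm"), list("jkgat", "lstm"),
                    list("jkgat", "concat"), list("jkgat", "maxpool"))) {
    spec <- model_spec(case[[1]], num_classes = 3, depth = 3, hidden_channels = 3,
                       attention_heads = 2, dropout = 0, aggregation = case[[2]],
                       lstm_hidden = 3)
    model <- init_model(spec, 4, seed = 7)
    gctx <- surfgnn:::graph_context(g, case[[1]])
    theta <- surfgnn:::flatten_params(model$params)
    lossfun <- function(th) {
      m <- model
      m$params <- surfgnn:::unflatten_like(model$params, th)
      fw <- surfgnn:::forward_full(m, gctx, X, training = FALSE)
      surfgnn:::ce_loss_grad(fw$logits, lab)$loss
    }
    fw <- surfgnn:::forward_full(model, gctx, X, training = FALSE)
    lg <- surfgnn:::ce_loss_grad(fw$logits, lab)
    gr <- surfgnn:::flatten_params(surfgnn:::backward_full(model, fw$cache, lg$dlogits))
    expect_length(gr, length(theta))
    idx <- sort(sample(length(theta), min(25, length(theta))))
    eps <- 1e-6
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + eps
      tm <- theta; tm[i] <- tm[i] - eps
      (lossfun(tp) - lossfun(tm)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - gr[idx]) / pmax(1e-6, abs(num) + abs(gr[idx]))), 1e-3)
  }
})
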