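#' Training configuration
#'
#' Optimization protocol: vertex-wise cross-entropy minimized with Adam,
#' gradients accumulated over mini-batches of whole graphs, validation-loss
#' early stopping with checkpoint retention of the best weights.
#'
#' @param max_epochs epoch budget (default 1000).
#' @param patience epochs without strict validation-loss improvement before
#'   stopping (default 150).
#' @param batch_graphs graphs per mini-batch (default 10); gradients are
#'   accumulated across the batch before each update.
#' @param learning_rate Adam step size (default 0.01).
#' @param weight_decay decay rate passed to the optimizer (default 0.0005).
#' @param l2_penalty explicit L2 regularization coefficient added to the
#'   loss over all weights (default 0.005).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a `training_config`.
#' @export
training_config <- function(max_epochs = 1000L, patience = 150L,
                            batch_graphs = 10L, learning_rate = 0.01,
                            weight_decay = 0.0005, l2_penalty = 0.005,
                            seed = 1L) {
  stopifnot(patience <= max_epochs, batch_graphs >= 1L, learning_rate > 0)
  structure(
    list(max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         batch_graphs = as.integer(batch_graphs), learning_rate = learning_rate,
         weight_decay = weight_decay, l2_penalty = l2_penalty,
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Assemble a dataset of (graph, features, labels) samples
#'
#' @param samples list of samples; each a list with elements `graph`
#'   (`surface_graph`), `features` (N x F matrix) and `labels`
#'   (`label_map`).
#' @param split character vector, one of `"train"`, `"validation"`,
#'   `"test"` per sample.
#' @return a `surf_dataset`.
#' @export
surf_dataset <- function(samples, split) {
  stopifnot(length(samples) == length(split),
            all(split %in% c("train", "validation", "test")))
  fs <- vapply(samples, function(s) ncol(s$features), 1L)
  if (length(unique(fs)) != 1L) stop("feature width differs across samples")
  for (s in samples) {
    if (nrow(s$features) != s$graph$n_vertices ||
        length(s$labels$labels) != s$graph$n_vertices) {
      stop("sample arrays disagree with the graph's vertex count")
    }
  }
  structure(list(samples = samples, split = split), class = "surf_dataset")
}

split_idx <- function(data, which) which(data$split == which)

#' Vertex-wise cross-entropy loss
#'
#' Mean negative log softmax probability of the true class over labeled
#' vertices; unlabeled vertices are excluded and contribute no gradient.
#'
#' @param logits numeric N x C matrix.
#' @param labels a `label_map` (codes 1..C; unlabeled code excluded).
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(logits, labels) {
  ce_loss_grad(logits, labels)$loss
}

ce_loss_grad <- function(logits, labels) {
  lab <- labels$labels
  keep <- lab != labels$unlabeled_code
  if (!any(keep)) stop("no labeled vertices: cross-entropy is undefined")
  lg <- logits[keep, , drop = FALSE]
  mx <- apply(lg, 1L, max)
  ex <- exp(lg - mx)
  p <- ex / rowSums(ex)
  idx <- cbind(seq_len(nrow(p)), lab[keep])
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dkeep <- p
  dkeep[idx] <- dkeep[idx] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[keep, ] <- dkeep / nrow(p)
  list(loss = loss, dlogits = dlogits)
}

#' Train a model on a dataset
#'
#' Minimizes vertex-wise cross-entropy (plus an explicit L2 weight penalty)
#' with Adam. Gradients are accumulated across all graphs of a mini-batch
#' before each update; the training order is reshuffled every epoch. After
#' every epoch the validation loss is evaluated in deterministic evaluation
#' mode; weights are checkpointed on strict improvement and training stops
#' when the validation loss has not improved for `patience` epochs. The run
#' is fully reproducible from `cfg$seed`.
#'
#' @param spec a `model_spec`.
#' @param data a `surf_dataset` with non-empty train and validation splits.
#' @param cfg a `training_config`.
#' @param verbose print a progress line every 10 epochs.
#' @return a `trained_model` with the best-validation weights and a
#'   `training_log` data frame (epoch, train_loss, val_loss).
#' @export
train <- function(spec, data, cfg = training_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "surf_dataset"),
            inherits(cfg, "training_config"))
  tr <- split_idx(data, "train")
  va <- split_idx(data, "validation")
  if (!length(tr) || !length(va)) stop("train and validation splits must be non-empty")

  set.seed(cfg$seed)
  F_in <- ncol(data$samples[[1]]$features)
  model <- init_model(spec, F_in)
  gctx <- lapply(data$samples, function(s) graph_context(s$graph, spec$architecture))

  theta <- flatten_params(model$params)
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  best_val <- Inf
  best_theta <- theta
  wait <- 0L
  log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)

  for (epoch in seq_len(cfg$max_epochs)) {
    order_ <- sample(tr)
    batches <- split(order_, ceiling(seq_along(order_) / cfg$batch_graphs))
    epoch_losses <- numeric(0)
    for (batch in batches) {
      gsum <- numeric(length(theta))
      lsum <- 0
      for (i in batch) {
        s <- data$samples[[i]]
        fw <- forward_full(model, gctx[[i]], s$features, training = TRUE)
        lg <- ce_loss_grad(fw$logits, s$labels)
        if (!is.finite(lg$loss)) {
          stop(sprintf("non-finite training loss at epoch %d (sample %d); try a smaller learning rate",
                       epoch, i))
        }
        gr <- backward_full(model, fw$cache, lg$dlogits)
        gsum <- gsum + flatten_params(gr)
        lsum <- lsum + lg$loss
      }
      grad <- gsum / length(batch) + 2 * cfg$l2_penalty * theta
      epoch_losses <- c(epoch_losses, lsum / length(batch) + cfg$l2_penalty * sum(theta^2))
      grad <- grad + cfg$weight_decay * theta
      step <- step + 1L
      m <- b1 * m + (1 - b1) * grad
      v <- b2 * v + (1 - b2) * grad^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      model$params <- unflatten_like(model$params, theta)
    }
    val_loss <- mean(vapply(va, function(i) {
      s <- data$samples[[i]]
      fw <- forward_full(model, gctx[[i]], s$features, training = FALSE)
      ce_loss_grad(fw$logits, s$labels)$loss
    }, numeric(1)))
    if (!is.finite(val_loss)) stop(sprintf("non-finite validation loss at epoch %d", epoch))

    log_epoch <- c(log_epoch, epoch)
    log_train <- c(log_train, mean(epoch_losses))
    log_val <- c(log_val, val_loss)
    if (verbose && epoch %% 10L == 0L) {
      message(sprintf("epoch %4d  train %.4f  val %.4f", epoch,
                      mean(epoch_losses), val_loss))
    }
    if (val_loss < best_val) {
      best_val <- val_loss
      best_theta <- theta
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  model$params <- unflatten_like(model$params, best_theta)
  model$training_log <- data.frame(epoch = log_epoch, train_loss = log_train,
                                   val_loss = log_val)
  model
}

#' Predict a parcellation for one sample
#'
#' Runs the model in evaluation mode and returns the argmax label map,
#' optionally masking logits with a spatial prior first.
#'
#' @param object a `trained_model`.
#' @param graph the `surface_graph`.
#' @param features N x F feature matrix.
#' @param prior optional `prior_mask` applied to the logits at test time.
#' @param ... unused.
#' @return list with `labels` (a `label_map`), `probabilities` (N x C,
#'   rows sum to 1) and `logits`.
#' @export
predict.trained_model <- function(object, graph, features, prior = NULL, ...) {
  logits <- forward(object, graph, features, train_mode = FALSE)
  if (!is.null(prior)) logits <- apply_prior(logits, prior)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  prob <- ex / rowSums(ex)
  labels <- label_map(max.col(logits, ties.method = "first"),
                      num_classes = object$spec$num_classes)
  list(labels = labels, probabilities = prob, logits = logits)
}
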