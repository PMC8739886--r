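#' Build the vertex-wise spatial label prior
#'
#' Because training and test surfaces are in vertex-wise correspondence, a
#' test vertex only needs to consider labels that were observed at that
#' vertex somewhere in the training maps. The prior is the per-vertex union
#' of labels across the training parcellations; a vertex never labeled in
#' any training map falls back to all-true (uninformative) support with a
#' warning.
#'
#' @param train_labels non-empty list of `label_map`s sharing N and C.
#' @return a `prior_mask`: list with `support` (N x C logical, each row has
#'   at least one TRUE) and `source_count`.
#' @export
build_prior <- function(train_labels) {
  stopifnot(length(train_labels) >= 1L)
  n <- length(train_labels[[1]]$labels)
  C <- max(vapply(train_labels, function(l) l$num_classes, 1L))
  support <- matrix(FALSE, n, C)
  for (lm in train_labels) {
    if (length(lm$labels) != n) stop("training label maps disagree on N")
    keep <- is_labeled(lm)
    support[cbind(which(keep), lm$labels[keep])] <- TRUE
  }
  empty <- rowSums(support) == 0L
  if (any(empty)) {
    warning(sprintf("%d vertex(es) unlabeled in every training map; their support is uninformative (all labels allowed)",
                    sum(empty)))
    support[empty, ] <- TRUE
  }
  structure(list(support = support, source_count = length(train_labels)),
            class = "prior_mask")
}

#' Apply the spatial prior to test-time logits
#'
#' Unsupported (vertex, label) entries are pushed to -Inf so their softmax
#' probability is exactly 0 and the argmax always lands on a supported
#' label; supported logits are unchanged. The prior is strictly a test-time
#' operator.
#'
#' @param logits numeric N x C matrix.
#' @param mask a `prior_mask` with matching dimensions.
#' @return the masked logit matrix.
#' @export
apply_prior <- function(logits, mask) {
  stopifnot(inherits(mask, "prior_mask"))
  if (!all(dim(logits) == dim(mask$support))) {
    stop(sprintf("logits are %dx%d but the prior is %dx%d",
                 nrow(logits), ncol(logits), nrow(mask$support), ncol(mask$support)))
  }
  logits[!mask$support] <- -Inf
  logits
}

#' Write / read a spatial prior as a sparse text file
#'
#' Plain-text format: a header line `N C source_count` followed by one
#' `vertex label` pair per line (1-based) for every supported entry.
#'
#' @param mask a `prior_mask`.
#' @param path file path.
#' @return `write_prior` returns `path` invisibly; `read_prior` the
#'   `prior_mask`.
#' @export
write_prior <- function(mask, path) {
  stopifnot(inherits(mask, "prior_mask"))
  idx <- which(mask$support, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d", nrow(mask$support), ncol(mask$support),
                     mask$source_count), con)
  writeLines(sprintf("%d %d", idx[, 1], idx[, 2]), con)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  support <- matrix(FALSE, hdr[1], hdr[2])
  if (length(lines) > 1L) {
    pairs <- do.call(rbind, strsplit(lines[-1], " "))
    support[cbind(as.integer(pairs[, 1]), as.integer(pairs[, 2]))] <- TRUE
  }
  structure(list(support = support, source_count = hdr[3]), class = "prior_mask")
}
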