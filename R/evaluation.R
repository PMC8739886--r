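#' Classification accuracy of a predicted parcellation
#'
#' Percentage of correctly predicted vertex labels relative to ground truth,
#' computed over vertices labeled in the truth map (the medial wall and any
#' other unlabeled vertices are excluded).
#'
#' @param pred,truth `label_map`s of equal length.
#' @return list with `accuracy` (percentage) and `correct` (logical
#'   N-vector; NA where truth is unlabeled).
#' @export
accuracy <- function(pred, truth) {
  if (length(pred$labels) != length(truth$labels)) stop("label maps disagree on N")
  keep <- is_labeled(truth)
  if (!any(keep)) stop("truth map has no labeled vertices")
  correct <- rep(NA, length(keep))
  correct[keep] <- pred$labels[keep] == truth$labels[keep]
  list(accuracy = 100 * mean(correct[keep]), correct = correct)
}

#' Dice overlap of one area between two parcellations
#'
#' Dice(J, K) = 2 |J intersect K| / (|J| + |K|) where J and K are the vertex
#' sets assigned to `area` in each map. When the area is absent from both
#' maps the coefficient is undefined and NA is returned.
#'
#' @param pred_a,pred_b `label_map`s of equal length.
#' @param area label id to compare.
#' @return Dice coefficient in [0, 1], or NA.
#' @export
dice <- function(pred_a, pred_b, area) {
  if (length(pred_a$labels) != length(pred_b$labels)) stop("label maps disagree on N")
  ja <- pred_a$labels == area
  jb <- pred_b$labels == area
  denom <- sum(ja) + sum(jb)
  if (denom == 0L) return(NA_real_)
  2 * sum(ja & jb) / denom
}

#' Mean Dice over all areas of two parcellations
#'
#' @param pred_a,pred_b `label_map`s.
#' @param areas label ids to average over (default: all classes of
#'   `pred_a`); areas absent from both maps are skipped.
#' @return list with `per_area` (named vector) and `mean`.
#' @export
dice_all <- function(pred_a, pred_b, areas = seq_len(pred_a$num_classes)) {
  per <- vapply(areas, function(a) dice(pred_a, pred_b, a), numeric(1))
  names(per) <- areas
  list(per_area = per, mean = mean(per, na.rm = TRUE))
}

#' Boundary-distance profile of misclassified vertices
#'
#' Boundary vertices are the truth-labeled vertices adjacent to a vertex
#' carrying a different truth label. Every misclassified vertex is binned by
#' its geodesic hop distance to the nearest boundary vertex; the profile is
#' the fraction of all misclassifications at each distance.
#'
#' @param pred,truth `label_map`s over the graph's vertices.
#' @param g the `surface_graph`.
#' @return list with `fractions` (named numeric vector over hop distance,
#'   summing to 1), `counts`, and `n_errors`. With zero misclassifications
#'   the profile is empty (`n_errors = 0`), not an error.
#' @export
boundary_error_profile <- function(pred, truth, g) {
  keep <- is_labeled(truth)
  lab <- truth$labels
  trip <- methods::as(methods::as(g$adjacency, "dMatrix"), "TsparseMatrix")
  i <- trip@i + 1L
  j <- trip@j + 1L
  across <- keep[i] & keep[j] & lab[i] != lab[j]
  boundary <- unique(i[across])
  if (!length(boundary)) stop("truth map has a single label: no areal boundary exists")
  wrong <- which(keep & pred$labels != lab)
  if (!length(wrong)) {
    return(list(fractions = numeric(0), counts = integer(0), n_errors = 0L))
  }
  hops <- geodesic_hops(g, boundary)
  tab <- table(hops[wrong])
  list(fractions = stats::setNames(as.numeric(tab) / length(wrong), names(tab)),
       counts = stats::setNames(as.integer(tab), names(tab)),
       n_errors = length(wrong))
}

#' Functional homogeneity of a parcellation
#'
#' For each parcel, the vertex-to-cortex Pearson correlation matrix is
#' decomposed by SVD and homogeneity is the percentage of its variance
#' explained by the first singular component,
#' `rho = 100 * sigma_1^2 / sum(sigma_i^2)`. A single-vertex parcel is 100 by
#' convention (flagged with a warning); the mean over parcels is reported.
#'
#' @param ts numeric N x t matrix of vertex time series.
#' @param parcels a `label_map`.
#' @return list with `per_parcel` (named percentages) and `mean`.
#' @export
functional_homogeneity <- function(ts, parcels) {
  ts <- as.matrix(ts)
  if (nrow(ts) != length(parcels$labels)) stop("time series and parcels disagree on N")
  keep <- is_labeled(parcels)
  # correlation of every vertex with every cortical vertex, computed once
  tc <- ts - rowMeans(ts)
  sds <- sqrt(rowSums(tc^2))
  sds[sds < 1e-12] <- 1e-12
  tc <- tc / sds
  ids <- sort(unique(parcels$labels[keep]))
  per <- vapply(ids, function(l) {
    vs <- which(parcels$labels == l)
    if (length(vs) == 1L) {
      warning(sprintf("parcel %d has a single vertex; homogeneity set to 100", l))
      return(100)
    }
    R <- tc[vs, , drop = FALSE] %*% t(tc[, , drop = FALSE])
    sv <- svd(R, nu = 0, nv = 0)$d
    100 * sv[1]^2 / sum(sv^2)
  }, numeric(1))
  names(per) <- ids
  list(per_parcel = per, mean = mean(per))
}

#' Scalar-map homogeneity of a parcellation
#'
#' Ratio of within-parcel variance to between-parcel variance for one scalar
#' feature: the mean over parcels of the within-parcel variance, divided by
#' the variance of the parcel means. Smaller is more homogeneous; the ratio
#' is dimensionless and invariant to shifting or rescaling the feature.
#'
#' @param feature numeric N-vector (e.g., a myelin or thickness map).
#' @param parcels a `label_map` with >= 2 parcels of >= 2 vertices each.
#' @return the variance ratio, or NA when the between-parcel variance is 0.
#' @export
scalar_homogeneity <- function(feature, parcels) {
  if (length(feature) != length(parcels$labels)) stop("feature and parcels disagree on N")
  keep <- is_labeled(parcels)
  lab <- parcels$labels[keep]
  x <- feature[keep]
  ids <- sort(unique(lab))
  if (length(ids) < 2L) stop("need at least 2 parcels")
  sizes <- table(lab)
  if (any(sizes < 2L)) stop("every parcel needs at least 2 vertices")
  mu <- tapply(x, lab, mean)
  s2 <- tapply(x, lab, stats::var)
  between <- stats::var(as.numeric(mu))
  if (between < 1e-300) return(NA_real_)
  mean(s2) / between
}

#' Consensus parcellation across predictions
#'
#' Per-vertex modal label over a set of predicted maps; ties are broken by
#' the smallest label id. Unlabeled codes participate like any other code.
#'
#' @param preds non-empty list of `label_map`s sharing N.
#' @return a `label_map`.
#' @export
consensus <- function(preds) {
  stopifnot(length(preds) >= 1L)
  mat <- vapply(preds, function(p) p$labels, integer(length(preds[[1]]$labels)))
  mat <- matrix(mat, ncol = length(preds))
  modal <- apply(mat, 1L, function(v) {
    tab <- table(v)
    as.integer(names(tab)[which.max(tab)])   # which.max takes the first = smallest id
  })
  label_map(modal, num_classes = max(vapply(preds, function(p) p$num_classes, 1L)),
            unlabeled_code = preds[[1]]$unlabeled_code)
}

#' Mean class-probability maps across subjects
#'
#' Element-wise mean of per-subject N x C probability matrices. For display,
#' values below `threshold` (default 1/C, the probability of assigning a
#' vertex at random) are zeroed; the unthresholded mean is returned
#' alongside.
#'
#' @param prob_stacks list of N x C matrices with rows summing to 1.
#' @param threshold display threshold (default `1/C`; 0 disables zeroing).
#' @return list with `mean` (N x C) and `thresholded`.
#' @export
mean_probability_maps <- function(prob_stacks, threshold = NULL) {
  stopifnot(length(prob_stacks) >= 1L)
  dims <- vapply(prob_stacks, dim, integer(2))
  if (length(unique(dims[2, ])) != 1L) stop("probability matrices disagree on C")
  if (length(unique(dims[1, ])) != 1L) stop("probability matrices disagree on N")
  avg <- Reduce(`+`, prob_stacks) / length(prob_stacks)
  if (is.null(threshold)) threshold <- 1 / ncol(avg)
  thr <- avg
  thr[thr < threshold] <- 0
  list(mean = avg, thresholded = thr)
}

#' Bootstrap standard error of mean test accuracy
#'
#' Resamples `sample_size` subjects with replacement from the per-subject
#' accuracies, computes the mean of each resample, and reports the standard
#' deviation of the `reps` bootstrap means.
#'
#' @param per_subject_accuracies numeric vector of per-subject accuracies
#'   (percentages).
#' @param sample_size subjects drawn per replicate (default: all).
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return the bootstrap standard error (same units as the input).
#' @export
bootstrap_se <- function(per_subject_accuracies,
                         sample_size = length(per_subject_accuracies),
                         reps = 1000L, seed = 1L) {
  stopifnot(length(per_subject_accuracies) >= 1L, reps >= 2L)
  set.seed(seed)
  means <- vapply(seq_len(reps), function(r) {
    mean(sample(per_subject_accuracies, sample_size, replace = TRUE))
  }, numeric(1))
  stats::sd(means)
}
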