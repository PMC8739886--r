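#' Mean time series per atlas region
#'
#' Aggregates a dense vertex-by-time BOLD matrix over a coarse anatomical
#' atlas: row k of the result is the mean series of all vertices assigned to
#' region k. The unlabeled code is skipped; regions present in the codebook
#' but with no vertices are dropped with a warning.
#'
#' @param ts numeric N x t matrix of vertex time series.
#' @param atlas a `label_map` of length N.
#' @return list with `values` (K x t matrix) and `region_ids` (sorted region
#'   codes corresponding to the rows).
#' @export
regional_mean_series <- function(ts, atlas) {
  ts <- as.matrix(ts)
  if (nrow(ts) != length(atlas$labels)) {
    stop(sprintf("time series has %d rows but atlas has %d vertices",
                 nrow(ts), length(atlas$labels)))
  }
  if (ncol(ts) < 2L) stop("need at least 2 time points")
  lab <- atlas$labels
  keep <- lab != atlas$unlabeled_code
  if (!any(keep)) stop("atlas labels every vertex as unlabeled")
  present <- sort(unique(lab[keep]))
  expected <- seq_len(atlas$num_classes)
  missing_regions <- setdiff(expected, present)
  if (length(missing_regions)) {
    warning(sprintf("atlas region(s) with zero vertices excluded: %s",
                    paste(missing_regions, collapse = ", ")))
  }
  counts <- as.numeric(table(factor(lab[keep], levels = present)))
  sums <- rowsum(ts[keep, , drop = FALSE], group = lab[keep])
  list(values = sums / counts, region_ids = present)
}

#' Regionalized functional connectivity features
#'
#' Pearson correlation of every vertex's time series with the mean series of
#' every atlas region, yielding an N x K feature matrix whose columns are
#' anatomically comparable across subjects regardless of mesh correspondence.
#' Series are demeaned per row before correlating; rows or regions with
#' (numerically) zero temporal variance produce 0 entries with a warning
#' rather than NaN.
#'
#' @param ts numeric N x t matrix of vertex time series.
#' @param regional result of [regional_mean_series()] with the same t.
#' @return list with `values` (N x K correlations in [-1, 1], columns named
#'   `conn_<region>`) and `region_ids`.
#' @export
connectivity_features <- function(ts, regional) {
  ts <- as.matrix(ts)
  reg <- as.matrix(regional$values)
  if (ncol(ts) != ncol(reg)) {
    stop(sprintf("time dimension mismatch: vertices have t = %d, regions t = %d",
                 ncol(ts), ncol(reg)))
  }
  t_n <- ncol(ts)
  vc <- ts - rowMeans(ts)
  rc <- reg - rowMeans(reg)
  vsd <- sqrt(rowSums(vc^2) / (t_n - 1))
  rsd <- sqrt(rowSums(rc^2) / (t_n - 1))
  floor_ <- 1e-12
  bad_v <- vsd < floor_
  bad_r <- rsd < floor_
  if (any(bad_v) || any(bad_r)) {
    warning(sprintf("%d vertex and %d region series have ~zero variance; their correlations are set to 0",
                    sum(bad_v), sum(bad_r)))
  }
  R <- (vc %*% t(rc)) / (t_n - 1) / outer(pmax(vsd, floor_), pmax(rsd, floor_))
  R[bad_v, ] <- 0
  R[, bad_r] <- 0
  R <- pmin(pmax(R, -1), 1)
  colnames(R) <- paste0("conn_", regional$region_ids)
  list(values = R, region_ids = regional$region_ids)
}

#' Dual regression of group spatial components
#'
#' Projects group-level spatial component maps onto a subject's time series
#' in two least-squares stages: (1) each time point's spatial pattern is
#' regressed on the group maps, giving C subject-specific time courses;
#' (2) each vertex's series is regressed on those time courses, giving the
#' subject-level N x C spatial coefficient maps.
#'
#' @param group_maps numeric N x C matrix of group component maps, full
#'   column rank.
#' @param ts numeric N x t matrix of the subject's time series.
#' @return list with `subject_maps` (N x C), `time_courses` (C x t).
#' @export
dual_regression <- function(group_maps, ts) {
  G <- as.matrix(group_maps)
  ts <- as.matrix(ts)
  if (nrow(G) != nrow(ts)) stop("group maps and time series disagree on N")
  C <- ncol(G)
  if (C >= min(nrow(ts), ncol(ts))) stop("need C < min(N, t)")
  qrG <- qr(G)
  if (qrG$rank < C) {
    dep <- setdiff(seq_len(C), qrG$pivot[seq_len(qrG$rank)])
    stop(sprintf("group maps are rank deficient; collinear column(s): %s",
                 paste(dep, collapse = ", ")))
  }
  S <- qr.coef(qrG, ts)                          # C x t time courses
  qrS <- qr(t(S))
  maps <- t(qr.coef(qrS, t(ts)))                 # N x C subject maps
  colnames(maps) <- colnames(G)
  list(subject_maps = maps, time_courses = S)
}

#' Assemble per-vertex training features column-wise
#'
#' Concatenates the configured feature blocks in fixed order —
#' connectivity (or dual-regression component loadings) | spectral | scalars —
#' into the N x F model input matrix with unique column names.
#'
#' @param connectivity optional N x K matrix (output `values` of
#'   [connectivity_features()] or `subject_maps` of [dual_regression()]).
#' @param spectral optional `spectral_coords` (or plain N x d matrix).
#' @param scalars optional named N x p matrix or named list of N-vectors.
#' @return numeric N x F matrix with unique column names.
#' @export
assemble_features <- function(connectivity = NULL, spectral = NULL, scalars = NULL) {
  blocks <- list()
  if (!is.null(connectivity)) {
    cn <- as.matrix(connectivity)
    if (is.null(colnames(cn))) colnames(cn) <- paste0("conn_", seq_len(ncol(cn)))
    blocks$connectivity <- cn
  }
  if (!is.null(spectral)) {
    sp <- if (inherits(spectral, "spectral_coords")) spectral$eigenvectors else as.matrix(spectral)
    colnames(sp) <- paste0("spectral_", seq_len(ncol(sp)))
    blocks$spectral <- sp
  }
  if (!is.null(scalars)) {
    if (is.list(scalars) && !is.matrix(scalars)) scalars <- do.call(cbind, scalars)
    sc <- as.matrix(scalars)
    if (is.null(colnames(sc))) stop("scalar maps must be named")
    blocks$scalars <- sc
  }
  if (!length(blocks)) stop("no feature blocks supplied")
  ns <- vapply(blocks, nrow, 1L)
  if (length(unique(ns)) != 1L) {
    stop(sprintf("feature blocks disagree on N: %s",
                 paste(sprintf("%s=%d", names(ns), ns), collapse = ", ")))
  }
  X <- do.call(cbind, unname(blocks))
  if (anyDuplicated(colnames(X))) {
    stop(sprintf("duplicate feature column name(s): %s",
                 paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", ")))
  }
  X
}

#' Fit a per-column z-scoring transform on training features
#'
#' Computes column means and SDs on training data so that the identical
#' transform can be applied at test time. By default only spectral and
#' scalar columns are standardized; correlation columns are already bounded
#' in [-1, 1] and are left alone.
#'
#' @param X training feature matrix from [assemble_features()].
#' @param columns character vector of columns to standardize, or `"auto"`
#'   (all columns not named `conn_*`), or `"all"`.
#' @return a `feature_scaling` object.
#' @export
fit_feature_scaling <- function(X, columns = "auto") {
  cols <- colnames(X)
  target <- if (identical(columns, "auto")) {
    cols[!startsWith(cols, "conn_")]
  } else if (identical(columns, "all")) cols else intersect(columns, cols)
  center <- colMeans(X[, target, drop = FALSE])
  scale_ <- apply(X[, target, drop = FALSE], 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  structure(list(columns = target, center = center, scale = scale_),
            class = "feature_scaling")
}

#' Apply a fitted feature scaling
#'
#' @param X feature matrix whose columns include the fitted ones.
#' @param scaling a `feature_scaling` from [fit_feature_scaling()].
#' @return X with the fitted columns z-scored using the training statistics.
#' @export
apply_feature_scaling <- function(X, scaling) {
  stopifnot(inherits(scaling, "feature_scaling"))
  for (cn in scaling$columns) {
    X[, cn] <- (X[, cn] - scaling$center[[cn]]) / scaling$scale[[cn]]
  }
  X
}
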