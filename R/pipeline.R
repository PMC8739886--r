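#' Build a model-ready dataset from a synthetic cohort
#'
#' Computes per-sample feature matrices (regionalized connectivity over the
#' cohort atlas, spectral position coordinates, scalar maps), splits
#' subjects into train/validation/test, and z-scores the spectral and
#' scalar feature blocks using training-set statistics only.
#'
#' @param cohort a `synthetic_cohort` from [make_cohort()].
#' @param n_train,n_val,n_test subject counts per split (in cohort order;
#'   must sum to at most the cohort size).
#' @param sessions `"concat"` (sessions concatenated in time, one sample per
#'   subject) or `"independent"` (one sample per session).
#' @param spectral_dim spectral coordinates to include (0 disables).
#' @param use_scalars include the four scalar maps.
#' @param standardize z-score spectral/scalar blocks with train statistics.
#' @return list with `dataset` (a `surf_dataset`), `scaling`, `spectral`,
#'   and `subject_of` (subject index per sample).
#' @export
cohort_dataset <- function(cohort, n_train, n_val, n_test,
                           sessions = c("concat", "independent"),
                           spectral_dim = 3L, use_scalars = TRUE,
                           standardize = TRUE) {
  sessions <- match.arg(sessions)
  S <- cohort$config$num_subjects
  if (n_train + n_val + n_test > S) stop("splits exceed the cohort size")
  split_of_subject <- rep(NA_character_, S)
  split_of_subject[seq_len(n_train)] <- "train"
  split_of_subject[n_train + seq_len(n_val)] <- "validation"
  split_of_subject[n_train + n_val + seq_len(n_test)] <- "test"

  spectral <- if (spectral_dim > 0L) {
    spectral_coordinates(cohort$mesh, spectral_dim)
  } else NULL

  samples <- list()
  subject_of <- integer(0)
  split <- character(0)
  for (s in seq_len(S)) {
    if (is.na(split_of_subject[s])) next
    ts_sets <- if (sessions == "concat") {
      list(do.call(cbind, cohort$time_series[[s]]))
    } else {
      cohort$time_series[[s]]
    }
    for (ts in ts_sets) {
      regional <- regional_mean_series(ts, cohort$atlas)
      conn <- connectivity_features(ts, regional)
      X <- assemble_features(
        connectivity = conn$values,
        spectral = spectral,
        scalars = if (use_scalars) cohort$scalars[[s]] else NULL
      )
      samples[[length(samples) + 1L]] <- list(
        graph = cohort$mesh, features = X, labels = cohort$subject_labels[[s]]
      )
      subject_of <- c(subject_of, s)
      split <- c(split, split_of_subject[s])
    }
  }

  scaling <- NULL
  if (standardize) {
    train_X <- do.call(rbind, lapply(samples[split == "train"], `[[`, "features"))
    scaling <- fit_feature_scaling(train_X, "auto")
    for (i in seq_along(samples)) {
      samples[[i]]$features <- apply_feature_scaling(samples[[i]]$features, scaling)
    }
  }

  list(dataset = surf_dataset(samples, split), scaling = scaling,
       spectral = spectral, subject_of = subject_of)
}

#' Build the feature matrix for one cohort subject
#'
#' Regionalized connectivity from the subject's time series (one session or
#' the temporal concatenation of all sessions), plus spectral coordinates
#' and the subject's scalar maps, optionally transformed with a fitted
#' training-set scaling. Used to featurize new sessions (e.g., of different
#' scan durations) for an already-trained model.
#'
#' @param cohort a `synthetic_cohort`.
#' @param subject subject index.
#' @param session session index, or NULL for temporal concatenation of all
#'   sessions.
#' @param spectral a `spectral_coords` for the cohort mesh (computed here
#'   when NULL).
#' @param scaling optional `feature_scaling` fitted on training data.
#' @param ts optional replacement N x t time-series matrix (overrides the
#'   cohort's stored sessions).
#' @param use_scalars include the scalar maps.
#' @return numeric N x F feature matrix.
#' @export
build_features <- function(cohort, subject, session = NULL, spectral = NULL,
                           scaling = NULL, ts = NULL, use_scalars = TRUE) {
  if (is.null(ts)) {
    ts <- if (is.null(session)) {
      do.call(cbind, cohort$time_series[[subject]])
    } else {
      cohort$time_series[[subject]][[session]]
    }
  }
  if (is.null(spectral)) spectral <- spectral_coordinates(cohort$mesh, 3L)
  regional <- regional_mean_series(ts, cohort$atlas)
  conn <- connectivity_features(ts, regional)
  X <- assemble_features(
    connectivity = conn$values, spectral = spectral,
    scalars = if (use_scalars) cohort$scalars[[subject]] else NULL
  )
  if (!is.null(scaling)) X <- apply_feature_scaling(X, scaling)
  X
}

#' Evaluate a trained model on the test split of a cohort dataset
#'
#' Predicts every test sample (optionally under a spatial prior), then
#' computes per-sample accuracy, the consensus parcellation, mean
#' probability maps, a pooled boundary-distance error profile, a bootstrap
#' standard error of the mean accuracy, within-subject Dice reproducibility
#' across repeated sessions, and functional/scalar homogeneity of the
#' predicted maps.
#'
#' @param model a `trained_model`.
#' @param ds result of [cohort_dataset()].
#' @param cohort the `synthetic_cohort` the dataset came from.
#' @param prior optional `prior_mask`.
#' @param bootstrap_reps replicates for the accuracy standard error.
#' @param seed RNG seed for the bootstrap.
#' @return an `evaluation_report` list.
#' @export
evaluate_model <- function(model, ds, cohort, prior = NULL,
                           bootstrap_reps = 1000L, seed = 1L) {
  data <- ds$dataset
  te <- split_idx(data, "test")
  if (!length(te)) stop("dataset has no test samples")
  preds <- vector("list", length(te))
  probs <- vector("list", length(te))
  accs <- numeric(length(te))
  for (k in seq_along(te)) {
    i <- te[k]
    s <- data$samples[[i]]
    pr <- predict.trained_model(model, s$graph, s$features, prior = prior)
    preds[[k]] <- pr$labels
    probs[[k]] <- pr$probabilities
    accs[k] <- accuracy(pr$labels, s$labels)$accuracy
  }
  test_subjects <- ds$subject_of[te]

  # pooled boundary-distance profile over test samples
  counts <- integer(0)
  for (k in seq_along(te)) {
    bp <- boundary_error_profile(preds[[k]], data$samples[[te[k]]]$labels,
                                 cohort$mesh)
    for (nm in names(bp$counts)) {
      counts[nm] <- (if (nm %in% names(counts)) counts[nm] else 0L) + bp$counts[nm]
    }
  }
  boundary_fractions <- if (length(counts)) counts / sum(counts) else numeric(0)

  # within-subject Dice across repeated sessions
  dice_by_subject <- NULL
  for (subj in unique(test_subjects)) {
    ks <- which(test_subjects == subj)
    if (length(ks) < 2L) next
    pairs <- utils::combn(ks, 2L)
    vals <- apply(pairs, 2L, function(p) {
      dice_all(preds[[p[1]]], preds[[p[2]]])$mean
    })
    dice_by_subject <- c(dice_by_subject, stats::setNames(mean(vals), subj))
  }

  # homogeneity of the first prediction per test subject, against that
  # subject's (concatenated) time series
  first_of_subject <- !duplicated(test_subjects)
  fh <- numeric(0)
  sh <- list()
  for (k in which(first_of_subject)) {
    subj <- test_subjects[k]
    ts <- do.call(cbind, cohort$time_series[[subj]])
    fh <- c(fh, suppressWarnings(functional_homogeneity(ts, preds[[k]])$mean))
    sc <- cohort$scalars[[subj]]
    for (nm in colnames(sc)) {
      # degenerate predictions (a singleton or missing parcel) leave the
      # variance ratio undefined for that subject
      val <- tryCatch(scalar_homogeneity(sc[, nm], preds[[k]]),
                      error = function(e) NA_real_)
      sh[[nm]] <- c(sh[[nm]], val)
    }
  }

  structure(list(
    per_sample_accuracy = accs,
    mean_accuracy = mean(accs),
    bootstrap_se = bootstrap_se(accs, reps = bootstrap_reps, seed = seed),
    boundary_error_fractions = boundary_fractions,
    dice_by_subject = dice_by_subject,
    mean_dice = if (is.null(dice_by_subject)) NA_real_ else mean(dice_by_subject),
    functional_homogeneity = mean(fh),
    scalar_homogeneity = vapply(sh, function(v) mean(v, na.rm = TRUE), numeric(1)),
    consensus = consensus(preds),
    mean_probability = mean_probability_maps(probs),
    predictions = preds
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> mean accuracy %.2f%% (SE %.3f) over %d samples\n",
              x$mean_accuracy, x$bootstrap_se, length(x$per_sample_accuracy)))
  if (!is.na(x$mean_dice)) cat(sprintf("  mean within-subject Dice %.3f\n", x$mean_dice))
  cat(sprintf("  functional homogeneity %.2f%%\n", x$functional_homogeneity))
  invisible(x)
}

#' Within-subject reproducibility across repeated sessions
#'
#' For each requested subject, draws `sessions` fresh sessions of each scan
#' duration from that subject's ground-truth parcel structure, predicts a
#' parcellation from every session independently, and measures
#' reproducibility as the mean areal Dice coefficient over all session
#' pairs. Longer sessions give less noisy connectivity estimates and hence
#' more reproducible predictions.
#'
#' @param model a `trained_model`.
#' @param cohort the `synthetic_cohort` (provides mesh, atlas, labels,
#'   scalars and the noise level).
#' @param subjects subject indices to evaluate.
#' @param durations vector of session lengths (time points).
#' @param sessions sessions drawn per subject and duration.
#' @param spectral,scaling as fitted on the training data (see
#'   [cohort_dataset()]).
#' @param prior optional `prior_mask` applied at prediction.
#' @param seed base RNG seed for the fresh sessions.
#' @return data frame with columns `duration`, `subject`, `mean_dice`.
#' @export
session_reproducibility <- function(model, cohort, subjects, durations,
                                    sessions = 4L, spectral = NULL,
                                    scaling = NULL, prior = NULL, seed = 1L) {
  if (is.null(spectral)) spectral <- spectral_coordinates(cohort$mesh, 3L)
  out <- NULL
  for (t_len in durations) {
    for (subj in subjects) {
      preds <- vector("list", sessions)
      for (k in seq_len(sessions)) {
        ts <- make_time_series(cohort$subject_labels[[subj]], t_len,
                               cohort$config$snr,
                               seed = seed + 1000L * t_len + 10L * subj + k)
        X <- build_features(cohort, subj, spectral = spectral,
                            scaling = scaling, ts = ts)
        preds[[k]] <- predict.trained_model(model, cohort$mesh, X, prior = prior)$labels
      }
      pairs <- utils::combn(sessions, 2L)
      vals <- apply(pairs, 2L, function(p) dice_all(preds[[p[1]]], preds[[p[2]]])$mean)
      out <- rbind(out, data.frame(duration = t_len, subject = subj,
                                   mean_dice = mean(vals)))
    }
  }
  out
}

#' Run the full synthetic pipeline
#'
#' simulate -> features -> train -> predict (with and without the spatial
#' prior) -> evaluate, entirely in memory, with every stage seeded from the
#' single run seed.
#'
#' @param synth a `synthetic_config`.
#' @param spec a `model_spec` (its `num_classes` must equal the cohort's
#'   parcel count).
#' @param train_cfg a `training_config`.
#' @param n_train,n_val,n_test subject split sizes.
#' @param sessions passed to [cohort_dataset()].
#' @param out_dir optional directory; when given, the mesh, template labels,
#'   atlas, prior, model checkpoint and a JSON report are written there.
#' @return list with `model`, `prior`, `report` (with prior),
#'   `report_no_prior`, `dataset` and `cohort`.
#' @export
run_pipeline <- function(synth, spec, train_cfg = training_config(),
                         n_train = 12L, n_val = 3L, n_test = 5L,
                         sessions = "concat", out_dir = NULL) {
  cohort <- make_cohort(synth)
  ds <- cohort_dataset(cohort, n_train, n_val, n_test, sessions = sessions)
  model <- train(spec, ds$dataset, train_cfg)
  tr <- split_idx(ds$dataset, "train")
  prior <- build_prior(lapply(ds$dataset$samples[tr], `[[`, "labels"))
  report <- evaluate_model(model, ds, cohort, prior = prior,
                           seed = train_cfg$seed)
  report_no_prior <- evaluate_model(model, ds, cohort, prior = NULL,
                                    seed = train_cfg$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_surface(cohort$mesh, file.path(out_dir, "mesh.surf.txt"))
    write_labels(cohort$template_labels, file.path(out_dir, "template_labels.txt"))
    write_labels(cohort$atlas, file.path(out_dir, "atlas.txt"))
    write_prior(prior, file.path(out_dir, "prior.txt"))
    save_model(model, file.path(out_dir, "model.rds"))
    jsonlite::write_json(list(
      mean_accuracy = report$mean_accuracy,
      mean_accuracy_no_prior = report_no_prior$mean_accuracy,
      bootstrap_se = report$bootstrap_se,
      per_sample_accuracy = report$per_sample_accuracy,
      functional_homogeneity = report$functional_homogeneity,
      scalar_homogeneity = as.list(report$scalar_homogeneity),
      boundary_error_fractions = as.list(report$boundary_error_fractions)
    ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  list(model = model, prior = prior, report = report,
       report_no_prior = report_no_prior, dataset = ds, cohort = cohort)
}
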