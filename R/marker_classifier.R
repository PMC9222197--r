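#' Configuration for marker-based compartment assignment
#'
#' Hyperparameter grids and cross-validation settings for the RBF-SVM
#' classifier.  Defaults follow common practice for organelle maps: a
#' logarithmic grid for the inverse kernel width sigma containing 0.1, a
#' cost grid containing 16, 100 rounds of stratified 5-fold cross-validation
#' scored by macro F1, and a 5% false-discovery-rate score cutoff.
#'
#' @param sigma_grid positive inverse-kernel-width values.
#' @param cost_grid positive constraint-violation costs.
#' @param cv_rounds rounds of repeated cross-validation (default 100; reduce
#'   for quick runs — tuning cost scales linearly in it).
#' @param folds folds per round (default 5); every class needs at least this
#'   many markers.
#' @param fdr per-class false-discovery-rate bound in (0, 1) (default 0.05).
#' @param seed integer seed driving all partition resampling.
#' @return a list of class `SVMConfig`.
#' @export
svm_config <- function(sigma_grid = c(0.01, 0.1, 1),
                       cost_grid = c(1, 16, 64),
                       cv_rounds = 100, folds = 5, fdr = 0.05, seed = 1L) {
  assert_that(all(sigma_grid > 0) && all(cost_grid > 0), "config_error",
              "sigma and cost grids must be positive")
  assert_that(folds >= 2, "config_error", "folds must be >= 2")
  assert_that(fdr > 0 && fdr < 1, "config_error", "fdr must lie in (0, 1)")
  structure(list(sigma_grid = sort(sigma_grid), cost_grid = sort(cost_grid),
                 cv_rounds = as.integer(cv_rounds), folds = as.integer(folds),
                 fdr = fdr, seed = as.integer(seed)),
            class = "SVMConfig")
}

#' Macro F1 score of a confusion table
#'
#' Unweighted mean over classes of the per-class F1 (harmonic mean of
#' precision and recall).  A class with zero precision + recall contributes
#' zero, so absent or never-predicted classes penalize the score.
#'
#' @param confusion square count matrix, rows = true class, columns =
#'   predicted class, identical class order.
#' @return score in `[0, 1]`.
#' @export
macro_f1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  assert_that(length(confusion) > 0 && nrow(confusion) == ncol(confusion),
              "config_error", "confusion table must be square and non-empty")
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  mean(f1)
}

profile_matrix_of <- function(profiles) {
  if (inherits(profiles, "SpatialProfileMatrix")) profiles$matrix
  else as.matrix(profiles)
}

check_marker_classes <- function(labels, folds) {
  counts <- table(labels)
  small <- names(counts)[counts < folds]
  assert_that(length(small) == 0, "config_error",
              "class(es) with fewer markers than folds (%d): %s",
              folds, paste(small, collapse = ", "))
  invisible(counts)
}

#' Tune SVM hyperparameters by repeated stratified cross-validation
#'
#' For every (sigma, cost) grid point, runs `cv_rounds` rounds of stratified
#' `folds`-fold cross-validation on the marker proteins only and records the
#' mean macro F1 over all rounds and folds.  Partitions are resampled each
#' round from a round-indexed seed stream, so the whole search is
#' deterministic under `config$seed`.  Ties on the mean score are broken
#' toward the smallest cost, then the smallest sigma.
#'
#' @param profiles `SpatialProfileMatrix` (or plain matrix with protein ids
#'   as rownames).
#' @param markers a `MarkerMap`; all markers must be rows of `profiles`.
#' @param config an [svm_config()].
#' @return list with `sigma`, `cost`, `cv_f1` (data frame of the full grid
#'   record: sigma, cost, mean_f1, sd_f1).
#' @export
tune_hyperparameters <- function(profiles, markers, config = svm_config()) {
  X <- profile_matrix_of(profiles)
  assert_that(all(names(markers) %in% rownames(X)), "config_error",
              "all markers must be present in the profile matrix")
  Xm <- X[names(markers), , drop = FALSE]
  labels <- as.character(markers)
  check_marker_classes(labels, config$folds)
  grid <- expand.grid(sigma = config$sigma_grid, cost = config$cost_grid)
  scores <- matrix(NA_real_, nrow(grid), config$cv_rounds * config$folds)
  col <- 0
  for (round in seq_len(config$cv_rounds)) {
    fold_id <- stratified_folds(labels, config$folds,
                                child_seed(config$seed, round))
    for (fold in seq_len(config$folds)) {
      col <- col + 1
      train <- fold_id != fold
      for (g in seq_len(nrow(grid))) {
        fit <- svm_fit(Xm[train, , drop = FALSE], labels[train],
                       sigma = grid$sigma[g], cost = grid$cost[g],
                       probability = FALSE)
        pred <- predict(fit, Xm[!train, , drop = FALSE], type = "class")
        cls <- sort(unique(labels))
        conf <- table(factor(labels[!train], levels = cls),
                      factor(pred, levels = cls))
        scores[g, col] <- macro_f1(conf)
      }
    }
  }
  grid$mean_f1 <- rowMeans(scores)
  grid$sd_f1 <- apply(scores, 1, sd)
  ord <- order(-grid$mean_f1, grid$cost, grid$sigma)
  best <- grid[ord[1], ]
  os_log("tuned SVM: sigma=%g cost=%g (CV macro-F1 %.3f)",
         best$sigma, best$cost, best$mean_f1)
  list(sigma = best$sigma, cost = best$cost, cv_f1 = grid)
}

#' Train the final SVM and score every protein
#'
#' Trains the multiclass RBF SVM on all markers at the tuned hyperparameters
#' and scores each protein with its top pairwise-coupled class probability.
#' Markers are scored out-of-fold (each by a model that never saw it, via a
#' stratified cross-validation split) so their scores are honest inputs for
#' threshold derivation; non-markers are scored by the full model.
#'
#' @param profiles `SpatialProfileMatrix` or matrix.
#' @param markers a `MarkerMap`.
#' @param sigma,cost tuned hyperparameters.
#' @param folds folds for out-of-fold marker scoring (default 5).
#' @param seed integer seed for the scoring split.
#' @return list with `scores` (data frame: protein_id, predicted_class,
#'   score, is_marker, true_class) and `model` (the full `rbf_svm` fit).
#' @export
train_and_score <- function(profiles, markers, sigma, cost, folds = 5,
                            seed = 1L) {
  X <- profile_matrix_of(profiles)
  assert_that(all(names(markers) %in% rownames(X)), "config_error",
              "all markers must be present in the profile matrix")
  labels <- as.character(markers)
  check_marker_classes(labels, folds)
  Xm <- X[names(markers), , drop = FALSE]
  model <- svm_fit(Xm, labels, sigma, cost, probability = TRUE)

  # out-of-fold marker probabilities
  fold_id <- stratified_folds(labels, folds, child_seed(seed, 104729L))
  oof <- matrix(NA_real_, nrow(Xm), length(model$classes),
                dimnames = list(rownames(Xm), model$classes))
  for (fold in seq_len(folds)) {
    train <- fold_id != fold
    fit <- svm_fit(Xm[train, , drop = FALSE], labels[train], sigma, cost,
                   probability = TRUE)
    p <- predict(fit, Xm[!train, , drop = FALSE], type = "prob")
    oof[!train, colnames(p)] <- p
  }

  unknown_ids <- setdiff(rownames(X), names(markers))
  prob_all <- matrix(NA_real_, nrow(X), length(model$classes),
                     dimnames = list(rownames(X), model$classes))
  prob_all[rownames(Xm), ] <- oof
  if (length(unknown_ids)) {
    prob_all[unknown_ids, ] <-
      predict(model, X[unknown_ids, , drop = FALSE], type = "prob")
  }
  top <- max.col(prob_all, ties.method = "first")
  scores <- data.frame(
    protein_id = rownames(X),
    predicted_class = model$classes[top],
    score = prob_all[cbind(seq_len(nrow(X)), top)],
    is_marker = rownames(X) %in% names(markers),
    true_class = ifelse(rownames(X) %in% names(markers),
                        unclass(markers)[rownames(X)], NA_character_),
    stringsAsFactors = FALSE, row.names = NULL)
  list(scores = scores, model = model)
}

#' Derive per-class score thresholds controlling the false-discovery rate
#'
#' For each compartment, orders the markers predicted into that compartment
#' by decreasing out-of-fold score and finds the lowest score `s` such that
#' the fraction of wrong-class markers among those scoring at least `s` is
#' at most `fdr`.  If no cutoff attains the bound (or no marker is predicted
#' into the class) the threshold is `+Inf` and the class is never assigned.
#'
#' @param marker_oof data frame with columns `predicted_class`, `score`,
#'   `true_class` (out-of-fold marker predictions; rows with `is_marker`
#'   FALSE are ignored if present).
#' @param fdr false-discovery bound in (0, 1).
#' @param classes optional class set for the threshold table (defaults to
#'   classes seen in the predictions).
#' @return named numeric vector of thresholds, one per class.
#' @export
derive_fdr_thresholds <- function(marker_oof, fdr = 0.05, classes = NULL) {
  df <- as.data.frame(marker_oof)
  if ("is_marker" %in% names(df)) df <- df[df$is_marker, ]
  assert_that(nrow(df) > 0, "config_error",
              "no out-of-fold marker predictions supplied")
  classes <- classes %||% sort(unique(c(df$predicted_class, df$true_class)))
  thresholds <- structure(rep(Inf, length(classes)), names = classes)
  for (cl in classes) {
    sub <- df[df$predicted_class == cl, ]
    if (nrow(sub) == 0) {
      warning(sprintf("no marker predicted into class '%s'; threshold +Inf",
                      cl))
      next
    }
    # candidate cutoffs are the distinct observed scores; the accepted set
    # {score >= s} includes all ties, so FDP is evaluated per distinct score
    cand <- sort(unique(sub$score), decreasing = TRUE)
    wrong_at <- vapply(cand, function(s) {
      sum(sub$true_class[sub$score >= s] != cl)
    }, numeric(1))
    n_at <- vapply(cand, function(s) sum(sub$score >= s), numeric(1))
    ok <- which(wrong_at / n_at <= fdr)
    if (length(ok)) {
      thresholds[cl] <- cand[max(ok)]
    }
  }
  thresholds
}

#' Apply score thresholds to produce final compartment labels
#'
#' A protein keeps its predicted compartment when its score reaches that
#' compartment's threshold, and is otherwise labelled `"unknown"`.
#'
#' @param scores data frame from [train_and_score()] (`$scores`).
#' @param thresholds named threshold vector from [derive_fdr_thresholds()].
#' @return a `ClassificationResult`: the input data frame plus a
#'   `final_label` column, with the thresholds attached as attribute
#'   `"thresholds"`.
#' @export
classify <- function(scores, thresholds) {
  df <- as.data.frame(scores)
  thr <- thresholds[df$predicted_class]
  thr[is.na(thr)] <- Inf
  df$final_label <- ifelse(df$score >= thr, df$predicted_class, "unknown")
  counts <- table(df$final_label)
  os_log("classified: %s",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  attr(df, "thresholds") <- thresholds
  class(df) <- c("ClassificationResult", "data.frame")
  df
}

#' End-to-end compartment assignment for one condition
#'
#' Convenience wrapper: tune (optionally), train with out-of-fold marker
#' scoring, derive per-class FDR thresholds, and classify.
#'
#' @param profiles `SpatialProfileMatrix` or matrix.
#' @param markers a `MarkerMap`.
#' @param config an [svm_config()].
#' @param tune if `FALSE`, skip the grid search and use the first grid value
#'   of each parameter.
#' @return a `ClassificationResult` with attributes `thresholds`, `tuning`
#'   and `model`.
#' @export
classify_profiles <- function(profiles, markers, config = svm_config(),
                              tune = TRUE) {
  if (tune) {
    tuned <- tune_hyperparameters(profiles, markers, config)
  } else {
    tuned <- list(sigma = config$sigma_grid[1], cost = config$cost_grid[1],
                  cv_f1 = NULL)
  }
  ts <- train_and_score(profiles, markers, tuned$sigma, tuned$cost,
                        folds = config$folds, seed = config$seed)
  thr <- derive_fdr_thresholds(ts$scores, fdr = config$fdr,
                               classes = ts$model$classes)
  res <- classify(ts$scores, thr)
  attr(res, "tuning") <- tuned
  attr(res, "model") <- ts$model
  res
}
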