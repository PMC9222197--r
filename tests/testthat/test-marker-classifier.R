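test_that("macro F1 matches hand-computed cases and is order-invariant", {
  expect_equal(macro_f1(diag(c(3, 5, 7))), 1)
  # two balanced classes, everything predicted as class A:
  # F1_A = 2/3, F1_B = 0 -> macro 1/3
  conf <- matrix(c(5, 0, 5, 0), 2, 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(macro_f1(conf), 1 / 3)
  perm <- conf[c(2, 1), c(2, 1)]
  expect_equal(macro_f1(perm), macro_f1(conf))
  expect_error(macro_f1(matrix(numeric(0), 0, 0)), class = "config_error")
  expect_error(macro_f1(matrix(1:6, 2, 3)), class = "config_error")
})

test_that("hyperparameter tuning honours its grid, seed and class-size contract", {
  sim <- small_sim()
  spm <- concatenate_replicates(sim$control)

  one <- svm_config(sigma_grid = 0.1, cost_grid = 16, cv_rounds = 1,
                    folds = 3, seed = 2)
  t1 <- suppressMessages(tune_hyperparameters(spm, sim$markers, one))
  expect_equal(t1$sigma, 0.1)
  expect_equal(t1$cost, 16)
  expect_equal(nrow(t1$cv_f1), 1)
  expect_gte(t1$cv_f1$mean_f1, 0.9)   # well-separated synthetic markers

  grid <- svm_config(sigma_grid = c(0.01, 0.1), cost_grid = c(1, 16),
                     cv_rounds = 2, folds = 3, seed = 2)
  t2 <- suppressMessages(tune_hyperparameters(spm, sim$markers, grid))
  t2b <- suppressMessages(tune_hyperparameters(spm, sim$markers, grid))
  expect_identical(t2[c("sigma", "cost")], t2b[c("sigma", "cost")])
  # returned point attains the grid maximum, ties broken to cheap models
  best <- max(t2$cv_f1$mean_f1)
  chosen <- t2$cv_f1[t2$cv_f1$sigma == t2$sigma & t2$cv_f1$cost == t2$cost, ]
  expect_equal(chosen$mean_f1, best)
  tied <- t2$cv_f1[t2$cv_f1$mean_f1 == best, ]
  expect_equal(t2$cost, min(tied$cost))
  expect_equal(t2$sigma, min(tied$sigma[tied$cost == t2$cost]))

  # a class smaller than the fold count is a config error naming the class
  few <- sim$markers[1:20]
  class(few) <- "MarkerMap"
  expect_error(
    suppressMessages(tune_hyperparameters(spm, few, svm_config(folds = 5))),
    class = "config_error")
})

test_that("train_and_score gives honest scores for markers and unknowns", {
  # probes appended to the default world: one protein at the centroid of
  # the largest marker class (deep inside) and one exactly between two
  # class centroids (ambiguous)
  sim <- default_sim()
  spm <- default_matrices()$control
  cent <- sim$centroids
  big <- names(which.max(table(unclass(sim$markers))))
  amb <- sum_normalize(0.5 * cent["cytosol", ] + 0.5 * cent["ER", ])
  X <- rbind(spm$matrix,
             DEEP = rep(cent[big, ], 3),
             AMBIG = rep(amb, 3))
  ts <- train_and_score(X, sim$markers, sigma = 0.1, cost = 16, seed = 4)
  expect_setequal(ts$scores$protein_id, rownames(X))
  expect_true(all(ts$scores$score >= 0 & ts$scores$score <= 1))

  # markers are recovered out-of-fold, with confident scores overall
  mk <- ts$scores[ts$scores$is_marker, ]
  expect_gt(mean(mk$predicted_class == mk$true_class), 0.9)
  expect_gt(median(mk$score), 0.9)

  deep <- ts$scores[ts$scores$protein_id == "DEEP", ]
  expect_identical(deep$predicted_class, big)
  expect_gt(deep$score, 0.9)
  expect_lt(ts$scores$score[ts$scores$protein_id == "AMBIG"], 0.62)

  single <- marker_map("M1", "onlyclass")
  expect_error(
    suppressMessages(train_and_score(spm, single, 0.1, 16)),
    class = "config_error")
})

test_that("FDR thresholds agree with an exhaustive cutoff scan", {
  # independent oracle: scan every observed score as a candidate cutoff
  oracle <- function(df, fdr) {
    classes <- sort(unique(c(df$predicted_class, df$true_class)))
    out <- structure(rep(Inf, length(classes)), names = classes)
    for (cl in classes) {
      sub <- df[df$predicted_class == cl, ]
      if (nrow(sub) == 0) next
      best <- Inf
      for (s in sort(unique(sub$score))) {
        acc <- sub[sub$score >= s, ]
        if (nrow(acc) > 0 && mean(acc$true_class != cl) <= fdr) {
          best <- min(best, s)
        }
      }
      out[cl] <- best
    }
    out
  }
  set.seed(5)
  for (case in 1:20) {
    n <- sample(10:40, 1)
    df <- data.frame(
      predicted_class = sample(c("a", "b", "c"), n, replace = TRUE),
      true_class = sample(c("a", "b", "c"), n, replace = TRUE),
      score = round(runif(n), 2))
    fdr <- sample(c(0.05, 0.2, 0.5), 1)
    expect_equal(
      suppressWarnings(derive_fdr_thresholds(df, fdr)),
      suppressWarnings(oracle(df, fdr)))
  }
})

test_that("FDR threshold edge cases behave as specified", {
  allright <- data.frame(predicted_class = rep("a", 4),
                         true_class = rep("a", 4),
                         score = c(0.9, 0.8, 0.7, 0.6))
  expect_equal(derive_fdr_thresholds(allright, 0.05, classes = "a"),
               c(a = 0.6))

  halfwrong <- data.frame(predicted_class = rep("a", 4),
                          true_class = c("a", "b", "a", "b"),
                          score = c(0.9, 0.9, 0.5, 0.5))
  expect_equal(derive_fdr_thresholds(halfwrong, 0.05, classes = "a"),
               c(a = Inf))

  expect_warning(
    thr <- derive_fdr_thresholds(allright, 0.05, classes = c("a", "b")),
    "no marker predicted")
  expect_equal(thr[["b"]], Inf)
})

test_that("raising the FDR never raises thresholds or unclassifies proteins", {
  set.seed(6)
  df <- data.frame(
    predicted_class = sample(c("a", "b"), 60, replace = TRUE),
    true_class = sample(c("a", "b"), 60, replace = TRUE),
    score = runif(60))
  lo <- suppressWarnings(derive_fdr_thresholds(df, 0.05))
  hi <- suppressWarnings(derive_fdr_thresholds(df, 0.25))
  expect_true(all(hi <= lo))
  cl_lo <- suppressMessages(classify(df, lo))
  cl_hi <- suppressMessages(classify(df, hi))
  was_classified <- cl_lo$final_label != "unknown"
  expect_true(all(cl_hi$final_label[was_classified] != "unknown"))
})

test_that("classify applies thresholds exactly as the invariant states", {
  sim <- small_sim()
  spm <- concatenate_replicates(sim$control)
  ts <- train_and_score(spm, sim$markers, 0.1, 16, seed = 4)
  classes <- sort(unique(unclass(sim$markers)))

  zeros <- structure(rep(0, length(classes)), names = classes)
  res0 <- suppressMessages(classify(ts$scores, zeros))
  expect_true(all(res0$final_label != "unknown"))

  infs <- structure(rep(Inf, length(classes)), names = classes)
  resI <- suppressMessages(classify(ts$scores, infs))
  expect_true(all(resI$final_label == "unknown"))

  thr <- suppressWarnings(derive_fdr_thresholds(ts$scores, 0.05,
                                                classes = classes))
  res <- suppressMessages(classify(ts$scores, thr))
  keep <- res$score >= unname(thr[res$predicted_class])
  expect_identical(res$final_label,
                   unname(ifelse(keep, res$predicted_class, "unknown")))
})

test_that("in the noiseless limit final labels recover the ground truth", {
  sim <- suppressMessages(
    simulate_dataset(generator_config(n_unknown = 30, n_movers = 0,
                                      markers_per_class = rep(6L, 11),
                                      mixture_fraction = 0,
                                      kappa = 1e8, seed = 12)))
  spm <- concatenate_replicates(sim$control)
  res <- suppressMessages(suppressWarnings(
    classify_profiles(spm, sim$markers,
                      svm_config(sigma_grid = 0.1, cost_grid = 16,
                                 cv_rounds = 1, seed = 1),
                      tune = FALSE)))
  truth <- sim$truth$true_class_control[res$protein_id]
  assigned <- res$final_label != "unknown"
  expect_identical(res$final_label[assigned], unname(truth[assigned]))
  expect_gt(mean(assigned), 0.95)
})
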