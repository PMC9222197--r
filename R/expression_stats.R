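# Whole-lysate expression arm: QC-based CV% feature filtering,
# median-log-ratio normalization, Pareto scaling, PCA and per-protein Welch
# t-tests with Bonferroni control.  Pipeline order is fixed:
# CV-filter -> MLR-normalize -> Pareto-scale -> PCA / t-tests.

expr_matrix_of <- function(table) {
  df <- as.data.frame(table)
  assert_that("protein_id" %in% names(df), "schema_error",
              "expression table needs a protein_id column")
  m <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein_id
  m
}

#' Filter features by coefficient of variation in QC samples
#'
#' Keeps a protein iff its percent coefficient of variation
#' (`100 * sd / mean`) across the QC pool columns is strictly lower than the
#' threshold.  With fewer than two QC columns the filter is skipped with a
#' warning.
#'
#' @param table expression data frame (`protein_id` + sample columns).
#' @param groups named vector mapping sample columns to group labels; QC
#'   columns are those labelled `"QC"`.
#' @param threshold CV% cutoff (default 25).
#' @return list with `table` (filtered), `removed` (data frame of dropped
#'   proteins with their CV%), and `cv` (named CV% vector).
#' @export
qc_cv_filter <- function(table, groups, threshold = 25) {
  m <- expr_matrix_of(table)
  qc_cols <- names(groups)[groups == "QC"]
  if (length(qc_cols) < 2) {
    warning("fewer than 2 QC columns; CV% filter skipped")
    return(list(table = table, removed = NULL, cv = NULL))
  }
  qc <- m[, qc_cols, drop = FALSE]
  cv <- 100 * apply(qc, 1, sd) / rowMeans(qc)
  keep <- cv < threshold
  removed <- data.frame(protein_id = rownames(m)[!keep],
                        cv_percent = unname(cv[!keep]),
                        stringsAsFactors = FALSE)
  os_log("CV%% filter (<%g%%): kept %d / %d proteins", threshold,
         sum(keep), length(keep))
  list(table = as.data.frame(table)[keep, , drop = FALSE],
       removed = removed, cv = cv)
}

#' Median-log-ratio normalization
#'
#' Scales each sample so that the median log-ratio of its abundances to a
#' reference profile — the across-sample geometric mean per protein — is
#' zero.  This is the median-log-ratio (size-factor) normalization family;
#' the median makes the factors robust to a minority of truly changing
#' proteins.
#'
#' @param table expression data frame (`protein_id` + positive sample
#'   columns).
#' @return list with `table` (normalized) and `factors` (named per-sample
#'   scale factors; normalized value = raw / factor).
#' @export
mlr_normalize <- function(table) {
  m <- expr_matrix_of(table)
  assert_that(all(is.finite(m)) && all(m > 0), "integrity_error",
              "MLR normalization needs strictly positive abundances")
  ref <- exp(rowMeans(log(m)))
  factors <- apply(m, 2, function(col) exp(median(log(col / ref))))
  norm <- sweep(m, 2, factors, "/")
  out <- data.frame(protein_id = rownames(m), norm, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = out, factors = factors)
}

#' Pareto scaling
#'
#' Feature-wise (per protein): subtract the mean and divide by the square
#' root of the standard deviation — milder than unit-variance scaling, the
#' usual choice for untransformed abundance data.  Constant features map to
#' all zeros with a warning.  Note the operation is not idempotent: scaling
#' twice rescales by the fourth root of the original spread.
#'
#' @param table expression data frame or matrix (features in rows).
#' @return object of the same shape, Pareto-scaled.
#' @export
pareto_scale <- function(table) {
  is_df <- is.data.frame(table) || "protein_id" %in% colnames(table)
  m <- if (is_df) expr_matrix_of(table) else as.matrix(table)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    warning(sprintf("%d constant feature(s) mapped to zero", sum(s == 0)))
  }
  scaled <- (m - mu) / ifelse(s > 0, sqrt(s), 1)
  scaled[s == 0, ] <- 0
  if (is_df) {
    data.frame(protein_id = rownames(m), scaled, check.names = FALSE,
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    scaled
  }
}

#' Principal component analysis of a sample-by-feature matrix
#'
#' Thin wrapper over the singular value decomposition with a fixed sign
#' convention (the largest-magnitude loading of each component is positive)
#' so output is deterministic.
#'
#' @param matrix samples x features numeric matrix (already centered/scaled
#'   as desired; columns are centered here).
#' @param k number of components (default `min(dim)`).
#' @return list with `scores` (samples x k), `loadings` (features x k) and
#'   `variance_explained` (percent, length k, non-increasing).
#' @export
pca_scores <- function(matrix, k = NULL) {
  m <- as.matrix(matrix)
  kmax <- min(nrow(m) - 1, ncol(m))
  k <- k %||% kmax
  assert_that(k >= 1 && k <= kmax, "config_error",
              "k must lie in 1..min(samples - 1, features)")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings,
       variance_explained = ve[seq_len(k)])
}

#' Per-protein Welch t-tests with Bonferroni correction
#'
#' Two-sided unequal-variance t-test per protein between two sample groups;
#' adjusted p-value `min(1, m * p_raw)` with `m` the number of proteins
#' tested.  Degenerate proteins (zero variance in both groups and equal
#' means) get `p = 1` by convention.
#'
#' @param table expression data frame (`protein_id` + sample columns).
#' @param groups named group vector over the sample columns.
#' @param group_a,group_b the two group labels to compare (defaults
#'   `"control"`, `"treated"`).
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @return data frame: `protein_id`, `t`, `p_raw`, `p_adj`, `significant`.
#' @export
ttest_bonferroni <- function(table, groups, group_a = "control",
                             group_b = "treated", alpha = 0.05) {
  m <- expr_matrix_of(table)
  ca <- names(groups)[groups == group_a]
  cb <- names(groups)[groups == group_b]
  assert_that(length(ca) >= 2 && length(cb) >= 2, "config_error",
              "each tested group needs at least two samples")
  A <- m[, ca, drop = FALSE]; B <- m[, cb, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  tstat[degenerate] <- 0
  p[degenerate] <- 1
  n_tests <- nrow(m)
  p_adj <- pmin(1, n_tests * p)
  data.frame(protein_id = rownames(m), t = unname(tstat),
             p_raw = unname(p), p_adj = unname(p_adj),
             significant = unname(p_adj < alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full expression pipeline
#'
#' CV% filter on QC pools, median-log-ratio normalization, Pareto scaling,
#' PCA of the samples, and Welch t-tests with Bonferroni control.  By
#' default the t-test runs on the Pareto-scaled values (set
#' `test_on_scaled = FALSE` to test normalized, unscaled abundances).
#'
#' @param table expression data frame (`protein_id` + sample columns).
#' @param groups named group vector (`control` / `treated` / `QC`).
#' @param cv_threshold CV% cutoff (default 25).
#' @param test_on_scaled run the t-test on Pareto-scaled values (default
#'   TRUE).
#' @param k_pca number of principal components (default 2).
#' @param alpha significance level (default 0.05).
#' @return list with `filtered`, `normalized`, `scaled`, `pca`, `tests`,
#'   and `n_significant`.
#' @export
expression_stats <- function(table, groups, cv_threshold = 25,
                             test_on_scaled = TRUE, k_pca = 2,
                             alpha = 0.05) {
  filt <- qc_cv_filter(table, groups, threshold = cv_threshold)
  norm <- mlr_normalize(filt$table)
  scaled <- pareto_scale(norm$table)
  sm <- expr_matrix_of(scaled)
  k_pca <- min(k_pca, ncol(sm) - 1)
  pca <- pca_scores(t(sm), k = k_pca)
  tests <- ttest_bonferroni(if (test_on_scaled) scaled else norm$table,
                            groups, alpha = alpha)
  os_log("expression: %d tested, %d significant after Bonferroni",
         nrow(tests), sum(tests$significant))
  list(filtered = filt, normalized = norm, scaled = scaled, pca = pca,
       tests = tests, n_significant = sum(tests$significant))
}
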