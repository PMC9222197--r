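# Radial-basis-function support vector machine, one-vs-one multiclass with
# pairwise-coupled class probabilities.  Implemented on top of the quadprog
# dual solver; small training sets (hundreds of markers) keep the dense QP
# cheap.  Kernel convention: k(x, y) = exp(-sigma * ||x - y||^2), so sigma is
# the inverse kernel width.

rbf_kernel <- function(X, Y, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-sigma * d2)
}

# Soft-margin binary C-SVM dual, solved with quadprog on a precomputed
# kernel block.  y must be +1/-1.  Returns the kernel-expansion
# coefficients (alpha_i * y_i) and intercept b.
svm_binary_fit <- function(K, y, cost) {
  n <- length(y)
  stopifnot(nrow(K) == n, all(y %in% c(-1, 1)))
  Q <- (y %o% y) * K
  D <- Q + diag(1e-8, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n),
                            Amat = A, bvec = b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  f_nob <- as.numeric(K %*% (alpha * y))
  tol <- 1e-6 * cost
  free <- alpha > tol & alpha < cost - tol
  if (any(free)) {
    b <- mean(y[free] - f_nob[free])
  } else {
    # no free support vectors: b lies between the KKT bounds
    up <- y == 1 & alpha < tol | y == -1 & alpha > cost - tol
    lo <- y == -1 & alpha < tol | y == 1 & alpha > cost - tol
    hi_b <- if (any(up)) min(y[up] - f_nob[up]) else Inf
    lo_b <- if (any(lo)) max(y[lo] - f_nob[lo]) else -Inf
    b <- mean(c(max(lo_b, -1e6), min(hi_b, 1e6)))
  }
  sv <- alpha > tol
  list(coef = (alpha * y)[sv], sv = which(sv), b = b)
}

# Platt's sigmoid fit: P(y = 1 | f) = 1 / (1 + exp(A f + B)), fitted by
# the regularized Newton procedure of Lin, Weng & Keerthi (2007).
platt_fit <- function(f, y, max_iter = 100) {
  prior1 <- sum(y > 0); prior0 <- sum(y < 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  Fv <- fval(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      nA <- A + step * dA; nB <- B + step * dB
      nF <- fval(nA, nB)
      if (nF < Fv + 1e-4 * step * gd) {
        A <- nA; B <- nB; Fv <- nF
        break
      }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B))
    }
  }
  list(A = A, B = B)
}

#' Fit a multiclass RBF support vector machine
#'
#' One-vs-one decomposition: one soft-margin binary SVM per class pair, with
#' optional per-pair Platt sigmoids so class probabilities can be obtained by
#' pairwise coupling at prediction time.
#'
#' @param X numeric feature matrix (rows = observations).
#' @param labels factor or character vector of class labels (>= 2 classes).
#' @param sigma inverse RBF kernel width in `exp(-sigma * ||x - y||^2)`.
#' @param cost constraint-violation cost C.
#' @param probability fit Platt sigmoids (needed for probability output).
#' @return an object of class `rbf_svm`.
#' @keywords internal
svm_fit <- function(X, labels, sigma, cost, probability = TRUE) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  assert_that(length(classes) >= 2, "config_error",
              "need at least two classes to train a classifier")
  K <- rbf_kernel(X, X, sigma)
  pairs <- utils::combn(length(classes), 2)
  models <- vector("list", ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    idx <- which(labels %in% classes[c(i, j)])
    y <- ifelse(labels[idx] == classes[i], 1, -1)
    fit <- svm_binary_fit(K[idx, idx, drop = FALSE], y, cost)
    f_train <- as.numeric(K[idx, idx[fit$sv], drop = FALSE] %*% fit$coef) +
      fit$b
    platt <- if (probability) platt_fit(f_train, y) else NULL
    models[[m]] <- list(i = i, j = j, idx = idx[fit$sv], coef = fit$coef,
                        b = fit$b, platt = platt)
  }
  structure(list(X = X, classes = classes, sigma = sigma, cost = cost,
                 models = models),
            class = "rbf_svm")
}

# Pairwise coupling of one-vs-one probabilities (Wu, Lin & Weng 2004,
# second approach): solve the KKT system of
#   min sum_i sum_{j!=i} (r_ji p_i - r_ij p_j)^2  s.t. sum p = 1.
couple_probabilities <- function(R) {
  k <- nrow(R)
  Q <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        Q[i, i] <- sum(R[-i, i]^2)
      } else {
        Q[i, j] <- -R[j, i] * R[i, j]
      }
    }
  }
  M <- rbind(cbind(Q, 1), c(rep(1, k), 0))
  rhs <- c(rep(0, k), 1)
  p <- tryCatch(solve(M, rhs)[seq_len(k)],
                error = function(e) rep(1 / k, k))
  p <- pmax(p, 0)
  p / sum(p)
}

#' Predict classes or class probabilities from an RBF SVM
#'
#' @param object an `rbf_svm` fit.
#' @param newdata feature matrix.
#' @param type `"class"` (one-vs-one majority vote; ties broken toward the
#'   class appearing first in the model's sorted class order) or
#'   `"prob"` (pairwise-coupled probabilities).
#' @param ... unused.
#' @return character vector of labels, or a probability matrix with one
#'   column per class.
#' @exportS3Method stats::predict
#' @keywords internal
predict.rbf_svm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  k <- length(object$classes)
  Kfull <- rbf_kernel(newdata, object$X, object$sigma)
  decisions <- vapply(object$models, function(m) {
    as.numeric(Kfull[, m$idx, drop = FALSE] %*% m$coef) + m$b
  }, numeric(n))
  decisions <- matrix(decisions, nrow = n)
  if (type == "class") {
    votes <- matrix(0L, n, k)
    for (m in seq_along(object$models)) {
      mm <- object$models[[m]]
      pos <- decisions[, m] > 0
      votes[, mm$i] <- votes[, mm$i] + pos
      votes[, mm$j] <- votes[, mm$j] + !pos
    }
    return(object$classes[max.col(votes, ties.method = "first")])
  }
  probs <- matrix(0, n, k, dimnames = list(rownames(newdata),
                                           object$classes))
  eps <- 1e-7
  for (obs in seq_len(n)) {
    R <- matrix(0, k, k)
    for (m in seq_along(object$models)) {
      mm <- object$models[[m]]
      stopifnot(!is.null(mm$platt))
      z <- mm$platt$A * decisions[obs, m] + mm$platt$B
      r <- if (z >= 0) exp(-z) / (1 + exp(-z)) else 1 / (1 + exp(z))
      r <- min(max(r, eps), 1 - eps)
      R[mm$i, mm$j] <- r
      R[mm$j, mm$i] <- 1 - r
    }
    probs[obs, ] <- couple_probabilities(R)
  }
  probs
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin across folds.  Returns an integer fold id per observation.
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold_id <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold_id
  })
}
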