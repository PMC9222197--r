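# Bayesian non-parametric two-sample test for differential localization.
# Each protein's replicated fraction profile is mapped to additive log-ratio
# coordinates; a zero-mean Gaussian process with squared-exponential
# covariance is fitted (MAP over Gamma-prior hyperparameters) to the control
# profiles, the treated profiles, and their pool.  The log Bayes factor
# contrasts the independent-model fit against the shared-model fit.

#' Additive log-ratio transform of a composition
#'
#' Maps a strictly positive `F`-part composition to `F - 1` unconstrained
#' coordinates `ln(p_j / p_ref)`, dropping the reference part.  Coordinate
#' order preserves fraction order with the reference removed.  Inputs are
#' floored at `eps` and renormalized first so zeros cannot reach the log.
#'
#' @param composition numeric vector summing to ~1.
#' @param ref reference part index (default: last).
#' @param eps zero floor applied before the transform (default 1e-6).
#' @return numeric vector of length `length(composition) - 1`.
#' @export
alr_transform <- function(composition, ref = length(composition),
                          eps = 1e-6) {
  n <- length(composition)
  assert_that(ref >= 1 && ref <= n, "config_error",
              "ALR reference index out of range")
  assert_that(all(composition >= 0), "integrity_error",
              "composition must be non-negative")
  p <- pmax(composition, eps)
  p <- p / sum(p)
  log(p[-ref] / p[ref])
}

#' Inverse additive log-ratio transform
#'
#' @param alr numeric vector of `F - 1` ALR coordinates.
#' @param ref index at which the reference part is re-inserted.
#' @return composition summing to 1.
#' @export
inverse_alr <- function(alr, ref = length(alr) + 1) {
  n <- length(alr) + 1
  assert_that(ref >= 1 && ref <= n, "config_error",
              "ALR reference index out of range")
  expv <- exp(alr)
  p_ref <- 1 / (1 + sum(expv))
  p <- numeric(n)
  p[-ref] <- expv * p_ref
  p[ref] <- p_ref
  p
}

#' Squared-exponential covariance function
#'
#' `k(x, x') = a2 * exp(-(x - x')^2 / (2 l^2))` with amplitude `a2` and
#' lengthscale `l` in fraction-index units.
#'
#' @param x,xp numeric inputs (vectorized).
#' @param hyper list with `a2`, `l` (and optionally `s2`, unused here).
#' @return covariance value(s).
#' @export
se_kernel <- function(x, xp, hyper) {
  assert_that(hyper$a2 > 0 && hyper$l > 0, "config_error",
              "kernel hyperparameters must be positive")
  hyper$a2 * exp(-(x - xp)^2 / (2 * hyper$l^2))
}

se_cov_matrix <- function(x, hyper) {
  d2 <- outer(x, x, "-")^2
  hyper$a2 * exp(-d2 / (2 * hyper$l^2))
}

#' Gamma priors for the GP hyperparameters
#'
#' Shape/rate Gamma priors on the amplitude `a2`, lengthscale `l` and noise
#' variance `s2` of the squared-exponential GP.  The defaults are weakly
#' informative stand-ins appropriate for ALR-scale profiles over ~10
#' fractions: amplitude ~ Gamma(2, 1), lengthscale ~ Gamma(3, 1), noise ~
#' Gamma(2, 2).
#'
#' @param a2_shape,a2_rate amplitude prior.
#' @param l_shape,l_rate lengthscale prior.
#' @param s2_shape,s2_rate noise-variance prior.
#' @return list of class `gp_priors`.
#' @export
gp_priors <- function(a2_shape = 2, a2_rate = 1,
                      l_shape = 3, l_rate = 1,
                      s2_shape = 2, s2_rate = 2) {
  pr <- list(a2 = c(shape = a2_shape, rate = a2_rate),
             l = c(shape = l_shape, rate = l_rate),
             s2 = c(shape = s2_shape, rate = s2_rate))
  assert_that(all(unlist(pr) > 0), "config_error",
              "Gamma prior parameters must be positive")
  structure(pr, class = "gp_priors")
}

# Cholesky of K + s2 I with escalating jitter.
chol_jitter <- function(M, id = NULL) {
  jitter <- 0
  repeat {
    ch <- tryCatch(chol(M + diag(jitter, nrow(M))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    jitter <- if (jitter == 0) 1e-8 else jitter * 10
    if (jitter > 1e-4) {
      stop_os("numerical_error",
              "covariance not positive definite%s",
              if (is.null(id)) "" else paste0(" for protein ", id))
    }
  }
}

#' Log marginal likelihood of a zero-mean GP with Gaussian noise
#'
#' `-1/2 y' (K + s2 I)^{-1} y - 1/2 log|K + s2 I| - n/2 log(2 pi)` computed
#' via a jittered Cholesky factorization (initial jitter 1e-8, escalated
#' tenfold up to 1e-4).  Repeated inputs (replicates) are allowed.
#'
#' @param xs numeric input locations.
#' @param ys observations (same length).
#' @param hyper list with `a2`, `l`, `s2`.
#' @return scalar log marginal likelihood.
#' @export
gp_log_marginal <- function(xs, ys, hyper) {
  n <- length(ys)
  assert_that(n >= 1 && length(xs) == n, "config_error",
              "xs and ys must be non-empty and equal length")
  K <- se_cov_matrix(xs, hyper) + diag(hyper$s2, n)
  ch <- chol_jitter(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  -0.5 * sum(ys * alpha) - sum(log(diag(ch))) - 0.5 * n * log(2 * pi)
}

# Negative penalized objective and gradient in log-parameter space.
# theta = (log a2, log l, log s2); priors on the natural scale.
gp_neg_objective <- function(theta, xs, ys, priors) {
  a2 <- exp(theta[1]); l <- exp(theta[2]); s2 <- exp(theta[3])
  n <- length(ys)
  d2 <- outer(xs, xs, "-")^2
  Kf <- a2 * exp(-d2 / (2 * l^2))
  K <- Kf + diag(s2, n)
  ch <- chol_jitter(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  logml <- -0.5 * sum(ys * alpha) - sum(log(diag(ch))) -
    0.5 * n * log(2 * pi)
  logprior <-
    stats::dgamma(a2, priors$a2["shape"], priors$a2["rate"], log = TRUE) +
    stats::dgamma(l, priors$l["shape"], priors$l["rate"], log = TRUE) +
    stats::dgamma(s2, priors$s2["shape"], priors$s2["rate"], log = TRUE)
  Kinv <- chol2inv(ch)
  W <- tcrossprod(alpha) - Kinv              # d logml / dK = W / 2
  g_a2 <- 0.5 * sum(W * Kf)                  # dK/dlog a2 = Kf
  g_l <- 0.5 * sum(W * (Kf * d2 / l^2))      # dK/dlog l = Kf d2 / l^2
  g_s2 <- 0.5 * sum(diag(W)) * s2
  # Gamma prior gradients wrt log-parameters
  gp_a2 <- (priors$a2[["shape"]] - 1) - priors$a2[["rate"]] * a2
  gp_l <- (priors$l[["shape"]] - 1) - priors$l[["rate"]] * l
  gp_s2 <- (priors$s2[["shape"]] - 1) - priors$s2[["rate"]] * s2
  list(value = -(logml + logprior),
       grad = -c(g_a2 + gp_a2, g_l + gp_l, g_s2 + gp_s2),
       logml = logml)
}

#' MAP estimate of the GP hyperparameters
#'
#' Maximizes the log marginal likelihood plus the log Gamma priors over
#' log-parameterized `(a2, l, s2)` by L-BFGS-B with analytic gradients and
#' seeded random restarts, returning the best optimum found.
#'
#' @param xs,ys observations.
#' @param priors a [gp_priors()].
#' @param n_restarts number of seeded restarts (default 5).
#' @param seed integer seed for restart initialization.
#' @return list with `a2`, `l`, `s2`, `log_marginal` (the unpenalized log
#'   marginal likelihood at the MAP), `objective` (penalized value) and
#'   `convergence` codes per restart.
#' @export
map_hyperparameters <- function(xs, ys, priors = gp_priors(),
                                n_restarts = 5, seed = 1L) {
  assert_that(length(ys) >= 2, "config_error",
              "need at least two observations")
  inits <- with_seed(seed, {
    first <- c(log(max(var(ys), 1e-3)), log(2), log(max(var(ys) / 4, 1e-3)))
    more <- if (n_restarts > 1) {
      lapply(seq_len(n_restarts - 1), function(i) {
        first + rnorm(3, 0, 1)
      })
    } else list()
    c(list(first), more)
  })
  best <- NULL
  codes <- integer(0)
  for (init in inits) {
    res <- tryCatch(
      stats::optim(init,
                   fn = function(th) gp_neg_objective(th, xs, ys, priors)$value,
                   gr = function(th) gp_neg_objective(th, xs, ys, priors)$grad,
                   method = "L-BFGS-B",
                   lower = rep(log(1e-6), 3), upper = rep(log(1e4), 3),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    codes <- c(codes, res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  assert_that(!is.null(best), "numerical_error",
              "all hyperparameter restarts failed")
  th <- best$par
  obj <- gp_neg_objective(th, xs, ys, priors)
  list(a2 = exp(th[1]), l = exp(th[2]), s2 = exp(th[3]),
       log_marginal = obj$logml, objective = -best$value,
       convergence = codes)
}

# Stack replicate ALR rows into (x = coordinate index, y = value) pairs.
alr_observations <- function(alr_matrix) {
  m <- as.matrix(alr_matrix)
  list(x = rep(seq_len(ncol(m)), each = nrow(m)), y = as.numeric(m))
}

#' Log Bayes factor for differential localization of one protein
#'
#' Fits three GPs — control replicates, treated replicates, and both pooled
#' — each at its own prior-penalized MAP, and returns
#' `logML(control) + logML(treated) - logML(pooled)`.  Observations are
#' (ALR coordinate index, ALR value) pairs with replicates entering as
#' repeated observations.  Positive values support the independent
#' (different-localization) model.
#'
#' @param ctrl,trt matrices of ALR profiles, one replicate per row
#'   (`F - 1` columns).
#' @param priors a [gp_priors()].
#' @param n_restarts,seed MAP optimization settings.
#' @return scalar log Bayes factor (attributes carry the three MAP fits).
#' @export
log_bayes_factor <- function(ctrl, trt, priors = gp_priors(),
                             n_restarts = 5, seed = 1L) {
  ctrl <- as.matrix(ctrl); trt <- as.matrix(trt)
  assert_that(nrow(ctrl) >= 1 && nrow(trt) >= 1, "config_error",
              "each condition needs at least one replicate")
  assert_that(ncol(ctrl) == ncol(trt), "config_error",
              "conditions disagree on profile length")
  oc <- alr_observations(ctrl)
  ot <- alr_observations(trt)
  fit_c <- map_hyperparameters(oc$x, oc$y, priors, n_restarts, seed)
  fit_t <- map_hyperparameters(ot$x, ot$y, priors, n_restarts, seed)
  fit_p <- map_hyperparameters(c(oc$x, ot$x), c(oc$y, ot$y), priors,
                               n_restarts, seed)
  lbf <- fit_c$log_marginal + fit_t$log_marginal - fit_p$log_marginal
  attr(lbf, "fits") <- list(control = fit_c, treated = fit_t, pooled = fit_p)
  lbf
}

#' Convert a log Bayes factor to a posterior probability of difference
#'
#' With prior probability `prior` on the independent model, the posterior is
#' `prior * BF / (prior * BF + 1 - prior)`, computed stably in log space as
#' a logistic of `logBF + logit(prior)`.
#'
#' @param log_bf log Bayes factor (vectorized).
#' @param prior prior probability of the independent model in (0, 1)
#'   (default 0.01).
#' @return posterior probabilities in `[0, 1]`.
#' @export
bf_to_posterior <- function(log_bf, prior = 0.01) {
  assert_that(prior > 0 && prior < 1, "config_error",
              "prior must lie in (0, 1)")
  # direct form is exact at log BF = 0 (returns the prior bit-for-bit);
  # capping the exponent keeps it stable at +/- infinity
  bf <- exp(pmin(log_bf, 700))
  prior * bf / (prior * bf + (1 - prior))
}

#' Run the differential-localization test over all shared proteins
#'
#' For each protein present in both conditions, extracts the per-replicate
#' compositions, applies the additive log-ratio transform, and computes the
#' GP log Bayes factor, posterior probability and mover flag.
#'
#' @param control,treated `SpatialProfileMatrix` objects.
#' @param priors a [gp_priors()].
#' @param prior prior probability of the independent model (default 0.01).
#' @param mover_threshold posterior cutoff for calling a mover; the default
#'   `1 - 1e-6` operationalizes "posterior equal to 1" at double precision.
#' @param alr_ref ALR reference fraction (default: last fraction).
#' @param n_restarts,seed MAP optimization settings.
#' @param proteins optional subset of protein ids to test.
#' @return a `DiffLocResult` data frame: `protein_id`, `log_bayes_factor`,
#'   `posterior`, `mover`, ordered by decreasing posterior then log Bayes
#'   factor (ties by protein id).
#' @export
diffloc_test <- function(control, treated, priors = gp_priors(),
                         prior = 0.01, mover_threshold = 1 - 1e-6,
                         alr_ref = NULL, n_restarts = 5, seed = 1L,
                         proteins = NULL) {
  common <- intersect_conditions(control, treated)
  if (!is.null(proteins)) common <- intersect(common, proteins)
  assert_that(length(common) > 0, "empty_result_error",
              "no shared protein to test")
  Fn <- control$n_fractions
  alr_ref <- alr_ref %||% Fn

  alr_block <- function(spm, id) {
    t(vapply(spm$replicate_boundaries, function(cols) {
      alr_transform(spm$matrix[id, cols], ref = alr_ref)
    }, numeric(Fn - 1)))
  }

  lbf <- vapply(common, function(id) {
    as.numeric(log_bayes_factor(alr_block(control, id),
                                alr_block(treated, id),
                                priors = priors, n_restarts = n_restarts,
                                seed = seed))
  }, numeric(1))
  res <- data.frame(protein_id = common,
                    log_bayes_factor = unname(lbf),
                    posterior = bf_to_posterior(unname(lbf), prior),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$mover <- res$posterior >= mover_threshold
  res <- res[order(-res$posterior, -res$log_bayes_factor, res$protein_id), ]
  rownames(res) <- NULL
  class(res) <- c("DiffLocResult", "data.frame")
  res
}

#' Flag and rank movers at a posterior threshold
#'
#' @param results a `DiffLocResult` (or data frame with `protein_id`,
#'   `log_bayes_factor`, `posterior`).
#' @param mover_threshold posterior cutoff (default `1 - 1e-6`).
#' @return the results with the `mover` flag recomputed, ordered by
#'   decreasing posterior, then log Bayes factor, then protein id.
#' @export
call_movers <- function(results, mover_threshold = 1 - 1e-6) {
  df <- as.data.frame(results)
  df$mover <- df$posterior >= mover_threshold
  df <- df[order(-df$posterior, -df$log_bayes_factor, df$protein_id), ]
  rownames(df) <- NULL
  class(df) <- c("DiffLocResult", "data.frame")
  df
}
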