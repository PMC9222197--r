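#' Configuration for the synthetic fractionation-data generator
#'
#' The generator emulates the structure of a replicated LOPIT-DC experiment:
#' per-protein compositional profiles over `F` centrifugation fractions,
#' concentrated around organelle-specific centroid profiles, with a curated
#' marker set and a configurable number of proteins whose compartment differs
#' between the two conditions ("movers").
#'
#' @param n_classes number of compartments (default 11).
#' @param F_fractions fractions per replicate (default 10).
#' @param R_replicates replicates per condition (default 3).
#' @param markers_per_class integer vector of marker counts per class;
#'   defaults to the curated 548-marker structure
#'   ([default_marker_counts()]) when `n_classes` is 11, otherwise 20 each.
#' @param n_unknown number of unlabelled proteins (default 500).
#' @param n_movers number of unknowns that change compartment between
#'   conditions (default 0).
#' @param lambda mover completeness in `[0, 1]`: the treated-condition
#'   centroid of a mover is `lambda * new + (1 - lambda) * old`.  1 is a
#'   complete translocation.
#' @param kappa Dirichlet precision (> 0): profiles are drawn
#'   `Dirichlet(kappa * centroid)`, so larger values concentrate profiles
#'   around their compartment centroid.  The default 200 gives marker
#'   clusters that separate cleanly in PCA, comparable to real maps.
#' @param separation minimum pairwise total-variation distance between class
#'   centroids (default 0.3).
#' @param mixture_fraction fraction of unknowns drawn from two-class mixture
#'   centroids, emulating proteins residing in multiple locations
#'   (default 0.2).
#' @param seed integer seed.
#' @return a list of class `GeneratorConfig`.
#' @export
generator_config <- function(n_classes = 11, F_fractions = 10,
                             R_replicates = 3, markers_per_class = NULL,
                             n_unknown = 500, n_movers = 0, lambda = 1,
                             kappa = 200, separation = 0.3,
                             mixture_fraction = 0.2, seed = 1L) {
  if (is.null(markers_per_class)) {
    markers_per_class <- if (n_classes == 11) {
      unname(default_marker_counts())
    } else {
      rep(20L, n_classes)
    }
  }
  assert_that(length(markers_per_class) == n_classes, "config_error",
              "markers_per_class must have one count per class")
  assert_that(n_movers <= n_unknown, "config_error",
              "n_movers must not exceed n_unknown")
  assert_that(lambda >= 0 && lambda <= 1, "config_error",
              "lambda must lie in [0, 1]")
  assert_that(kappa > 0, "config_error", "kappa must be positive")
  classes <- if (n_classes == 11) default_compartments() else
    paste0("class_", seq_len(n_classes))
  structure(
    list(n_classes = n_classes, F_fractions = F_fractions,
         R_replicates = R_replicates,
         markers_per_class = as.integer(markers_per_class),
         n_unknown = as.integer(n_unknown), n_movers = as.integer(n_movers),
         lambda = lambda, kappa = kappa, separation = separation,
         mixture_fraction = mixture_fraction, classes = classes,
         seed = as.integer(seed)),
    class = "GeneratorConfig"
  )
}

#' Generate compartment centroid profiles
#'
#' Each compartment gets a compositional profile over the fractions with a
#' distinct peak, mimicking organelle-specific sedimentation: early-pelleting
#' compartments peak in early fractions, soluble ones late.  When there are
#' more classes than fractions the surplus classes get bimodal profiles.
#' Centroids are jittered (seeded) and rejected until every pair is at least
#' `separation` apart in total-variation distance.
#'
#' @param n_classes number of compartments.
#' @param F_fractions number of fractions.
#' @param seed integer seed.
#' @param separation minimum pairwise total-variation distance (default 0.3).
#' @param max_tries bounded retries before giving up (default 50).
#' @return `n_classes` x `F_fractions` matrix; rows sum to 1.
#' @export
make_class_centroids <- function(n_classes, F_fractions, seed,
                                 separation = 0.3, max_tries = 50) {
  assert_that(n_classes >= 2, "config_error", "need at least two classes")
  assert_that(n_classes <= 2 * F_fractions, "config_error",
              "too many classes for the fraction count")
  # Each compartment: a dominant enrichment peak plus a class-specific
  # secondary peak (organelles spread over two pellets), a boost in the
  # final-supernatant fraction (every protein retains soluble signal there,
  # which also stabilizes the log-ratio reference), and a small floor so no
  # fraction is ever empty.
  main_share <- 0.50; sec_share <- 0.25; ref_boost <- 0.10; floor_bg <- 0.02
  secondary <- if (F_fractions == 10) {
    c(5, 7, 9, 6, 8, 3, 1, 4, 2, 6)
  } else {
    (((seq_len(F_fractions) - 1) + floor(F_fractions / 2)) %%
       F_fractions) + 1
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      width <- 0.45 * 0.95^(try - 1)   # sharpen peaks if separation fails
      cent <- matrix(0, n_classes, F_fractions)
      j <- seq_len(F_fractions)
      bump <- function(at) {
        g <- exp(-(j - at)^2 / (2 * width^2))
        g / sum(g)
      }
      for (k in seq_len(n_classes)) {
        if (k <= F_fractions) {
          g <- main_share * bump(k) + sec_share * bump(secondary[k])
        } else {
          # surplus classes: bimodal, peaks between fractions so they do
          # not coincide with any unimodal class's enrichment maximum
          p1 <- ((k - F_fractions - 1) * 3) %% F_fractions + 1.5
          p2 <- ((p1 + floor(F_fractions / 2) - 1) %% F_fractions) + 1
          g <- (main_share + sec_share) * (bump(p1) + bump(p2)) / 2
        }
        prof <- g + floor_bg
        prof[F_fractions] <- prof[F_fractions] + ref_boost
        prof <- prof * exp(rnorm(F_fractions, 0, 0.05))  # seeded jitter
        cent[k, ] <- prof / sum(prof)
      }
      tv <- pairwise_tv(cent)
      if (min(tv) >= separation) {
        rownames(cent) <- paste0("class_", seq_len(n_classes))
        colnames(cent) <- paste0("fraction_", j)
        return(cent)
      }
    }
  })
  stop_os("config_error",
          "could not achieve centroid separation %.2f in %d tries",
          separation, max_tries)
}

# all pairwise total-variation distances between composition rows
pairwise_tv <- function(m) {
  n <- nrow(m)
  pairs <- utils::combn(n, 2)
  apply(pairs, 2, function(ij) sum(abs(m[ij[1], ] - m[ij[2], ])) / 2)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a paired control/treated fractionation dataset with ground truth
#'
#' Marker and unknown proteins are assigned compartments; each protein's
#' profile in each replicate is drawn `Dirichlet(kappa * centroid)` of its
#' compartment centroid.  Movers use their control-class centroid in the
#' control condition and the blend
#' `lambda * centroid_new + (1 - lambda) * centroid_old` in the treated one.
#' A floor of 1e-9 (followed by renormalization) removes exact zeros so
#' downstream log-ratio transforms stay finite.
#'
#' @param config a [generator_config()].
#' @return list with elements `control` and `treated`
#'   (normalized `FractionationExperiment`s), `markers` (a `MarkerMap`),
#'   `centroids`, and `truth` — a list with `true_class_control`,
#'   `true_class_treated` (named vectors), `mover_ids` and `mover_pairs`
#'   (data frame `protein_id`, `class_control`, `class_treated`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  cfg <- config
  cent <- make_class_centroids(cfg$n_classes, cfg$F_fractions,
                               child_seed(cfg$seed, 1),
                               separation = cfg$separation)
  rownames(cent) <- cfg$classes

  with_seed(child_seed(cfg$seed, 2), {
    marker_ids <- sprintf("MRK%04d", seq_len(sum(cfg$markers_per_class)))
    marker_class <- rep(cfg$classes, cfg$markers_per_class)
    unk_ids <- if (cfg$n_unknown > 0) {
      sprintf("UNK%04d", seq_len(cfg$n_unknown))
    } else character(0)

    # unknowns: mostly pure classes, some two-class mixtures
    n_mix <- round(cfg$mixture_fraction * cfg$n_unknown)
    is_mix <- rep(FALSE, cfg$n_unknown)
    if (n_mix > 0) is_mix[sample.int(cfg$n_unknown, n_mix)] <- TRUE
    unk_class <- sample(cfg$classes, cfg$n_unknown, replace = TRUE)
    mix_partner <- vapply(seq_len(cfg$n_unknown), function(i) {
      if (is_mix[i]) sample(setdiff(cfg$classes, unk_class[i]), 1)
      else NA_character_
    }, character(1))

    # movers are drawn from the pure unknowns so translocation is well defined
    pure_idx <- which(!is_mix)
    assert_that(length(pure_idx) >= cfg$n_movers, "config_error",
                "not enough pure unknowns to host the movers")
    mover_idx <- if (cfg$n_movers > 0) {
      sort(sample(pure_idx, cfg$n_movers))
    } else integer(0)
    mover_new <- vapply(mover_idx, function(i) {
      sample(setdiff(cfg$classes, unk_class[i]), 1)
    }, character(1))

    ids <- c(marker_ids, unk_ids)
    ctrl_class <- c(marker_class, unk_class)
    names(ctrl_class) <- ids
    trt_class <- ctrl_class
    trt_class[unk_ids[mover_idx]] <- mover_new

    centroid_for <- function(i, condition) {
      id <- ids[i]
      if (i > length(marker_ids)) {
        u <- i - length(marker_ids)
        if (is_mix[u]) {
          return(0.5 * cent[unk_class[u], ] + 0.5 * cent[mix_partner[u], ])
        }
        if (condition == "treated" && u %in% mover_idx) {
          old <- cent[unk_class[u], ]
          new <- cent[trt_class[id], ]
          return(cfg$lambda * new + (1 - cfg$lambda) * old)
        }
      }
      cent[ctrl_class[id], ]
    }

    draw_experiment <- function(condition) {
      reps <- lapply(seq_len(cfg$R_replicates), function(r) {
        m <- t(vapply(seq_along(ids), function(i) {
          p <- rdirichlet(1, cfg$kappa * centroid_for(i, condition))[1, ]
          p <- pmax(p, 1e-9)
          p / sum(p)
        }, numeric(cfg$F_fractions)))
        rownames(m) <- ids
        colnames(m) <- paste0("fraction_", seq_len(cfg$F_fractions))
        m
      })
      names(reps) <- paste0("rep", seq_len(cfg$R_replicates))
      fractionation_experiment(condition, reps)
    }

    control <- draw_experiment("control")
    treated <- draw_experiment("treated")

    mover_ids <- unk_ids[mover_idx]
    truth <- list(
      true_class_control = ctrl_class,
      true_class_treated = trt_class,
      mover_ids = mover_ids,
      mover_pairs = data.frame(
        protein_id = mover_ids,
        class_control = unname(ctrl_class[mover_ids]),
        class_treated = unname(trt_class[mover_ids]),
        stringsAsFactors = FALSE),
      mixture_ids = unk_ids[is_mix]
    )
    markers <- suppressMessages(marker_map(marker_ids, marker_class))
    list(control = control, treated = treated, markers = markers,
         centroids = cent, truth = truth)
  })
}

#' Simulate a whole-lysate expression table with QC pool columns
#'
#' Emulates a label-free expression experiment with two groups plus a
#' quality-control group of pooled samples: per-protein log-normal
#' abundances, group effects expressed as log2 fold changes, and QC columns
#' drawn around the pool mean with a controllable coefficient of variation so
#' that CV-based feature filtering can be exercised.
#'
#' @param n_proteins number of proteins.
#' @param n_per_group samples per biological group (default 5).
#' @param n_qc QC pool columns (default 3).
#' @param effect_ids protein ids (or indices) carrying a true effect.
#' @param log2fc log2 fold change applied to `effect_ids` in the treated
#'   group (default 0).
#' @param cv_qc coefficient of variation of the QC columns (default 0.1);
#'   may be a per-protein vector.
#' @param cv_bio biological coefficient of variation within groups
#'   (default 0.2).
#' @param seed integer seed.
#' @return list with `table` (data frame: `protein_id` then sample columns),
#'   `groups` (named vector mapping sample column to
#'   control/treated/QC) and `truth` (character vector of true-effect ids).
#' @export
simulate_expression_table <- function(n_proteins, n_per_group = 5, n_qc = 3,
                                      effect_ids = character(0), log2fc = 0,
                                      cv_qc = 0.1, cv_bio = 0.2, seed = 1L) {
  with_seed(seed, {
    ids <- sprintf("PROT%05d", seq_len(n_proteins))
    if (is.numeric(effect_ids)) effect_ids <- ids[effect_ids]
    assert_that(all(effect_ids %in% ids), "config_error",
                "effect_ids must be simulated proteins")
    base <- exp(rnorm(n_proteins, mean = log(1e5), sd = 1))
    fc <- ifelse(ids %in% effect_ids, 2^log2fc, 1)
    sdlog_bio <- sqrt(log1p(cv_bio^2))
    draw_group <- function(mu, n) {
      vapply(seq_len(n), function(i) {
        mu * exp(rnorm(n_proteins, -sdlog_bio^2 / 2, sdlog_bio))
      }, numeric(n_proteins))
    }
    ctrl <- draw_group(base, n_per_group)
    trt <- draw_group(base * fc, n_per_group)
    pool <- rowMeans(cbind(ctrl, trt))
    cv_qc <- rep_len(cv_qc, n_proteins)
    qc <- vapply(seq_len(n_qc), function(i) {
      pool * exp(rnorm(n_proteins, 0, sqrt(log1p(cv_qc^2))))
    }, numeric(n_proteins))
    tab <- data.frame(protein_id = ids, ctrl, trt, qc,
                      stringsAsFactors = FALSE)
    snames <- c(paste0("control_", seq_len(n_per_group)),
                paste0("treated_", seq_len(n_per_group)),
                paste0("QC_", seq_len(n_qc)))
    colnames(tab)[-1] <- snames
    groups <- structure(rep(c("control", "treated", "QC"),
                            c(n_per_group, n_per_group, n_qc)),
                        names = snames)
    list(table = tab, groups = groups, truth = effect_ids)
  })
}

#' Write a simulated dataset to disk in the package's tabular formats
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    control = file.path(dir, "control_profiles.tsv"),
    treated = file.path(dir, "treated_profiles.tsv"),
    markers = file.path(dir, "markers.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_profiles(sim$control, paths[["control"]])
  write_profiles(sim$treated, paths[["treated"]])
  utils::write.table(
    data.frame(protein_id = names(sim$markers),
               compartment = unclass(sim$markers)),
    paths[["markers"]], sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  utils::write.table(
    data.frame(protein_id = names(tr$true_class_control),
               class_control = unname(tr$true_class_control),
               class_treated = unname(tr$true_class_treated),
               mover = names(tr$true_class_control) %in% tr$mover_ids),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
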