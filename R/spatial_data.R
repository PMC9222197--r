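#' Data model for differential-centrifugation fractionation profiles
#'
#' A `FractionationExperiment` holds one condition's replicated protein-by-
#' fraction abundance tables, as produced by a LOPIT-DC style workflow in
#' which organelles are separated into `F` sequential centrifugation
#' fractions (default 10) and protein abundance is quantified per fraction
#' (one isobaric-label channel per fraction).
#'
#' @param condition_label single string naming the condition
#'   (e.g. `"control"`).
#' @param replicates named or unnamed list of numeric matrices, one per
#'   replicate; rows are proteins (rownames are protein ids), columns the
#'   `F` fractions in centrifugation order.  All abundances must be finite
#'   and non-negative and all replicates must share the same fraction count.
#' @return an object of class `FractionationExperiment`.
#' @export
fractionation_experiment <- function(condition_label, replicates) {
  assert_that(is.character(condition_label) && length(condition_label) == 1,
              "schema_error", "condition_label must be a single string")
  assert_that(is.list(replicates) && length(replicates) >= 1,
              "schema_error", "at least one replicate is required")
  replicates <- lapply(replicates, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  Fs <- vapply(replicates, ncol, integer(1))
  assert_that(length(unique(Fs)) == 1, "schema_error",
              "replicates disagree on fraction count: %s",
              paste(Fs, collapse = ", "))
  for (i in seq_along(replicates)) {
    m <- replicates[[i]]
    assert_that(!is.null(rownames(m)), "schema_error",
                "replicate %d has no protein ids (rownames)", i)
    assert_that(!anyDuplicated(rownames(m)), "integrity_error",
                "replicate %d contains duplicated protein ids", i)
    assert_that(all(is.finite(m)) && all(m >= 0), "integrity_error",
                "replicate %d contains negative or non-finite abundances", i)
  }
  if (is.null(names(replicates))) {
    names(replicates) <- paste0("rep", seq_along(replicates))
  }
  structure(
    list(condition_label = condition_label,
         replicates = replicates,
         n_fractions = unname(Fs[1])),
    class = "FractionationExperiment"
  )
}

#' @export
print.FractionationExperiment <- function(x, ...) {
  cat(sprintf(
    "FractionationExperiment '%s': %d replicate(s), %d fractions\n",
    x$condition_label, length(x$replicates), x$n_fractions))
  for (nm in names(x$replicates)) {
    cat(sprintf("  %s: %d proteins\n", nm, nrow(x$replicates[[nm]])))
  }
  invisible(x)
}

#' Read fractionation profiles from a delimited file
#'
#' Accepts either wide form (columns `protein_id`, `replicate`,
#' `fraction_1` ... `fraction_F`) or long form (columns `protein_id`,
#' `replicate`, `fraction`, `abundance`).  The delimiter is autodetected from
#' the file extension: `.csv` is comma-separated, anything else is read as
#' tab-separated.  Replicates are ordered by their label.
#'
#' @param path path to a TSV/CSV file.
#' @param condition_label condition name attached to the returned experiment;
#'   defaults to the file name without extension.
#' @return a [fractionation_experiment()].
#' @export
read_profiles <- function(path, condition_label = NULL) {
  assert_that(file.exists(path), "schema_error", "file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  condition_label <- condition_label %||%
    sub("\\.[^.]*$", "", basename(path))

  long_form <- all(c("protein_id", "replicate", "fraction", "abundance")
                   %in% names(df))
  wide_cols <- grep("^fraction_[0-9]+$", names(df), value = TRUE)
  wide_form <- all(c("protein_id", "replicate") %in% names(df)) &&
    length(wide_cols) > 0

  if (!long_form && !wide_form) {
    stop_os("schema_error", paste(
      "expected wide columns (protein_id, replicate, fraction_1..fraction_F)",
      "or long columns (protein_id, replicate, fraction, abundance)"))
  }

  if (long_form && !wide_form) {
    check_abundance(df$abundance)
    Fn <- max(df$fraction)
    assert_that(all(df$fraction %in% seq_len(Fn)), "schema_error",
                "fraction indices must be 1..F")
    key <- paste(df$protein_id, df$replicate, df$fraction)
    assert_that(!anyDuplicated(key), "integrity_error",
                "duplicate (protein, replicate, fraction) rows")
    reps <- split(df, df$replicate)
    replicates <- lapply(reps, function(d) {
      ids <- sort(unique(d$protein_id))
      m <- matrix(NA_real_, length(ids), Fn,
                  dimnames = list(ids, paste0("fraction_", seq_len(Fn))))
      m[cbind(match(d$protein_id, ids), d$fraction)] <- d$abundance
      assert_that(!anyNA(m), "integrity_error",
                  "incomplete fraction series in long-form input")
      m
    })
  } else {
    wide_cols <- paste0("fraction_",
                        sort(as.integer(sub("^fraction_", "", wide_cols))))
    for (cl in wide_cols) check_abundance(df[[cl]])
    key <- paste(df$protein_id, df$replicate)
    assert_that(!anyDuplicated(key), "integrity_error",
                "duplicate (protein, replicate) rows")
    reps <- split(df, df$replicate)
    replicates <- lapply(reps, function(d) {
      m <- as.matrix(d[, wide_cols, drop = FALSE])
      rownames(m) <- d$protein_id
      m[order(rownames(m)), , drop = FALSE]
    })
  }
  replicates <- replicates[order(names(replicates))]
  fractionation_experiment(condition_label, replicates)
}

check_abundance <- function(x) {
  assert_that(is.numeric(x), "integrity_error", "non-numeric abundance")
  assert_that(all(is.finite(x)) && all(x >= 0), "integrity_error",
              "negative or non-finite abundance value")
}

#' Write a FractionationExperiment to a wide-form delimited file
#'
#' Inverse of [read_profiles()]: values round-trip exactly (written with
#' full double precision).
#'
#' @param exp a `FractionationExperiment`.
#' @param path output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(exp, path) {
  stopifnot(inherits(exp, "FractionationExperiment"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  rows <- lapply(names(exp$replicates), function(nm) {
    m <- exp$replicates[[nm]]
    data.frame(protein_id = rownames(m), replicate = nm,
               m, check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  colnames(df)[-(1:2)] <- paste0("fraction_", seq_len(exp$n_fractions))
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalize an abundance vector to a composition
#'
#' Divides by the vector sum so the profile sums to one — the per-replicate
#' channel normalization used for fractionation profiles.
#'
#' @param raw non-negative numeric vector with positive sum.
#' @return numeric vector summing to 1.
#' @export
sum_normalize <- function(raw) {
  assert_that(is.numeric(raw) && all(is.finite(raw)) && all(raw >= 0),
              "integrity_error", "abundances must be finite and non-negative")
  s <- sum(raw)
  assert_that(s > 0, "degenerate_profile_error",
              "all-zero abundance vector cannot be normalized")
  raw / s
}

#' Sum-normalize every profile of an experiment, dropping degenerate rows
#'
#' Proteins with an all-zero profile in a replicate are treated as missing in
#' that replicate and dropped from it, with a logged count.
#'
#' @param exp a `FractionationExperiment`.
#' @return a `FractionationExperiment` whose rows each sum to 1.
#' @export
normalize_experiment <- function(exp) {
  stopifnot(inherits(exp, "FractionationExperiment"))
  reps <- lapply(names(exp$replicates), function(nm) {
    m <- exp$replicates[[nm]]
    rs <- rowSums(m)
    zero <- rs == 0
    if (any(zero)) {
      os_log("%s/%s: dropped %d all-zero profile(s)",
             exp$condition_label, nm, sum(zero))
      m <- m[!zero, , drop = FALSE]
      rs <- rs[!zero]
    }
    m / rs
  })
  names(reps) <- names(exp$replicates)
  fractionation_experiment(exp$condition_label, reps)
}

#' Concatenate sum-normalized replicates into a profile matrix
#'
#' Keeps only proteins observed in every replicate (missing-value removal)
#' and binds the replicate profiles column-wise, giving each protein a
#' concatenated R x F profile.  Each replicate block of each row sums to 1.
#'
#' @param exp a `FractionationExperiment` with sum-normalized replicates
#'   (see [normalize_experiment()]).
#' @return an object of class `SpatialProfileMatrix` with fields
#'   `protein_ids`, `matrix`, `replicate_boundaries`, `n_fractions`,
#'   `condition_label`.
#' @export
concatenate_replicates <- function(exp) {
  stopifnot(inherits(exp, "FractionationExperiment"))
  Fn <- exp$n_fractions
  for (nm in names(exp$replicates)) {
    rs <- rowSums(exp$replicates[[nm]])
    assert_that(all(abs(rs - 1) <= 1e-9), "integrity_error",
                "replicate %s is not sum-normalized; call normalize_experiment() first",
                nm)
  }
  ids <- Reduce(intersect, lapply(exp$replicates, rownames))
  assert_that(length(ids) > 0, "empty_result_error",
              "no protein is present in every replicate")
  ids <- sort(ids)
  blocks <- lapply(exp$replicates, function(m) m[ids, , drop = FALSE])
  mat <- do.call(cbind, blocks)
  R <- length(blocks)
  colnames(mat) <- paste0(rep(names(exp$replicates), each = Fn),
                          "_fraction_", rep(seq_len(Fn), R))
  boundaries <- lapply(seq_len(R), function(r) ((r - 1) * Fn + 1):(r * Fn))
  names(boundaries) <- names(exp$replicates)
  structure(
    list(protein_ids = ids, matrix = mat,
         replicate_boundaries = boundaries,
         n_fractions = Fn,
         condition_label = exp$condition_label),
    class = "SpatialProfileMatrix"
  )
}

#' @export
print.SpatialProfileMatrix <- function(x, ...) {
  cat(sprintf(
    "SpatialProfileMatrix '%s': %d proteins x %d columns (%d replicate(s) x %d fractions)\n",
    x$condition_label, length(x$protein_ids), ncol(x$matrix),
    length(x$replicate_boundaries), x$n_fractions))
  invisible(x)
}

#' Proteins observed in both conditions
#'
#' The differential-localization test runs only on proteins profiled in both
#' conditions; this returns that sorted intersection.
#'
#' @param a,b `SpatialProfileMatrix` objects built with the same fraction
#'   count.
#' @return sorted character vector of shared protein ids (possibly empty,
#'   with a warning).
#' @export
intersect_conditions <- function(a, b) {
  stopifnot(inherits(a, "SpatialProfileMatrix"),
            inherits(b, "SpatialProfileMatrix"))
  assert_that(a$n_fractions == b$n_fractions, "schema_error",
              "profile matrices disagree on fraction count")
  common <- sort(intersect(a$protein_ids, b$protein_ids))
  if (length(common) == 0) {
    warning("no protein is shared between the two conditions")
  }
  common
}

#' Read a marker file mapping proteins to compartments
#'
#' Markers are proteins with a single literature-established subcellular
#' residence, used as labelled training data for compartment assignment.
#' The file must have two columns, `protein_id` and `compartment`.  Markers
#' absent from `proteins` (when given) are dropped with a logged count.
#'
#' @param path two-column TSV/CSV.
#' @param proteins optional character vector of profiled protein ids used to
#'   filter the markers.
#' @return a named character vector (class `MarkerMap`): names are protein
#'   ids, values compartment labels.
#' @export
read_markers <- function(path, proteins = NULL) {
  assert_that(file.exists(path), "schema_error", "file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  assert_that(all(c("protein_id", "compartment") %in% names(df)),
              "schema_error",
              "marker file needs columns protein_id and compartment")
  assert_that(nrow(df) > 0, "schema_error", "marker file is empty")
  dup <- unique(df$protein_id[duplicated(df$protein_id)])
  if (length(dup)) {
    conflicting <- vapply(dup, function(p) {
      length(unique(df$compartment[df$protein_id == p])) > 1
    }, logical(1))
    assert_that(!any(conflicting), "integrity_error",
                "marker(s) listed under two compartments: %s",
                paste(head(dup[conflicting], 5), collapse = ", "))
    df <- df[!duplicated(df$protein_id), ]
  }
  marker_map(df$protein_id, df$compartment, proteins)
}

#' Construct a MarkerMap
#'
#' @param protein_id character vector of marker ids.
#' @param compartment compartment label per marker.
#' @param proteins optional profiled-protein filter, as in [read_markers()].
#' @return named character vector of class `MarkerMap`.
#' @export
marker_map <- function(protein_id, compartment, proteins = NULL) {
  assert_that(!anyDuplicated(protein_id), "integrity_error",
              "duplicated marker protein id")
  mm <- structure(as.character(compartment), names = as.character(protein_id))
  if (!is.null(proteins)) {
    missing <- setdiff(names(mm), proteins)
    if (length(missing)) {
      os_log("dropped %d marker(s) absent from the profile matrix",
             length(missing))
      mm <- mm[setdiff(names(mm), missing)]
    }
  }
  assert_that(length(mm) > 0, "empty_result_error",
              "no marker remains after filtering")
  counts <- table(mm)
  os_log("markers: %d proteins in %d compartments (%s)",
         length(mm), length(counts),
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  class(mm) <- "MarkerMap"
  mm
}

#' @export
print.MarkerMap <- function(x, ...) {
  counts <- table(unclass(x))
  cat(sprintf("MarkerMap: %d markers, %d compartments\n",
              length(x), length(counts)))
  print(counts)
  invisible(x)
}

#' Default compartment class set
#'
#' The 11 subcellular compartments resolved by the differential
#' centrifugation protocol.
#' @return character vector of 11 compartment names.
#' @export
default_compartments <- function() {
  c("cytosol", "ER", "proteasome", "Golgi", "lysosome", "mitochondrion",
    "nucleus", "nucleus-chromatin", "ribosome", "peroxisome",
    "plasma membrane")
}

#' Curated marker counts per compartment
#'
#' Per-class sizes of the 548-protein curated marker set used as the default
#' synthetic-data marker structure.
#' @return named integer vector over [default_compartments()].
#' @export
default_marker_counts <- function() {
  structure(c(58L, 96L, 29L, 16L, 17L, 101L, 107L, 32L, 47L, 15L, 30L),
            names = default_compartments())
}
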