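# Shared fixtures, memoized so heavy simulations run once per session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# The default synthetic world: curated marker structure, 500 unknowns,
# 50 complete movers, kappa = 200.
default_sim <- function() {
  memo("default_sim", suppressMessages(
    simulate_dataset(generator_config(n_unknown = 500, n_movers = 50,
                                      lambda = 1, kappa = 200, seed = 20))))
}

default_matrices <- function() {
  memo("default_matrices", {
    sim <- default_sim()
    list(control = concatenate_replicates(sim$control),
         treated = concatenate_replicates(sim$treated))
  })
}

# Null world: no movers at all.
null_sim <- function() {
  memo("null_sim", suppressMessages(
    simulate_dataset(generator_config(n_unknown = 500, n_movers = 0,
                                      kappa = 200, seed = 11))))
}

# A small, fast world for structural tests.
small_sim <- function() {
  memo("small_sim", suppressMessages(
    simulate_dataset(generator_config(n_unknown = 40, n_movers = 5,
                                      markers_per_class = rep(6L, 11),
                                      kappa = 200, seed = 3))))
}

# Two-protein, one-replicate wide-form profile file.
write_tiny_wide <- function(path) {
  df <- data.frame(protein_id = c("P1", "P2"), replicate = "rep1",
                   matrix(c(1:10, 10:1), nrow = 2, byrow = TRUE))
  colnames(df)[-(1:2)] <- paste0("fraction_", 1:10)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_tiny_long <- function(path) {
  df <- expand.grid(protein_id = c("P1", "P2"), fraction = 1:10,
                    stringsAsFactors = FALSE)
  df$replicate <- "rep1"
  df$abundance <- ifelse(df$protein_id == "P1", df$fraction,
                         11 - df$fraction)
  write.table(df[, c("protein_id", "replicate", "fraction", "abundance")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

rdirichlet_test <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

# ALR replicate blocks of one protein from a SpatialProfileMatrix.
alr_blocks <- function(spm, id) {
  t(vapply(spm$replicate_boundaries, function(cols) {
    alr_transform(spm$matrix[id, cols])
  }, numeric(spm$n_fractions - 1)))
}
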