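#' @keywords internal
"_PACKAGE"

#' @importFrom stats rgamma rnorm runif optim prcomp pt sd var median qnorm
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded to `seed`, then
#' restores the previous RNG state so that package functions never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit signed-integer range R requires.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}

os_log <- function(fmt, ...) {
  message(sprintf(paste0("[orgshift] ", fmt), ...))
}

stop_os <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "orgshift_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) stop_os(class, fmt, ...)
  invisible(TRUE)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  ifelse(x > 30, x, log1p(exp(x)))
}
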