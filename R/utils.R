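# Internal helpers shared across modules.

#' @keywords internal
mc_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "mircurate_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#' A `NULL` seed leaves the current stream in place.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Validate a 1-based closed interval on a precursor of length `n`.
check_interval <- function(x, n = NULL, what = "interval") {
  if (length(x) != 2L || anyNA(x) || x[1] > x[2] || x[1] < 1L)
    mc_stop("parameter_error", "%s must be c(start, end) with 1 <= start <= end", what)
  if (!is.null(n) && x[2] > n)
    mc_stop("parameter_error", "%s end (%d) exceeds precursor length (%d)", what, x[2], n)
  invisible(as.integer(x))
}

interval_width <- function(x) as.integer(x[2] - x[1] + 1L)

# RNA alphabet helpers
RNA_BASES <- c("A", "C", "G", "U")
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
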