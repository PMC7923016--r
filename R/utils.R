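# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Printed tables in breed-authentication reports conventionally round
#' half-up (0.0645 -> 0.065), unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Run expr with a locally seeded RNG, restoring global RNG state afterwards.
# Keeps simulation calls free of global side effects.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a single integer `seed` is required", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Locale-independent (C byte order) sort, so GENEPOP allele codes and
# canonical genotype keys are reproducible across systems.
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) stop(sprintf(...), call. = FALSE)
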