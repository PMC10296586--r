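# Shared internal helpers: error signalling with condition classes (the CLI
# maps these to exit codes) and seed-scoped RNG.

stop_invalid <- function(fmt, ...) {
  stop(structure(
    class = c("clocknets_invalid_parameter", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_data <- function(fmt, ...) {
  stop(structure(
    class = c("clocknets_data_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Deterministically expands one master seed into `n` independent sub-seeds,
#' used wherever a study runs many seeded simulations (batteries, scaling
#' studies, quench ensembles), so that every run is replayable from the single
#' master seed.
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x))
    stop_invalid("%s must be a single integer >= %s (got %s)", name, min,
                 paste(format(x), collapse = ","))
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x))
    stop_invalid("%s must be a single finite number", name)
  if (x < lower || x > upper || (strict_lower && x <= lower))
    stop_invalid("%s must be in %s%s, %s] (got %g)",
                 name, if (strict_lower) "(" else "[", lower, upper, x)
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
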