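# Internal helpers shared across modules.

# Deterministic fan-out of a master seed into per-stage seeds, so that adding
# or reordering one stage never perturbs the stream another stage sees.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
fan_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) %% 2147483647 + 7919 * stage) %% 2147483647)
}

# Run `expr` under a locally-set RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Named numeric of the three growth-curve parameters, in fixed order.
param_names <- function() c("a", "b", "c")

as_param_vec <- function(x, name) {
  x <- unlist(x)
  if (length(x) != 3L || !all(param_names() %in% names(x))) {
    abort(sprintf("`%s` must be a named length-3 vector with names a, b, c", name))
  }
  x[param_names()]
}
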