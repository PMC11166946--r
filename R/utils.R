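# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Stop with a consistent invalid-argument condition.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("spacefrail_invalid_argument", "error")))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_invalid(...)
  invisible(TRUE)
}

# Round half away from zero (printed percentages in the source data are
# half-up rounded; base round() is banker's rounding).
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators are pure in (params, seed).
with_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed that stays inside 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer(((abs(as.numeric(seed)) %% 100003) * 7919 + abs(as.numeric(i))) %% 2147483647)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
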