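
# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so library code never disturbs user
#' simulations.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with sprintf-style formatting and no call in the message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

is_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# log a progress line to stderr (the pipeline's only chatter channel)
log_msg <- function(fmt, ...) {
  message(sprintf(fmt, ...))
  invisible(NULL)
}
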