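# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Seed handling: functions that take an explicit `seed` must not disturb the
## caller's RNG stream, so the global seed is restored on exit.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_ctaei <- function(..., call. = FALSE) stop(..., call. = call.)

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

check_matrix_ids <- function(m, what) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_ctaei(what, " must have row and column names")
  if (anyDuplicated(rownames(m)))
    stop_ctaei("duplicated row ids in ", what)
  if (anyDuplicated(colnames(m)))
    stop_ctaei("duplicated column ids in ", what)
  invisible(m)
}
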