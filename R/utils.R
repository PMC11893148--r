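# internal helpers shared across pipeline stages

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf-style formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# median over finite values; NA if none
finite_median <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

#' @keywords internal
assert_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort("%s is missing required column(s): %s", where,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}

# run an expression with a locally-seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
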