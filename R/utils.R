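#' @keywords internal
"_PACKAGE"

# stop() with sprintf formatting; call. = FALSE keeps messages user-facing
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

# Run expr with a temporary RNG state; restores (or removes) .Random.seed after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Population (divide-by-N) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

zscore_pop <- function(x) {
  s <- sd_pop(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}
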