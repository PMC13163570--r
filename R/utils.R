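# internal helpers shared across modules

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# sample() without the length-1 surprise
sample_int <- function(n, size, replace = FALSE) {
  sample.int(n, size = size, replace = replace)
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# light I/O logging used by the readers/writers
log_io <- function(action, path, nrow, ncol) {
  message(sprintf("%s %s: %d rows x %d cols", action, path, nrow, ncol))
}
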