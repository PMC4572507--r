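# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Population standard deviation (the pairwise-distance arrays are the full
## population of unordered pairs, not a sample).
popSD <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

## sample() without the length-1 surprise
sampleVec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}

stopIfNot1String <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty string", call. = FALSE)
  invisible(x)
}
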