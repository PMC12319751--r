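# Seed plumbing: one top-level seed fans out into named substreams so that
# independent stages (scheduling, EMG, neural background, ICA init, k-means,
# permutations) draw from unrelated, reproducible streams.

#' Derive a named substream seed
#'
#' Deterministically maps a top-level integer seed and a stream name to a new
#' seed below `2^31`, so every stochastic stage of the pipeline can be
#' re-seeded independently and reproducibly.
#'
#' @param seed top-level integer seed
#' @param name substream name, e.g. `"schedule"`, `"emg"`, `"ica"`
#' @return a single integer seed
#' @export
substreamSeed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1999999973
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopIfNot <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}
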