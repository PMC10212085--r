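# Named RNG substreams built on L'Ecuyer-CMRG, so that each stochastic
# ingredient of a simulation (division noise, expression switching,
# measurement noise, cytometry replicates) draws from its own stream.
# Turning one noise source on or off then never perturbs the others, and a
# given (config, seed) pair is bit-reproducible.

#' Create named, independent RNG substreams from one root seed
#'
#' @param seed single integer root seed.
#' @param names character vector of stream names.
#' @return An object of class `rng_streams`; pass to [with_stream()].
#' @keywords internal
rng_streams <- function(seed, names) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(names) >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  env <- new.env(parent = emptyenv())
  for (nm in names) {
    s <- parallel::nextRNGStream(s)
    assign(nm, s, envir = env)
  }
  structure(list(env = env), class = "rng_streams")
}

#' Evaluate an expression with the RNG positioned on a named substream
#'
#' The stream state is advanced and saved back, and the caller's RNG state
#' is restored afterwards.
#'
#' @param streams an [rng_streams()] object.
#' @param name stream name.
#' @param expr expression performing random draws.
#' @keywords internal
with_stream <- function(streams, name, expr) {
  stopifnot(inherits(streams, "rng_streams"))
  if (!exists(name, envir = streams$env, inherits = FALSE))
    stop("unknown RNG stream: ", name)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", get(name, envir = streams$env), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = streams$env)
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
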