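# internal helpers shared across modules

#' Derive a per-generator RNG seed from a master seed and a stream name
#'
#' Each synthetic-data generator draws from its own stream so that adding a
#' generator (or reordering calls) never perturbs another generator's output.
#' The stream seed is a deterministic 31-bit hash of (seed, name).
#'
#' @param seed master integer seed
#' @param name generator name, e.g. "tpp"
#' @return integer seed suitable for [set.seed()]
#' @keywords internal
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(name)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate code under a generator-specific RNG stream, restoring RNG state
#' @keywords internal
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  expr
}

# scalar positivity check with a readable error
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
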