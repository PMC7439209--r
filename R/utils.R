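#' Internal input-validation helpers
#'
#' Small wrappers so every module raises classed conditions that tests can
#' match on.
#'
#' @name hemimorph-conditions
#' @keywords internal
NULL

stop_config <- function(msg, ...) {
  abort(msg, class = "hemimorph_config_error", ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = "hemimorph_parse_error", ...)
}

stop_input <- function(msg, ...) {
  abort(msg, class = "hemimorph_input_error", ...)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Derive a stage seed from a global seed
#'
#' Deterministic, collision-avoiding derivation of per-stage / per-subject
#' seeds from one user-facing seed. Kept below `2^31` so the result is a
#' valid R integer seed.
#'
#' @param seed integer global seed.
#' @param ... integer offsets identifying the stage (and, optionally, the
#'   subject index within the stage).
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  offs <- c(...)
  x <- as.double(seed) %% 2147483629
  for (o in offs) {
    # linear congruential mix per offset; stays in [0, 2^31 - 19)
    x <- (x * 48271 + as.double(o) + 1) %% 2147483629
  }
  as.integer(x)
}

# Run code under a locally-set RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
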