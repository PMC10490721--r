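# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never
#' perturbs the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-item seed from a master seed
#'
#' Deterministic stream splitting: item i of a run seeded with `master`
#' always receives the same sub-seed, and sub-seeds stay below 2^31.
#'
#' @param master integer master seed.
#' @param i item index (>= 1).
#' @return integer seed.
#' @keywords internal
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 16807) %% 2147483587)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# dB <-> linear power helpers
db_to_pow <- function(db) 10^(db / 10)
pow_to_db <- function(p) 10 * log10(p)

signal_energy <- function(x) sum(as.double(x)^2)
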