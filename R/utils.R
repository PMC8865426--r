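#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current global RNG state, seeds the generator, evaluates the
#' expression, and restores the previous state, so that every randomized
#' function in the package is a pure function of its `seed` argument and
#' never disturbs the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive `n` reproducible sub-seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @keywords internal
snmtf_log <- function(..., verbose = getOption("snmtf.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  }
  invisible(NULL)
}

# Shared guard against division by exact zero in multiplicative updates.
.DENOM_GUARD <- 1e-12

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max ||
      (integer && x != floor(x))) {
    stop(sprintf("`%s` must be a single %s in [%s, %s]", name,
                 if (integer) "integer" else "number",
                 format(min), format(max)), call. = FALSE)
  }
  invisible(TRUE)
}
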