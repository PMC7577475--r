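# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the R RNG with `seed`, evaluates `expr`, and restores the previous
#' global RNG state so that seeded package functions do not perturb the
#' caller's random stream.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 65536) * 31627 + index * 7919) %% 2147483629L
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_odd_k <- function(k) {
  stop_if_not_scalar_number(k, "k")
  if (k != as.integer(k) || k < 3 || k %% 2 == 0) {
    stop("window size `k` must be an odd integer >= 3", call. = FALSE)
  }
  as.integer(k)
}
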