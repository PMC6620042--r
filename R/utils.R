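# Shared internal helpers: seeded RNG hygiene, Fisher z, seed fan-out.

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Deterministic sub-seed derivation: a master seed plus a small integer
# offset and an optional character tag yield a reproducible child seed
# below 2^31 (R integers are 32-bit).
spawn_seed <- function(seed, offset = 0L, tag = "") {
  h <- 0
  if (nzchar(tag)) {
    for (cc in utf8ToInt(tag)) h <- (h * 31 + cc) %% 1000003
  }
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(offset) + h) %%
    2147483629)
}

#' Fisher z transform with clamping
#'
#' Transforms Pearson correlations to the Fisher z scale. Correlations are
#' clamped to +/-(1 - 1e-12) first so that numerically perfect correlations
#' map to a large finite value (about 13.8) rather than infinity.
#'
#' @param r numeric vector or matrix of correlations.
#' @return `atanh` of the clamped input, same shape as `r`.
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-12
  atanh(pmin(pmax(r, -lim), lim))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
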