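# Internal helpers: seeded evaluation and substream derivation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so seeded generators never perturb user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# Derive a deterministic substream seed from a base seed and a stream index,
# kept inside 32-bit integer range.  Substreams decouple independent draws
# (e.g. per-residue noise) so enlarging one stream does not perturb others.
substream <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(index)) %%
               2147483647)
}

# Shared argument checks -------------------------------------------------

stopifnot_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
}

stopifnot_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and positive", name), call. = FALSE)
  }
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
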