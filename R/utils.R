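#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed, fully specified RNG state, restoring the caller's
# state afterwards. Fixing all three RNG kinds keeps simulations bit-identical
# across platforms and R sessions.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kinds <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kinds))
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Derive a stream-specific child seed from a master seed, kept below 2^31.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + stream) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) sprintf("%.12g", x)
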