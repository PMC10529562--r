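# Run expr under a temporary RNG state; the caller's .Random.seed is restored.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
deriveSeed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 1299721) %% 2147483647
}

#' Format a proportion as a percentage string
#'
#' Machine-readable outputs keep full precision; printed tables use a fixed
#' number of decimals, e.g. `formatPercent(77189/77501, 3)` gives "99.597".
#'
#' @param x Proportion in [0, 1].
#' @param digits Decimal places.
#' @return Character scalar, percent value without the "%" sign.
#' @export
formatPercent <- function(x, digits = 2) {
  formatC(round(100 * x, digits), format = "f", digits = digits)
}
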