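#' @keywords internal
"_PACKAGE"

# Contrast-enhancement phase labels, in acquisition order.
PHASES <- c("NCE", "E-AP", "L-AP", "PVP")

#' Round half away from zero
#'
#' Report tables use conventional half-up rounding (2.5 -> 3), not the
#' banker's rounding of [base::round()]. A small epsilon guards against
#' binary representation error at the .5 boundary.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.5)      # 3, where round(2.5) gives 2
#' round_half_up(46.742)   # 47
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-stream seed from a base seed and stream indices.
# Multipliers are distinct primes so (lesion, reader, timepoint) streams do
# not collide; result kept inside the 32-bit integer range.
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- (as.double(base) + sum(c(7919, 104729, 1299709, 15485863)[seq_along(idx)] * idx)) %%
    2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cect <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# quiet R CMD check notes for ggplot2 NSE column references
utils::globalVariables(c("rank", "max_percent_change", "percent_difference"))
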