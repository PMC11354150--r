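#' Round half away from zero
#'
#' Rounding used for display and for inverting published rounded tables.
#' Base `round()` rounds half to even; published association tables
#' conventionally round half away from zero, so ties like 0.045 print as
#' 0.05 rather than 0.04.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-away-from-zero at `digits` places.
#' @export
#' @examples
#' round_half_away(0.125, 2)  # 0.13, where round(0.125, 2) gives 0.12
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  # small epsilon guards against values like 0.575 stored as 0.57499...96
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Evaluate `expr` under a locally seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_data <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
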