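`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic stream-splitting used throughout the package so that every
#' randomized stage (per-split ranking, per-replicate curve simulation,
#' bootstrap resampling) gets its own reproducible seed from one master seed.
#' The scheme is a fixed linear congruence modulo 2^31 - 1, so child seeds
#' always fit in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  as.integer((as.double(master) %% 2147483647 * 48271 +
                104729 * as.double(index)) %% 2147483647)
}

# cumulative trapezoidal integral of y over x, anchored at 0
cumtrapz_ <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# coefficient of determination that tolerates a zero-variance response
r_squared_ <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= .Machine$double.eps) {
    return(if (ss_res <= .Machine$double.eps) 1 else 0)
  }
  max(0, min(1, 1 - ss_res / ss_tot))
}
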