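#' Normalize raw detector counts to fraction of administered dose
#'
#' `activity(t) = raw(t) / efficiency / administered`; the exact inverse of
#' the simulator's detector stage ([detector_counts()]).
#'
#' @param raw_counts detector counts per sample.
#' @param efficiency detector efficiency, in (0, 1] (calibration; about 0.03
#'   for the rotating-dish beta detector emulated here).
#' @param administered administered dose in the same count-equivalent units.
#' @param time_min sampling times in minutes (default one per minute from 0).
#' @param meta optional metadata list attached to the curve.
#' @return A `tac` object.
#' @export
normalize_counts <- function(raw_counts, efficiency, administered,
                             time_min = seq_along(raw_counts) - 1,
                             meta = list()) {
  if (efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must be in (0, 1]", call. = FALSE)
  }
  if (administered <= 0) stop("`administered` must be > 0", call. = FALSE)
  meta$detector_efficiency <- meta$detector_efficiency %||% efficiency
  as_tac(time_min, raw_counts / efficiency / administered, meta)
}

#' Patlak linearization of an irreversible-uptake curve
#'
#' Closed-system Patlak transform: with `medium(t) = 1 - activity(t)` (dose
#' conservation in fraction-of-dose units), plots normalized uptake
#' `y(t) = activity(t) / medium(t)` against normalized integrated exposure
#' `x(t) = integral_0^t medium ds / medium(t)` (trapezoidal cumulative
#' integration at the native sampling).  Irreversible accumulation at rate
#' `a` makes these points fall on a line of slope `a`.
#'
#' @param curve a `tac` object with all activities < 1.
#' @return A data frame with columns `time_min`, `x`, `y`.
#' @export
patlak_transform <- function(curve) {
  stopifnot(inherits(curve, "tac"))
  medium <- 1 - curve$activity
  if (any(medium <= 0)) {
    stop("medium activity must stay positive (activity < 1 everywhere)",
         call. = FALSE)
  }
  x <- cumtrapz_(curve$time_min, medium) / medium
  y <- curve$activity / medium
  data.frame(time_min = curve$time_min, x = x, y = y)
}

#' Fit the Patlak regression line
#'
#' Ordinary least squares of the Patlak-transformed points from `t_start`
#' onward.  The slope is the tracer accumulation rate constant `a` (per min);
#' multiplied by the medium glucose concentration it estimates the glucose
#' consumption of the culture.
#'
#' @param curve a `tac` object.
#' @param t_start first time (min) included in the regression; the default 0
#'   uses the whole curve, appropriate for the closed-system model which is
#'   linear from the start at these uptake magnitudes.
#' @return A `patlak_fit`: `slope_a` (per min), `intercept_b`, `r_squared`,
#'   `glucose_consumption` (mM per min, using the curve's `glucose_mM`
#'   metadata, default 5.5).
#' @export
patlak_fit <- function(curve, t_start = 0) {
  tf <- patlak_transform(curve)
  tf <- tf[tf$time_min >= t_start, , drop = FALSE]
  if (nrow(tf) < 3L) stop("need at least 3 points after `t_start`", call. = FALSE)
  if (stats::var(tf$x) == 0) stop("degenerate Patlak abscissa", call. = FALSE)
  fit <- stats::lm(y ~ x, data = tf)
  slope <- unname(stats::coef(fit)[2L])
  glucose <- attr(curve, "meta")$glucose_mM %||% 5.5
  structure(list(slope_a = slope,
                 intercept_b = unname(stats::coef(fit)[1L]),
                 r_squared = r_squared_(tf$y, stats::fitted(fit)),
                 glucose_consumption = slope * glucose),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("Patlak fit: slope a = %.4g /min, intercept b = %.4g, R2 = %.4f\n",
              x$slope_a, x$intercept_b, x$r_squared))
  invisible(x)
}

#' One-phase association fit of a saturable-binding curve
#'
#' Bounded Levenberg-Marquardt least squares of
#' `A(t) = amax * (1 - exp(-k t))`, the standard receptor-ligand association
#' model: `amax` reflects the number of accessible binding sites (fraction of
#' administered dose at plateau) and `k` the association rate constant.
#' Starting values come from the curve geometry (`amax0` = mean of the last
#' samples, `k0` from the half-rise time); bounds `amax` in `[0, 1]`,
#' `k` in `(0, 10]` per min keep the exponent from diverging.
#'
#' @param curve a `tac` object with at least 4 samples.
#' @return A `one_phase_fit`: `amax`, `k`, `r_squared`.
#' @export
one_phase_fit <- function(curve) {
  stopifnot(inherits(curve, "tac"))
  t <- curve$time_min
  a <- curve$activity
  if (length(t) < 4L) stop("need at least 4 points", call. = FALSE)
  if (any(a < 0)) stop("`activity` must be non-negative", call. = FALSE)
  d <- diff(a)
  if (all(d <= 0) && any(d < 0)) {
    stop("curve is monotone decreasing; not a saturable association",
         call. = FALSE)
  }
  tail_n <- max(3L, ceiling(length(a) / 10))
  amax0 <- max(mean(utils::tail(a, tail_n)), max(a) * 0.5, 1e-12)
  half_idx <- which(a >= amax0 / 2)
  t_half <- if (length(half_idx) && t[half_idx[1L]] > 0) t[half_idx[1L]]
            else max(t) / 4
  k0 <- min(max(log(2) / t_half, 1e-6), 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ amax * (1 - exp(-k * t)),
      start = list(amax = min(amax0, 1), k = k0),
      lower = c(0, 1e-9), upper = c(1, 10),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 500L)
    ),
    error = function(e) stop("one-phase fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- stats::coef(fit)
  structure(list(amax = unname(est["amax"]),
                 k = unname(est["k"]),
                 r_squared = r_squared_(a, stats::fitted(fit))),
            class = "one_phase_fit")
}

#' @export
print.one_phase_fit <- function(x, ...) {
  cat(sprintf("one-phase association: Amax = %.4g (fraction of dose), k = %.4g /min, R2 = %.4f\n",
              x$amax, x$k, x$r_squared))
  invisible(x)
}

#' Compare a kinetic parameter between two replicate groups
#'
#' @param fits_group1,fits_group2 lists of kinetic fit objects
#'   (`patlak_fit` or `one_phase_fit`), at least 2 per group.
#' @param parameter name of the parameter to compare (e.g. `"amax"`, `"k"`,
#'   `"slope_a"`).
#' @return A `kinetic_comparison`: parameter name, per-group `mean` and `sd`,
#'   `fold_change` (group1 / group2), Welch t-test `p`.  Identical constant
#'   groups give p = 1; distinct constant groups are flagged with p = 0.
#' @export
compare_kinetics <- function(fits_group1, fits_group2, parameter) {
  if (length(fits_group1) < 2L || length(fits_group2) < 2L) {
    stop("need at least 2 fits per group", call. = FALSE)
  }
  pull <- function(fits) vapply(fits, function(f) {
    v <- f[[parameter]]
    if (is.null(v)) stop("fits carry no parameter `", parameter, "`",
                         call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  v1 <- pull(fits_group1)
  v2 <- pull(fits_group2)
  if (mean(v2) == 0) stop("zero group-2 mean: fold change undefined",
                          call. = FALSE)
  if (stats::var(v1) == 0 && stats::var(v2) == 0) {
    p <- if (mean(v1) == mean(v2)) 1 else 0
    flag <- if (p == 0) "constant groups: p below reportable floor" else NULL
  } else {
    p <- stats::t.test(v1, v2)$p.value
    flag <- NULL
  }
  structure(list(parameter = parameter,
                 mean1 = mean(v1), sd1 = stats::sd(v1),
                 mean2 = mean(v2), sd2 = stats::sd(v2),
                 fold_change = mean(v1) / mean(v2),
                 p = p, flag = flag),
            class = "kinetic_comparison")
}

#' @export
print.kinetic_comparison <- function(x, ...) {
  cat(sprintf("%s: %.4g ± %.4g vs %.4g ± %.4g (fold change %.3g, p = %.3g)\n",
              x$parameter, x$mean1, x$sd1, x$mean2, x$sd2,
              x$fold_change, x$p))
  if (!is.null(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}
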