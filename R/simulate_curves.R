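#' Tracer presets for the time-activity curve simulators
#'
#' Kinetic parameters of the four built-in presets emulating low-passage
#' (LNCaP-30) and high-passage (LNCaP-80) prostate cancer cultures measured
#' in a rotating-dish beta detector:
#' FDG presets use an irreversible accumulation rate `a` (per min);
#' PSMA presets use a one-phase association with plateau `amax`
#' (fraction of dose) and association constant `k` (per min).  The PSMA
#' presets are chosen so that LNCaP-30 vs LNCaP-80 differ 15-fold in `amax`
#' and 5-fold in `k`, while uptake stays far below the administered dose and
#' plateaus within the 120-min acquisition.
#'
#' @return A named list of parameter lists.
#' @export
tracer_presets <- function() {
  list(
    `FDG-LNCaP30`  = list(tracer = "FDG",  cell_model = "LNCaP-30",
                          accumulation_rate_a = 1.4e-7),
    `FDG-LNCaP80`  = list(tracer = "FDG",  cell_model = "LNCaP-80",
                          accumulation_rate_a = 2.7e-7),
    `PSMA-LNCaP30` = list(tracer = "PSMA", cell_model = "LNCaP-30",
                          amax = 0.045, k = 0.040),
    `PSMA-LNCaP80` = list(tracer = "PSMA", cell_model = "LNCaP-80",
                          amax = 0.003, k = 0.008)
  )
}

#' Configuration for the time-activity curve simulators
#'
#' @param preset one of `"FDG-LNCaP30"`, `"FDG-LNCaP80"`, `"PSMA-LNCaP30"`,
#'   `"PSMA-LNCaP80"` or `"custom"`.  Presets fill in the kinetic parameters;
#'   explicitly supplied parameters override them.
#' @param duration acquisition length in minutes.
#' @param sampling sampling interval in minutes; `duration / sampling` must be
#'   integral.
#' @param accumulation_rate_a irreversible accumulation rate (per min), FDG
#'   forward model.
#' @param amax plateau uptake as a fraction of the administered dose (<= 1),
#'   PSMA forward model.
#' @param k association rate constant (per min), PSMA forward model.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise applied per sample (default 1%).
#' @param detector_efficiency fraction of source emission recovered by the
#'   detector (default 0.03, i.e. 3%).
#' @param glucose_mM medium glucose concentration (mM), carried as metadata
#'   for the Patlak glucose-consumption readout.
#' @param volume_ml medium volume (mL), metadata only.
#' @param seed integer seed for the measurement noise.
#' @return An object of class `tracer_sim_config`.
#' @export
tracer_sim_config <- function(preset = "custom",
                              duration = 120,
                              sampling = 1,
                              accumulation_rate_a = NULL,
                              amax = NULL,
                              k = NULL,
                              noise_cv = 0.01,
                              detector_efficiency = 0.03,
                              glucose_mM = 5.5,
                              volume_ml = 3,
                              seed = 1L) {
  presets <- tracer_presets()
  preset <- match.arg(preset, c("custom", names(presets)))
  tracer <- NA_character_
  cell_model <- NA_character_
  if (preset != "custom") {
    pp <- presets[[preset]]
    tracer <- pp$tracer
    cell_model <- pp$cell_model
    accumulation_rate_a <- accumulation_rate_a %||% pp$accumulation_rate_a
    amax <- amax %||% pp$amax
    k <- k %||% pp$k
  }
  if (duration <= 0 || sampling <= 0 ||
      abs(duration / sampling - round(duration / sampling)) > 1e-9) {
    stop("`duration` must be a positive integral multiple of `sampling`",
         call. = FALSE)
  }
  if (!is.null(accumulation_rate_a) && accumulation_rate_a < 0) {
    stop("`accumulation_rate_a` must be >= 0", call. = FALSE)
  }
  if (!is.null(amax) && (amax < 0 || amax > 1)) {
    stop("`amax` must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(k) && k < 0) stop("`k` must be >= 0", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (detector_efficiency <= 0 || detector_efficiency > 1) {
    stop("`detector_efficiency` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(preset = preset, tracer = tracer, cell_model = cell_model,
         duration = duration, sampling = sampling,
         accumulation_rate_a = accumulation_rate_a,
         amax = amax, k = k,
         noise_cv = noise_cv,
         detector_efficiency = detector_efficiency,
         glucose_mM = glucose_mM, volume_ml = volume_ml,
         seed = as.integer(seed)),
    class = "tracer_sim_config"
  )
}

# construct a time-activity curve object
as_tac <- function(time_min, activity, meta = list()) {
  stopifnot(length(time_min) == length(activity))
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("`time_min` must be strictly increasing", call. = FALSE)
  }
  if (any(activity < 0) || any(activity > 1)) {
    stop("`activity` must lie in [0, 1] (fraction of administered dose)",
         call. = FALSE)
  }
  structure(
    data.frame(time_min = time_min, activity = activity),
    meta = meta,
    class = c("tac", "data.frame")
  )
}

#' @export
print.tac <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("time-activity curve: %d samples over %g min (%s, %s)\n",
              nrow(x), max(x$time_min),
              m$tracer %||% "tracer?", m$cell_model %||% "model?"))
  invisible(x)
}

tac_noise_ <- function(clean, noise_cv, seed) {
  if (noise_cv == 0) return(clean)
  set.seed(seed)
  pmax(0, clean * (1 + stats::rnorm(length(clean), 0, noise_cv)))
}

tac_meta_ <- function(config, extra = list()) {
  utils::modifyList(
    list(tracer = config$tracer, cell_model = config$cell_model,
         preset = config$preset,
         detector_efficiency = config$detector_efficiency,
         glucose_mM = config$glucose_mM, volume_ml = config$volume_ml,
         noise_cv = config$noise_cv, seed = config$seed),
    extra
  )
}

#' Simulate an FDG-like irreversible-uptake time-activity curve
#'
#' Closed-system mass balance for an irreversibly trapped tracer in a dish:
#' `d cells/dt = a * medium(t)` with `medium(t) = 1 - cells(t)` in
#' fraction-of-dose units, i.e. `cells(t) = 1 - exp(-a t)`.  Dose is conserved
#' exactly before measurement noise; multiplicative Gaussian noise of CV
#' `noise_cv` is then applied per sample.
#'
#' @param config a [tracer_sim_config()] with `accumulation_rate_a` set
#'   (directly or via an FDG preset).
#' @return A `tac` object: data frame `time_min`, `activity` with a `meta`
#'   attribute carrying the assay metadata and generating parameters.
#' @examples
#' curve <- simulate_fdg_curve(tracer_sim_config("FDG-LNCaP30", seed = 1))
#' tail(curve, 2)
#' @export
simulate_fdg_curve <- function(config) {
  stopifnot(inherits(config, "tracer_sim_config"))
  a <- config$accumulation_rate_a
  if (is.null(a)) stop("`accumulation_rate_a` is not set", call. = FALSE)
  if (a < 0) stop("`accumulation_rate_a` must be >= 0", call. = FALSE)
  t <- seq(0, config$duration, by = config$sampling)
  clean <- -expm1(-a * t)
  activity <- tac_noise_(clean, config$noise_cv, config$seed)
  as_tac(t, activity,
         tac_meta_(config, list(tracer = config$tracer %||% "FDG",
                                accumulation_rate_a = a)))
}

#' Simulate a PSMA-like saturable-binding time-activity curve
#'
#' One-phase association kinetics `A(t) = amax * (1 - exp(-k t))` sampled per
#' minute, with multiplicative Gaussian measurement noise of CV `noise_cv`.
#'
#' @param config a [tracer_sim_config()] with `amax` and `k` set (directly or
#'   via a PSMA preset).
#' @return A `tac` object.
#' @export
simulate_psma_curve <- function(config) {
  stopifnot(inherits(config, "tracer_sim_config"))
  amax <- config$amax
  k <- config$k
  if (is.null(amax) || is.null(k)) stop("`amax` and `k` must be set", call. = FALSE)
  if (amax > 1) stop("`amax` must be <= 1 (fraction of dose)", call. = FALSE)
  t <- seq(0, config$duration, by = config$sampling)
  clean <- amax * -expm1(-k * t)
  activity <- tac_noise_(clean, config$noise_cv, config$seed)
  as_tac(t, activity, tac_meta_(config, list(tracer = config$tracer %||% "PSMA",
                                             amax = amax, k = k)))
}

#' Convert a time-activity curve to raw detector counts
#'
#' Forward detector stage: `counts(t) = activity(t) * efficiency *
#' administered`.  [normalize_counts()] is its exact inverse.
#'
#' @param curve a `tac` object.
#' @param administered administered dose in detector count-equivalents.
#' @param efficiency detector efficiency; defaults to the curve's metadata
#'   (0.03 if absent).
#' @return Numeric vector of counts per sample.
#' @export
detector_counts <- function(curve, administered, efficiency = NULL) {
  stopifnot(inherits(curve, "tac"), administered > 0)
  eff <- efficiency %||% attr(curve, "meta")$detector_efficiency %||% 0.03
  curve$activity * eff * administered
}
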