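#' Configuration for the synthetic survival cohort simulator
#'
#' Describes a patient-by-gene cohort of standardized (z-score) expression
#' values with a progression-free survival (PFS) outcome generated from a
#' proportional-hazards model.  Defaults emulate a primary prostate cancer
#' cohort of 493 patients and 122 glucose-metabolism / PSMA-related genes
#' with an overall progression rate near 18.9%, and plant four prognostic
#' genes (PARP2, SLC2A4, CTH, ALDOB) at their bootstrap-stabilized
#' multivariable log-hazard weights, plus FOLH1 as a null gene.
#'
#' @param n_patients number of patients.
#' @param n_genes number of gene columns (>= number of causal genes).
#' @param causal_effects named numeric vector of log-hazard per z-unit for
#'   the planted prognostic genes; genes with effect 0 are generated but carry
#'   no signal.
#' @param baseline_hazard baseline event rate per month (exponential
#'   baseline).
#' @param censoring_window upper bound (months) of the uniform administrative
#'   censoring distribution.  When `NULL` (default) it is calibrated once by
#'   bisection so that the expected event rate equals `target_event_rate`
#'   (see [calibrate_censoring_window()]).
#' @param target_event_rate expected fraction of patients with an observed
#'   progression event; used only when `censoring_window` is `NULL`.
#' @param clinical_effects optional named numeric vector of log-hazards for
#'   standard-normal clinical covariates added to the table.
#' @param correlation pairwise equi-correlation of gene z-scores, in `[0, 1)`.
#' @param gene_names optional character vector of length `n_genes`; must
#'   contain every name in `causal_effects`.  By default causal genes keep
#'   their names and filler genes are named `G001`, `G002`, ...
#' @param seed integer seed; the simulation is fully deterministic given the
#'   configuration.
#' @return An object of class `cohort_sim_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_sim_config <- function(n_patients = 493L,
                              n_genes = 122L,
                              causal_effects = c(PARP2 = 0.254, SLC2A4 = -0.733,
                                                 CTH = -0.372, ALDOB = 0.140,
                                                 FOLH1 = 0),
                              baseline_hazard = 0.002,
                              censoring_window = NULL,
                              target_event_rate = 0.189,
                              clinical_effects = NULL,
                              correlation = 0,
                              gene_names = NULL,
                              seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("`n_patients` must be a positive count", call. = FALSE)
  }
  if (length(causal_effects) &&
      (is.null(names(causal_effects)) || anyDuplicated(names(causal_effects)) ||
       any(!nzchar(names(causal_effects))))) {
    stop("`causal_effects` must have unique non-empty names", call. = FALSE)
  }
  if (n_genes < length(causal_effects)) {
    stop("`n_genes` must be at least the number of causal genes", call. = FALSE)
  }
  if (baseline_hazard <= 0) stop("`baseline_hazard` must be > 0", call. = FALSE)
  if (!is.null(censoring_window) && censoring_window <= 0) {
    stop("`censoring_window` must be > 0", call. = FALSE)
  }
  if (correlation < 0 || correlation >= 1) {
    stop("`correlation` must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(clinical_effects) && is.null(names(clinical_effects))) {
    stop("`clinical_effects` must be named", call. = FALSE)
  }
  if (is.null(gene_names)) {
    filler <- sprintf("G%03d", seq_len(n_genes))
    filler <- setdiff(filler, names(causal_effects))
    gene_names <- c(names(causal_effects),
                    filler[seq_len(n_genes - length(causal_effects))])
  } else {
    if (length(gene_names) != n_genes || anyDuplicated(gene_names)) {
      stop("`gene_names` must be ", n_genes, " unique names", call. = FALSE)
    }
    missing <- setdiff(names(causal_effects), gene_names)
    if (length(missing)) {
      stop("unknown gene in `causal_effects`: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  beta <- causal_effects
  gamma <- clinical_effects %||% stats::setNames(numeric(0), character(0))
  # Var of the linear predictor under equi-correlated z and independent
  # standard-normal clinical covariates.
  lp_var <- (1 - correlation) * sum(beta^2) + correlation * sum(beta)^2 +
    sum(gamma^2)
  if (is.null(censoring_window)) {
    censoring_window <- calibrate_censoring_window(
      baseline_hazard = baseline_hazard,
      lp_sd = sqrt(lp_var),
      target_event_rate = target_event_rate
    )
  }

  structure(
    list(n_patients = as.integer(n_patients),
         n_genes = as.integer(n_genes),
         causal_effects = beta,
         baseline_hazard = baseline_hazard,
         censoring_window = censoring_window,
         target_event_rate = target_event_rate,
         clinical_effects = gamma,
         correlation = correlation,
         gene_names = gene_names,
         seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

#' Calibrate the administrative censoring window for a target event rate
#'
#' With an exponential event time of rate `h0 * exp(lp)`, `lp ~ N(0, lp_sd^2)`,
#' and uniform censoring on `(0, W]`, the expected event probability is
#' `E[1 - (1 - exp(-hW)) / (hW)]`.  This function solves for the `W` that
#' attains a target expected event rate by bisection; the expectation over the
#' linear predictor is computed by numerical quadrature, so the calibration is
#' deterministic.
#'
#' @param baseline_hazard baseline hazard per month.
#' @param lp_sd standard deviation of the linear predictor.
#' @param target_event_rate desired expected event fraction, in (0, 1).
#' @param tol absolute tolerance on the achieved expected rate.
#' @return The censoring window `W` in months.
#' @export
calibrate_censoring_window <- function(baseline_hazard, lp_sd,
                                       target_event_rate = 0.189,
                                       tol = 1e-10) {
  stopifnot(baseline_hazard > 0, lp_sd >= 0,
            target_event_rate > 0, target_event_rate < 1)
  rate_at <- function(W) {
    expected_event_rate_(W, baseline_hazard, lp_sd)
  }
  lo <- 0
  hi <- 1
  it <- 0L
  while (rate_at(hi) < target_event_rate) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 400L) stop("censoring calibration failed to bracket the target")
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < target_event_rate) lo <- mid else hi <- mid
    if (abs(rate_at(mid) - target_event_rate) < tol) break
  }
  (lo + hi) / 2
}

# P(event) for exponential time at hazard h censored uniformly on (0, W]
prob_event_ <- function(hW) {
  ifelse(hW < 1e-10, hW / 2, 1 + expm1(-hW) / hW)
}

expected_event_rate_ <- function(W, baseline_hazard, lp_sd) {
  if (lp_sd == 0) return(prob_event_(baseline_hazard * W))
  f <- function(u) stats::dnorm(u) * prob_event_(baseline_hazard * exp(lp_sd * u) * W)
  stats::integrate(f, -10, 10, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

#' Simulate a synthetic expression/survival cohort
#'
#' Draws standardized gene expression (equi-correlated standard normal
#' z-scores), optional clinical covariates, and a progression-free survival
#' outcome from an exponential proportional-hazards model with linear
#' predictor `sum(beta_g * z_g) + sum(gamma_c * x_c)`, censored uniformly on
#' `(0, censoring_window]`.
#'
#' @param config a [cohort_sim_config()] object.
#' @return A `cohort_table`: a data frame with columns `patient_id`,
#'   `time_months`, `event`, any clinical covariates, then one column per
#'   gene; attributes `genes`, `clinical` and `sim_config` record the layout
#'   and generating configuration.
#' @examples
#' cfg <- cohort_sim_config(n_patients = 60, n_genes = 10, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' mean(cohort$event)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_patients
  p <- config$n_genes
  genes <- config$gene_names
  set.seed(config$seed)

  z <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, genes))
  rho <- config$correlation
  if (rho > 0) {
    shared <- stats::rnorm(n)
    z <- sqrt(rho) * shared + sqrt(1 - rho) * z
  }

  gamma <- config$clinical_effects
  clin <- NULL
  if (length(gamma)) {
    clin <- matrix(stats::rnorm(n * length(gamma)), n, length(gamma),
                   dimnames = list(NULL, names(gamma)))
  }

  beta <- config$causal_effects
  lp <- numeric(n)
  if (length(beta)) lp <- lp + drop(z[, names(beta), drop = FALSE] %*% beta)
  if (length(gamma)) lp <- lp + drop(clin %*% gamma)

  hazard <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::runif(n, 0, config$censoring_window)

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    time_months = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )
  if (length(gamma)) cohort <- cbind(cohort, as.data.frame(clin))
  cohort <- cbind(cohort, as.data.frame(z))

  structure(cohort,
            genes = genes,
            clinical = names(gamma),
            sim_config = config,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d patients, %d genes, %d clinical covariates\n",
              nrow(x), length(attr(x, "genes")),
              length(attr(x, "clinical") %||% character(0))))
  cat(sprintf("  events: %d (%.1f%%)\n", sum(x$event),
              100 * mean(x$event)))
  invisible(x)
}

# gene columns of a cohort table (attribute if present, else everything
# outside the reserved clinical set)
cohort_genes_ <- function(cohort) {
  g <- attr(cohort, "genes")
  if (!is.null(g)) return(g)
  setdiff(names(cohort), reserved_cohort_columns_())
}

reserved_cohort_columns_ <- function() {
  c("patient_id", "time_months", "event",
    "age", "race", "histology", "t_status", "n_status")
}
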