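#' Wald-type derived quantities for a log-hazard coefficient
#'
#' `hr = exp(beta)`, `ci95 = exp(beta -/+ 1.96 * se)`, and a two-sided normal
#' (Wald) p-value for `beta / se`.  Vectorized over features.
#'
#' @param beta log-hazard coefficient(s).
#' @param se standard error(s), >= 0.
#' @return A list with `hr`, `ci_lower`, `ci_upper`, `p`.  A zero `se` with a
#'   non-zero `beta` yields `p = 0` and is flagged with a warning.
#' @examples
#' derive_hr(-0.733, 0.244)  # HR 0.48, 95% CI 0.30-0.78
#' @export
derive_hr <- function(beta, se) {
  if (any(se < 0)) stop("`se` must be >= 0", call. = FALSE)
  z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  if (any(se == 0 & beta != 0)) {
    warning("zero standard error with non-zero coefficient: p-value set to 0")
  }
  list(hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)))
}

new_cox_model_ <- function(features, beta, se, n_boot = 0L,
                           cindex_apparent = NA_real_,
                           cindex_corrected = NA_real_,
                           ties = "breslow", extra = list()) {
  d <- derive_hr(beta, se)
  structure(
    c(list(features = features,
           beta = stats::setNames(beta, features),
           se = stats::setNames(se, features),
           hr = stats::setNames(d$hr, features),
           ci95 = cbind(lower = d$ci_lower, upper = d$ci_upper),
           p = stats::setNames(d$p, features),
           cindex_apparent = cindex_apparent,
           cindex_corrected = cindex_corrected,
           n_boot = as.integer(n_boot),
           ties = ties),
      extra),
    class = "cox_model"
  )
}

#' @export
print.cox_model <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards model (%s ties%s)\n", x$ties,
              if (x$n_boot > 0) sprintf(", %d bootstrap replications", x$n_boot)
              else ""))
  tab <- data.frame(beta = x$beta, se = x$se, HR = x$hr,
                    ci_lower = x$ci95[, "lower"], ci_upper = x$ci95[, "upper"],
                    p = x$p, row.names = x$features)
  print(round(tab, digits))
  if (!is.na(x$cindex_apparent)) {
    cat(sprintf("Harrell's c-index: %.3f", x$cindex_apparent))
    if (!is.na(x$cindex_corrected)) {
      cat(sprintf(" (%.3f corrected for optimism)", x$cindex_corrected))
    }
    cat("\n")
  }
  invisible(x)
}

cox_check_features_ <- function(cohort, features) {
  missing <- setdiff(features, names(cohort))
  if (length(missing)) {
    stop("features not present in cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (sum(cohort$event) < 1) stop("cohort has no events", call. = FALSE)
  const <- features[vapply(cohort[features],
                           function(v) stats::var(as.numeric(v)) == 0,
                           logical(1))]
  if (length(const)) {
    stop("constant covariate(s) make the information matrix singular: ",
         paste(const, collapse = ", "), call. = FALSE)
  }
}

#' Fit a multivariable Cox proportional-hazards model
#'
#' Partial-likelihood fit (Breslow tie handling by default, Efron available)
#' of `Surv(time_months, event)` on the given feature columns, through
#' \pkg{survival}.  Standard errors come from the inverse observed
#' information.
#'
#' @param cohort a `cohort_table` with `time_months` and `event`.
#' @param features character vector of covariate columns (genes and/or
#'   clinical variables).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol convergence tolerance passed to the fitter.
#' @return A `cox_model` with per-feature `beta`, `se`, `hr`, `ci95`, Wald
#'   `p`, and the apparent Harrell's c-index of the linear predictor.
#' @export
fit_cox <- function(cohort, features, ties = c("breslow", "efron"),
                    tol = 1e-9) {
  ties <- match.arg(ties)
  cox_check_features_(cohort, features)
  dat <- data.frame(.time = cohort$time_months, .event = cohort$event,
                    cohort[features], check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", features), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(eps = tol,
                                                           iter.max = 100L))
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  if (any(!is.finite(beta)) || any(!is.finite(se))) {
    stop("Cox fit did not converge or the information matrix is singular",
         call. = FALSE)
  }
  lp <- drop(as.matrix(cohort[features]) %*% beta)
  new_cox_model_(features, beta, se, ties = ties,
                 cindex_apparent = concordance_index(lp, cohort$time_months,
                                                     cohort$event),
                 extra = list(loglik = fit$loglik))
}

#' Bootstrap-stabilized Cox coefficients
#'
#' Resamples patients with replacement `B` times, refits the multivariable
#' Cox model on each resample, and reports the mean bootstrap coefficient as
#' the stabilized estimate with the bootstrap standard deviation as its
#' standard error.  Hazard ratios, 95% CIs and Wald p-values are derived from
#' these via [derive_hr()].
#'
#' @param cohort a `cohort_table`.
#' @param features covariate columns.
#' @param B number of bootstrap replications (default 500).
#' @param seed integer seed for the resampling.
#' @param ties tie handling, as in [fit_cox()].
#' @return A `cox_model` with `n_boot = B`; the matrix of per-replicate
#'   coefficients is attached as `boot_beta`.  Fails if more than 20% of
#'   replicates do not converge.
#' @export
bootstrap_cox <- function(cohort, features, B = 500L, seed = 1L,
                          ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (B < 1) stop("`B` must be >= 1", call. = FALSE)
  full <- fit_cox(cohort, features, ties = ties)
  n <- nrow(cohort)
  boot <- matrix(NA_real_, B, length(features),
                 dimnames = list(NULL, features))
  set.seed(seed)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_b <- tryCatch(fit_cox(cohort[idx, , drop = FALSE], features,
                              ties = ties),
                      error = function(e) NULL)
    if (is.null(fit_b)) failed <- failed + 1L else boot[b, ] <- fit_b$beta
  }
  if (failed > 0.2 * B) {
    stop(sprintf("%d of %d bootstrap replicates failed to converge",
                 failed, B), call. = FALSE)
  }
  ok <- stats::complete.cases(boot)
  beta <- colMeans(boot[ok, , drop = FALSE])
  se <- apply(boot[ok, , drop = FALSE], 2, stats::sd)
  if (sum(ok) == 1L) se <- rep(0, length(beta))
  lp <- drop(as.matrix(cohort[features]) %*% beta)
  new_cox_model_(features, unname(beta), unname(se), n_boot = B, ties = ties,
                 cindex_apparent = concordance_index(lp, cohort$time_months,
                                                     cohort$event),
                 extra = list(boot_beta = boot[ok, , drop = FALSE],
                              n_failed = failed, seed = as.integer(seed)))
}
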