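#' Kaplan-Meier product-limit estimate per group
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @param group optional grouping vector; a single curve is returned when
#'   omitted.
#' @return A named list of `km_curve` objects, one per group, each with
#'   `event_times` (all observed times), `survival`, `at_risk`, and
#'   `median_survival` (first time at which survival drops to 0.5 or below;
#'   `NA` means "not reached").
#' @export
km_estimate <- function(times, events, group = NULL) {
  if (!length(times)) stop("empty survival data", call. = FALSE)
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  g <- if (is.null(group)) factor(rep("all", length(times))) else factor(group)
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ g)
  if (is.null(fit$strata)) {
    strata_id <- rep(1L, length(fit$time))
    levels_out <- levels(g)[1L]
  } else {
    strata_id <- rep(seq_along(fit$strata), fit$strata)
    levels_out <- sub("^g=", "", names(fit$strata))
  }
  out <- lapply(seq_along(levels_out), function(i) {
    sel <- strata_id == i
    surv <- fit$surv[sel]
    tt <- fit$time[sel]
    med_idx <- which(surv <= 0.5)
    structure(list(event_times = tt,
                   survival = surv,
                   at_risk = fit$n.risk[sel],
                   n_events = fit$n.event[sel],
                   median_survival = if (length(med_idx)) tt[med_idx[1L]]
                                     else NA_real_),
              class = "km_curve")
  })
  stats::setNames(out, levels_out)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, median survival %s\n",
              length(x$event_times),
              if (is.na(x$median_survival)) "not reached"
              else format(x$median_survival, digits = 4)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the survival experience of
#' two groups.
#'
#' @param times_a,events_a follow-up times and event indicators of group A.
#' @param times_b,events_b same for group B.
#' @return A list with `chi_square` and two-sided `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (sum(events_a) + sum(events_b) == 0) {
    stop("no events in either group", call. = FALSE)
  }
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ grp)
  chi <- unname(sd_fit$chisq)
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Probability that, of a usable (comparable) patient pair, the one with the
#' higher risk predictor experiences the event first; ties in the predictor
#' count 0.5.
#'
#' @param predictor numeric risk score (higher = higher risk).
#' @param times follow-up times.
#' @param events event indicators.
#' @return Harrell's c in `[0, 1]`.
#' @export
concordance_index <- function(predictor, times, events) {
  stopifnot(length(predictor) == length(times),
            length(times) == length(events))
  cf <- survival::concordance(survival::Surv(times, events) ~ predictor,
                              reverse = TRUE)
  counts <- cf$count
  usable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no comparable pairs", call. = FALSE)
  unname(cf$concordance)
}

#' Optimism-corrected Harrell's c-index of a Cox model
#'
#' Harrell's bootstrap internal-validation procedure: the model is refit on
#' each bootstrap resample; the optimism of replicate `b` is the c-index of
#' the replicate model on its own resample minus its c-index on the original
#' cohort.  The corrected c-index is the apparent c-index minus the mean
#' optimism.
#'
#' @param cohort a `cohort_table`.
#' @param features covariate columns of the model.
#' @param B bootstrap replications (default 500).
#' @param seed integer seed.
#' @param ties Cox tie handling.
#' @return A list with `apparent`, `corrected`, `optimism` (per-replicate
#'   vector), and `B`.
#' @export
optimism_corrected_cindex <- function(cohort, features, B = 500L, seed = 1L,
                                      ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (B < 1) stop("`B` must be >= 1", call. = FALSE)
  full <- fit_cox(cohort, features, ties = ties)
  x <- as.matrix(cohort[features])
  apparent <- concordance_index(drop(x %*% full$beta),
                                cohort$time_months, cohort$event)
  set.seed(seed)
  n <- nrow(cohort)
  optimism <- rep(NA_real_, B)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_b <- tryCatch(fit_cox(cohort[idx, , drop = FALSE], features,
                              ties = ties),
                      error = function(e) NULL)
    if (is.null(fit_b)) {
      failed <- failed + 1L
      next
    }
    lp_boot <- drop(x[idx, , drop = FALSE] %*% fit_b$beta)
    lp_orig <- drop(x %*% fit_b$beta)
    c_bb <- concordance_index(lp_boot, cohort$time_months[idx],
                              cohort$event[idx])
    c_bo <- concordance_index(lp_orig, cohort$time_months, cohort$event)
    optimism[b] <- c_bb - c_bo
  }
  if (failed > 0.2 * B) {
    stop(sprintf("%d of %d bootstrap replicates failed", failed, B),
         call. = FALSE)
  }
  list(apparent = apparent,
       corrected = apparent - mean(optimism, na.rm = TRUE),
       optimism = optimism,
       B = as.integer(B))
}

#' Compare clinical variables between two risk groups
#'
#' Continuous variables are compared with a Welch t-test and summarized as
#' mean +/- SD; categorical variables with a chi-square test on the
#' contingency table (no continuity correction) and summarized as
#' proportions of the first non-reference level.
#'
#' @param cohort data frame holding the variables.
#' @param grouping factor-like vector with exactly two levels.
#' @param variables character vector of column names to compare.
#' @return A data frame with one row per variable: `variable`, `test`,
#'   per-group summaries, `statistic`, `p`.
#' @export
compare_risk_groups <- function(cohort, grouping, variables) {
  g <- factor(grouping)
  if (nlevels(g) != 2L || any(table(g) == 0)) {
    stop("`grouping` must define two non-empty groups", call. = FALSE)
  }
  rows <- lapply(variables, function(v) {
    if (is.null(cohort[[v]])) stop("no column `", v, "` in cohort", call. = FALSE)
    x <- cohort[[v]]
    if (is.numeric(x)) {
      x1 <- x[g == levels(g)[1L]]
      x2 <- x[g == levels(g)[2L]]
      if (stats::var(x1) == 0 && stats::var(x2) == 0) {
        stat <- 0
        p <- if (mean(x1) == mean(x2)) 1 else 0
      } else {
        tt <- stats::t.test(x1, x2)
        stat <- unname(tt$statistic)
        p <- tt$p.value
      }
      data.frame(variable = v, test = "t_test",
                 group1 = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
                 group2 = sprintf("%.2f ± %.2f", mean(x2), stats::sd(x2)),
                 statistic = stat, p = p, stringsAsFactors = FALSE)
    } else {
      tab <- table(g, x)
      if (nrow(tab) < 2L || ncol(tab) < 2L ||
          any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        stop("empty row/column in the contingency table for `", v, "`",
             call. = FALSE)
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      prop <- prop.table(tab, margin = 1)
      lev <- colnames(tab)[min(2L, ncol(tab))]
      data.frame(variable = v, test = "chi_square",
                 group1 = sprintf("%.1f%% %s", 100 * prop[1L, lev], lev),
                 group2 = sprintf("%.1f%% %s", 100 * prop[2L, lev], lev),
                 statistic = unname(ct$statistic), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
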