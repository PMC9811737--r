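# Hand-written oracles kept independent of the package implementation.

# Breslow log partial likelihood for a single covariate, coded directly from
# its definition: sum over event times of (beta * x_i - d_t * log(sum over
# risk set of exp(beta * x_j))), with tied events sharing one risk-set term.
breslow_loglik_1d <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    deaths <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[deaths]) -
      length(deaths) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# dense grid-search maximizer of the Breslow partial likelihood
grid_cox_1d <- function(time, event, x, lo = -5, hi = 5, n = 40001L) {
  grid <- seq(lo, hi, length.out = n)
  ll <- vapply(grid, breslow_loglik_1d, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# fuzzy C-means objective recomputed from scratch for given memberships
# and centroids
fcm_objective_brute <- function(values, memberships, centroids, m) {
  total <- 0
  for (i in seq_along(values)) {
    for (j in seq_along(centroids)) {
      total <- total + memberships[i, j]^m * (values[i] - centroids[j])^2
    }
  }
  total
}

# Harrell's c by pair enumeration: usable pairs are those where the shorter
# follow-up ended in an event; predictor ties count 0.5
concordance_brute <- function(predictor, time, event) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j] && event[i] == event[j]) next
      first <- if (time[i] < time[j]) i else j
      second <- if (time[i] < time[j]) j else i
      if (event[first] != 1) next
      den <- den + 1
      if (predictor[first] > predictor[second]) num <- num + 1
      else if (predictor[first] == predictor[second]) num <- num + 0.5
    }
  }
  num / den
}

# minimal cohort table builder for unit tests
toy_cohort <- function(time, event, genes = NULL, clinical = NULL) {
  df <- data.frame(patient_id = sprintf("P%03d", seq_along(time)),
                   time_months = time, event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(clinical)) df <- cbind(df, as.data.frame(clinical))
  if (!is.null(genes)) df <- cbind(df, as.data.frame(genes))
  structure(df,
            genes = if (is.null(genes)) character(0) else colnames(genes),
            clinical = if (is.null(clinical)) character(0)
                       else colnames(clinical),
            class = c("cohort_table", "data.frame"))
}

# small planted-signal cohort used by ranking and pipeline tests
planted_cohort <- function(n = 200, p = 12, beta = c(GSTRONG = 1.2),
                           seed = 42, event_rate = 0.4) {
  gene_names <- c(names(beta),
                  sprintf("N%02d", seq_len(p - length(beta))))
  cfg <- cohort_sim_config(n_patients = n, n_genes = p,
                           causal_effects = beta,
                           baseline_hazard = 0.01,
                           target_event_rate = event_rate,
                           gene_names = gene_names, seed = seed)
  simulate_cohort(cfg)
}
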