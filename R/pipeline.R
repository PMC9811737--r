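#' Configuration of the end-to-end prognostic-modelling pipeline
#'
#' @param cohort either a [cohort_sim_config()] (the cohort is simulated) or
#'   a path to a cohort TSV/CSV readable by [read_cohort()].
#' @param n_splits number of event-rate-preserving random splits.
#' @param train_fraction training fraction per split.
#' @param k consensus top-list size.
#' @param n_trees Random Forest size.
#' @param cv_folds folds for the Lasso penalty cross-validation.
#' @param rf_labels `"fcm"` or `"recorded"` target for the forest arm.
#' @param B bootstrap replications for coefficient stabilization and the
#'   optimism correction.
#' @param alpha significance threshold for score inclusion.
#' @param force_include genes forced into the genetic score regardless of
#'   significance (e.g. `"FOLH1"`).
#' @param ties Cox tie handling.
#' @param seed master seed; every randomized stage derives its own stream
#'   via [child_seed()].
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes all artifacts and a run manifest there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_sim_config(),
                            n_splits = 100L,
                            train_fraction = 0.67,
                            k = 10L,
                            n_trees = 500L,
                            cv_folds = 5L,
                            rf_labels = c("fcm", "recorded"),
                            B = 500L,
                            alpha = 0.05,
                            force_include = NULL,
                            ties = c("breslow", "efron"),
                            seed = 1L,
                            out_dir = NULL) {
  rf_labels <- match.arg(rf_labels)
  ties <- match.arg(ties)
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  if (n_splits <= 0) stop("`n_splits` must be positive", call. = FALSE)
  if (B <= 0) stop("`B` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (is.character(cohort) && !file.exists(cohort)) {
    stop("cohort file does not exist: ", cohort, call. = FALSE)
  }
  if (!is.character(cohort) && !inherits(cohort, "cohort_sim_config")) {
    stop("`cohort` must be a file path or a cohort_sim_config", call. = FALSE)
  }
  structure(list(cohort = cohort, n_splits = as.integer(n_splits),
                 train_fraction = train_fraction, k = as.integer(k),
                 n_trees = as.integer(n_trees), cv_folds = as.integer(cv_folds),
                 rf_labels = rf_labels, B = as.integer(B), alpha = alpha,
                 force_include = force_include, ties = ties,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage_ <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full prognostic-modelling pipeline
#'
#' Orchestrates the whole procedure on one cohort: simulate or load the
#' cohort; define the FCM event label; draw event-rate-preserving random
#' splits; rank genes per split by Random Forest and hybrid Lasso; aggregate
#' the rankings and intersect the two top-k lists; stabilize a multivariable
#' Cox model on the consensus genes by bootstrap; build the genetic score
#' from the significant coefficients (plus any forced genes); dichotomize at
#' the cohort median; and report Kaplan-Meier curves, the log-rank test, the
#' apparent and optimism-corrected c-index, and risk-group comparisons of
#' any clinical covariates.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return A `pipeline_result` list with elements `cohort`, `labeling`,
#'   `splits`, `ranking`, `model`, `score`, `score_table`, `km`, `logrank`,
#'   `cindex`, `group_comparison`, and `manifest`.  When `config$out_dir` is
#'   set the artifacts and a JSON run manifest are also written there.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  cohort <- pipeline_stage_("cohort", {
    if (is.character(config$cohort)) read_cohort(config$cohort)
    else simulate_cohort(config$cohort)
  })
  say("cohort: %d patients, %d genes, %d events (%.1f%%)",
      nrow(cohort), length(cohort_genes_(cohort)), sum(cohort$event),
      100 * mean(cohort$event))

  labeling <- pipeline_stage_("label", define_event_label(cohort, "fcm"))
  say("FCM event threshold: %.1f months; %d adverse labels",
      labeling$threshold_months, sum(labeling$labels))

  splits <- pipeline_stage_("splits",
    make_splits(cohort, n_splits = config$n_splits,
                train_fraction = config$train_fraction,
                seed = child_seed(seed, 1L)))

  ranking <- pipeline_stage_("ranking",
    consensus_rank(cohort, labeling, splits, k = config$k,
                   n_trees = config$n_trees, cv_folds = config$cv_folds,
                   rf_labels = config$rf_labels,
                   seed = child_seed(seed, 2L)))
  say("consensus top-%d intersection: %s", config$k,
      paste(ranking$consensus$genes, collapse = ", "))

  model_features <- union(ranking$consensus$genes, config$force_include)
  model <- pipeline_stage_("cox",
    bootstrap_cox(cohort, model_features, B = config$B,
                  seed = child_seed(seed, 3L), ties = config$ties))

  score <- pipeline_stage_("score",
    build_genetic_score(model, alpha = config$alpha,
                        force_include = config$force_include))
  score_table <- apply_score(score, cohort)
  score$threshold <- attr(score_table, "threshold")
  say("genetic score: %s (cutoff %.4f)", score$formula_text, score$threshold)

  km <- pipeline_stage_("km",
    km_estimate(cohort$time_months, cohort$event, score_table$risk_group))
  lr <- pipeline_stage_("logrank", {
    hi <- score_table$risk_group == "high"
    logrank_test(cohort$time_months[!hi], cohort$event[!hi],
                 cohort$time_months[hi], cohort$event[hi])
  })
  cindex <- pipeline_stage_("cindex",
    optimism_corrected_cindex(cohort, model_features, B = config$B,
                              seed = child_seed(seed, 4L),
                              ties = config$ties))
  say("log-rank chi2 = %.1f (p = %.2g); c-index %.3f (%.3f corrected)",
      lr$chi_square, lr$p, cindex$apparent, cindex$corrected)

  clinical <- attr(cohort, "clinical") %||% character(0)
  group_comparison <- if (length(clinical)) {
    pipeline_stage_("group-comparison",
      compare_risk_groups(cohort, score_table$risk_group, clinical))
  } else NULL

  manifest <- list(
    package = "prognokin",
    version = as.character(utils::packageVersion("prognokin")),
    seed = seed,
    config = manifest_config_(config),
    n_patients = nrow(cohort),
    n_genes = length(cohort_genes_(cohort)),
    event_rate = mean(cohort$event),
    consensus_genes = ranking$consensus$genes,
    score_formula = score$formula_text,
    score_cutoff = score$threshold
  )

  result <- structure(
    list(cohort = cohort, labeling = labeling, splits = splits,
         ranking = ranking, model = model, score = score,
         score_table = score_table, km = km, logrank = lr, cindex = cindex,
         group_comparison = group_comparison, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result_(result, config)
  result
}

manifest_config_ <- function(config) {
  cfg <- unclass(config)
  if (inherits(cfg$cohort, "cohort_sim_config")) {
    cfg$cohort <- unclass(cfg$cohort)
  }
  cfg$out_dir <- NULL
  cfg
}

write_pipeline_result_ <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_cohort(result$cohort, p("cohort.tsv"))
  write_rankings(list(result$ranking$agg_rf, result$ranking$agg_lasso),
                 p("rankings.tsv"))
  jsonlite::write_json(result$ranking$consensus[c("k", "genes")],
                       p("consensus.json"), auto_unbox = TRUE, digits = NA)
  write_model_json(result$model, p("model.json"))
  utils::write.table(
    data.frame(patient_id = result$score_table$patient_id,
               score = fmt_num_(result$score_table$score),
               risk_group = result$score_table$risk_group),
    p("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  km_rows <- do.call(rbind, lapply(names(result$km), function(g) {
    k <- result$km[[g]]
    data.frame(group = g, time = k$event_times, survival = k$survival,
               at_risk = k$at_risk)
  }))
  utils::write.table(km_rows, p("km.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  # manifest carries an md5 of the serialized configuration, so identical
  # manifests imply identical inputs and (given the seed scheme) outputs
  cfg_path <- p("config.json")
  jsonlite::write_json(result$manifest$config, cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- result$manifest
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(config$out_dir)
}

#' Run a batch kinetic analysis of simulated or stored curve groups
#'
#' For each named group, either simulates `n_replicates` preset curves (one
#' [child_seed()] stream per replicate) or reads curve files, fits the model
#' matching the tracer (Patlak for FDG, one-phase association for PSMA), and
#' compares the kinetic parameters between the two groups.
#'
#' @param groups named list of two group specifications; each is a list with
#'   either `preset` and optionally `n_replicates` (default 6) and
#'   `noise_cv`, or `files` (paths readable by [read_curve()]).
#' @param seed master seed for simulated replicates.
#' @return A `kinetics_report`: per-group `fits`, per-parameter
#'   `comparisons`, and a `summary` data frame of parameter means and SDs.
#' @export
run_kinetics <- function(groups, seed = 1L) {
  if (length(groups) != 2L || is.null(names(groups))) {
    stop("`groups` must be a named list of two groups", call. = FALSE)
  }
  sim_group <- function(group_spec, gi) {
    if (!is.null(group_spec$files)) {
      if (!length(group_spec$files)) stop("empty group", call. = FALSE)
      return(lapply(group_spec$files, read_curve))
    }
    if (is.null(group_spec$preset)) stop("group needs `preset` or `files`", call. = FALSE)
    nrep <- group_spec$n_replicates %||% 6L
    if (nrep < 1L) stop("empty group", call. = FALSE)
    lapply(seq_len(nrep), function(r) {
      cfg <- tracer_sim_config(group_spec$preset,
                               noise_cv = group_spec$noise_cv %||% 0.01,
                               seed = child_seed(seed, 100L * gi + r))
      if (cfg$tracer == "FDG") simulate_fdg_curve(cfg)
      else simulate_psma_curve(cfg)
    })
  }
  curves <- Map(sim_group, groups, seq_along(groups))
  tracers <- lapply(curves, function(cs) {
    tr <- unique(vapply(cs, function(c) attr(c, "meta")$tracer %||% "unknown",
                        character(1)))
    if (length(tr) != 1L) stop("mixed tracer types in one group", call. = FALSE)
    tr
  })
  if (length(unique(unlist(tracers))) != 1L) {
    stop("the two groups use different tracers", call. = FALSE)
  }
  tracer <- tracers[[1L]]
  fits <- lapply(curves, function(cs) {
    lapply(cs, if (tracer == "FDG") patlak_fit else one_phase_fit)
  })
  params <- if (tracer == "FDG") c("slope_a", "glucose_consumption")
            else c("amax", "k")
  comparisons <- lapply(params, function(p) {
    compare_kinetics(fits[[1L]], fits[[2L]], p)
  })
  names(comparisons) <- params
  summary <- do.call(rbind, lapply(params, function(p) {
    cmp <- comparisons[[p]]
    data.frame(parameter = p,
               group = names(groups),
               mean = c(cmp$mean1, cmp$mean2),
               sd = c(cmp$sd1, cmp$sd2),
               stringsAsFactors = FALSE)
  }))
  structure(list(tracer = tracer, fits = fits, comparisons = comparisons,
                 summary = summary, seed = as.integer(seed)),
            class = "kinetics_report")
}

#' @export
print.kinetics_report <- function(x, ...) {
  cat(sprintf("kinetics report (%s): groups %s\n", x$tracer,
              paste(names(x$fits), collapse = " vs ")))
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}
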