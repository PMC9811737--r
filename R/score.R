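#' Build a genetic score from a fitted Cox model
#'
#' Retains the features whose Wald p-value falls below `alpha` and uses their
#' (bootstrap-stabilized) log-hazard coefficients as score weights; features
#' in `force_include` are added with their coefficients regardless of
#' significance.  The score of a patient is the corresponding linear
#' combination of gene z-scores.
#'
#' @param model a `cox_model` (typically from [bootstrap_cox()]).
#' @param alpha significance threshold for retention (default 0.05).
#' @param force_include optional character vector of model features to add
#'   irrespective of their p-value.
#' @return A `genetic_score`: `coefficients` (named weights), `threshold`
#'   (`NA` until set by [apply_score()]), `formula_text` rendering of the
#'   linear combination.
#' @examples
#' \dontrun{
#' score <- build_genetic_score(model)            # p < 0.05 genes only
#' forced <- build_genetic_score(model, force_include = "FOLH1")
#' }
#' @export
build_genetic_score <- function(model, alpha = 0.05, force_include = NULL) {
  stopifnot(inherits(model, "cox_model"))
  keep <- model$features[model$p < alpha]
  if (length(force_include)) {
    missing <- setdiff(force_include, model$features)
    if (length(missing)) {
      stop("`force_include` features not in the model: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    keep <- union(keep, force_include)
  }
  keep <- model$features[model$features %in% keep]  # preserve model order
  if (!length(keep)) {
    stop("no feature passes p < ", alpha,
         " and `force_include` is empty", call. = FALSE)
  }
  w <- model$beta[keep]
  structure(list(coefficients = w,
                 threshold = NA_real_,
                 formula_text = render_score_formula_(w)),
            class = "genetic_score")
}

render_score_formula_ <- function(w) {
  term <- sprintf("%s*%s",
                  vapply(abs(w), format, character(1), digits = 3),
                  names(w))
  sign <- ifelse(w < 0, "-", "+")
  out <- paste0(if (w[1L] < 0) "-" else "", term[1L])
  if (length(w) > 1L) {
    out <- paste(out, paste(sign[-1L], term[-1L], collapse = " "))
  }
  out
}

#' @export
print.genetic_score <- function(x, ...) {
  cat("genetic score:", x$formula_text, "\n")
  if (!is.na(x$threshold)) {
    cat(sprintf("dichotomization cutoff (cohort median): %.4f\n", x$threshold))
  }
  invisible(x)
}

#' Apply a genetic score to a cohort and dichotomize at the median
#'
#' Computes `s_i = sum(w_g * z_ig)` per patient and assigns risk groups at
#' the cohort median: patients with `s_i >= median` are the high-risk group
#' (scores equal to the cutoff go to `high`).
#'
#' @param score a `genetic_score`.
#' @param cohort a `cohort_table` containing every score gene.
#' @return A data frame `patient_id`, `score`, `risk_group` (factor
#'   `low`/`high`), with the cutoff in attribute `threshold`.
#' @export
apply_score <- function(score, cohort) {
  stopifnot(inherits(score, "genetic_score"))
  genes <- names(score$coefficients)
  missing <- setdiff(genes, names(cohort))
  if (length(missing)) {
    stop("cohort lacks score gene column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- drop(as.matrix(cohort[genes]) %*% score$coefficients)
  cutoff <- stats::median(s)
  out <- data.frame(
    patient_id = cohort$patient_id %||% sprintf("P%04d", seq_len(nrow(cohort))),
    score = s,
    risk_group = factor(ifelse(s >= cutoff, "high", "low"),
                        levels = c("low", "high")),
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- cutoff
  out
}
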