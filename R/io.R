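#' Read a cohort table from TSV/CSV
#'
#' Expects columns `patient_id`, `time_months`, `event`; every column outside
#' the reserved clinical set (`age`, `race`, `histology`, `t_status`,
#' `n_status`, plus any names passed in `clinical`) is treated as a gene
#' z-score column and must be numeric.  The schema mirrors a portal-style
#' z-score expression export joined to follow-up data.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param clinical extra column names to treat as clinical covariates.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, clinical = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "time_months", "event")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id values", call. = FALSE)
  }
  reserved <- union(reserved_cohort_columns_(), clinical)
  genes <- setdiff(names(df), reserved)
  bad <- genes[!vapply(df[genes], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric expression column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$time_months)) {
    stop("`time_months` must be numeric", call. = FALSE)
  }
  n_missing <- sum(is.na(df[genes]))
  if (n_missing > 0) {
    warning(sprintf("%d missing expression values", n_missing))
  }
  structure(df,
            genes = genes,
            clinical = intersect(names(df), setdiff(reserved, required)),
            class = c("cohort_table", "data.frame"))
}

# format numerics so that read-back reproduces them exactly
fmt_num_ <- function(x) {
  if (!is.numeric(x)) return(x)
  sprintf("%.17g", x)
}

#' Write a cohort table to TSV (with a JSON sidecar of the generating config)
#'
#' @param cohort a `cohort_table`.
#' @param path output path (tab-separated).
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  num <- names(out)[vapply(out, is.numeric, logical(1))]
  out[num] <- lapply(out[num], fmt_num_)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- attr(cohort, "sim_config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a time-activity curve from CSV (plus optional JSON metadata sidecar)
#'
#' @param path CSV with columns `time_min`, `activity_fraction` (or
#'   `activity`); metadata is read from `<path>.json` when present.
#' @return A `tac` object.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  act_col <- intersect(c("activity_fraction", "activity"), names(df))
  if (is.null(df$time_min) || !length(act_col)) {
    stop("curve file needs `time_min` and `activity_fraction` columns",
         call. = FALSE)
  }
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  as_tac(df$time_min, df[[act_col[1L]]], meta)
}

#' Write a time-activity curve to CSV with a JSON metadata sidecar
#'
#' @param curve a `tac` object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "tac"))
  df <- data.frame(time_min = fmt_num_(curve$time_min),
                   activity_fraction = fmt_num_(curve$activity))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  meta <- attr(curve, "meta")
  if (length(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Serialize a Cox model to JSON
#'
#' @param model a `cox_model`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "cox_model"))
  payload <- list(
    features = model$features,
    beta = as.list(model$beta),
    se = as.list(model$se),
    hr = as.list(model$hr),
    ci95 = list(lower = unname(model$ci95[, "lower"]),
                upper = unname(model$ci95[, "upper"])),
    p = as.list(model$p),
    cindex_apparent = model$cindex_apparent,
    cindex_corrected = model$cindex_corrected,
    n_boot = model$n_boot,
    ties = model$ties
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Write an aggregated ranking (or several) to TSV
#'
#' @param aggregates list of `aggregated_ranking` objects.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_rankings <- function(aggregates, path) {
  rows <- do.call(rbind, lapply(aggregates, function(a) {
    data.frame(gene = a$gene, method = attr(a, "method"),
               mean_rank = a$mean_rank, order = seq_len(nrow(a)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
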