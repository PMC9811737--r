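#' Event-rate-preserving random train/test splits
#'
#' Repeated random splits stratified on the binary class so that the training
#' and test event rates match the cohort's as closely as integer rounding
#' allows: events and non-events are sampled separately, `round(fraction * n)`
#' of each.
#'
#' @param cohort a `cohort_table`.
#' @param n_splits number of random splits (default 100).
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.67).
#' @param seed integer seed; split `i` uses [child_seed()] stream `i`.
#' @param labels optional binary vector to stratify on; defaults to the
#'   recorded `event` column.
#' @return A `split_plan`: list with `splits` (each a list of `train` and
#'   `test` row indices), `n_splits`, `train_fraction`, `seed`.
#' @export
make_splits <- function(cohort, n_splits = 100L, train_fraction = 0.67,
                        seed = 1L, labels = NULL) {
  labels <- labels %||% cohort$event
  if (length(labels) != nrow(cohort)) {
    stop("`labels` must have one entry per patient", call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  cls <- split(seq_len(nrow(cohort)), as.integer(labels != 0))
  if (length(cls) < 2L || any(lengths(cls) < 2L)) {
    stop("both classes must have at least 2 members", call. = FALSE)
  }
  n_train <- lapply(cls, function(idx) {
    k <- round(train_fraction * length(idx))
    if (k == 0L || k == length(idx)) {
      stop("`train_fraction` leaves a class empty on one side", call. = FALSE)
    }
    k
  })
  splits <- vector("list", n_splits)
  for (i in seq_len(n_splits)) {
    set.seed(child_seed(seed, i))
    train <- sort(unlist(Map(function(idx, k) sample(idx, k), cls, n_train),
                         use.names = FALSE))
    splits[[i]] <- list(train = train,
                        test = setdiff(seq_len(nrow(cohort)), train))
  }
  structure(list(splits = splits, n_splits = as.integer(n_splits),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

new_feature_ranking_ <- function(genes, weights, method, split_id = NA_integer_) {
  stopifnot(length(genes) == length(weights), all(is.finite(weights)),
            all(weights >= 0))
  ord <- order(-weights, genes)
  rank <- integer(length(genes))
  rank[ord] <- seq_along(genes)
  structure(
    data.frame(gene = genes, weight = weights, rank = rank,
               stringsAsFactors = FALSE),
    method = method, split_id = split_id,
    class = c("feature_ranking", "data.frame")
  )
}

#' Rank genes by Random Forest impurity importance
#'
#' Fits a Breiman-style classification forest (via \pkg{ranger}, impurity
#' importance, `sqrt(p)` candidate features per node) on the binary event
#' label and ranks genes by decreasing mean impurity decrease.  Ties are
#' broken alphabetically by gene symbol.
#'
#' @param train_expr numeric matrix or data frame, patients x genes.
#' @param train_labels binary vector with both classes present.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed passed to the forest.
#' @return A `feature_ranking` data frame: `gene`, `weight` (importance),
#'   `rank` (1 = most important; a permutation of `1..n_genes`).
#' @export
rank_random_forest <- function(train_expr, train_labels, n_trees = 500L,
                               seed = 1L) {
  x <- as.data.frame(train_expr)
  if (length(unique(train_labels)) < 2L) {
    stop("`train_labels` must contain both classes", call. = FALSE)
  }
  fit <- ranger::ranger(x = x, y = factor(train_labels),
                        num.trees = n_trees,
                        importance = "impurity",
                        num.threads = 1L, seed = seed,
                        verbose = FALSE)
  imp <- ranger::importance(fit)
  # impurity importance can be marginally negative on pure-noise features
  imp <- pmax(imp, 0)
  new_feature_ranking_(names(imp), unname(imp), "random_forest")
}

#' Rank genes by hybrid-Lasso coefficient magnitude
#'
#' L1-penalized logistic regression on the (FCM-defined) binary event label,
#' with the penalty chosen at the cross-validated deviance minimum.  The
#' ranking weight of a gene is the absolute coefficient at the chosen
#' penalty; genes shrunk exactly to zero share the worst rank block, ordered
#' alphabetically within it.
#'
#' @param train_expr numeric matrix or data frame, patients x genes.
#' @param train_labels binary vector with both classes present (intended to
#'   come from [define_event_label()] in `"fcm"` mode).
#' @param lambda_grid optional penalty grid; default lets \pkg{glmnet} choose.
#' @param cv_folds number of cross-validation folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @return A `feature_ranking` data frame (see [rank_random_forest()]).
#' @export
rank_hybrid_lasso <- function(train_expr, train_labels, lambda_grid = NULL,
                              cv_folds = 5L, seed = 1L) {
  x <- as.matrix(train_expr)
  if (length(unique(train_labels)) < 2L) {
    stop("`train_labels` must contain both classes", call. = FALSE)
  }
  if (!is.null(lambda_grid) && length(lambda_grid) == 0L) {
    stop("`lambda_grid` must not be empty", call. = FALSE)
  }
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, factor(train_labels), family = "binomial",
                          alpha = 1, nfolds = cv_folds,
                          lambda = lambda_grid,
                          type.measure = "deviance",
                          standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  new_feature_ranking_(colnames(x), abs(beta), "hybrid_lasso")
}

#' Aggregate per-split rankings into a consensus ordering
#'
#' Averages the per-split ranks of every gene and orders genes by ascending
#' mean rank, ties broken alphabetically.
#'
#' @param rankings list of `feature_ranking` objects over an identical gene
#'   set (one per split, same method).
#' @return An `aggregated_ranking`: data frame `gene`, `mean_rank` sorted by
#'   mean rank; attribute `method`.
#' @export
aggregate_rankings <- function(rankings) {
  if (!length(rankings)) stop("`rankings` must be non-empty", call. = FALSE)
  genes <- sort(rankings[[1L]]$gene)
  rank_mat <- vapply(rankings, function(r) {
    if (!setequal(r$gene, genes)) {
      stop("rankings cover different gene sets", call. = FALSE)
    }
    r$rank[match(genes, r$gene)]
  }, numeric(length(genes)))
  mean_rank <- rowMeans(as.matrix(rank_mat))
  ord <- order(mean_rank, genes)
  structure(
    data.frame(gene = genes[ord], mean_rank = mean_rank[ord],
               stringsAsFactors = FALSE),
    method = attr(rankings[[1L]], "method"),
    n_rankings = length(rankings),
    class = c("aggregated_ranking", "data.frame")
  )
}

#' Intersect the top-k genes of two aggregated rankings
#'
#' @param agg_a,agg_b `aggregated_ranking` objects (typically the Random
#'   Forest and hybrid-Lasso aggregates).
#' @param k top-list size (default 10).
#' @return A `consensus_set`: list with `k`, `genes` (alphabetical
#'   intersection of the two top-k sets), and the two top-k lists.
#' @export
consensus_top_k <- function(agg_a, agg_b, k = 10L) {
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  if (k > nrow(agg_a) || k > nrow(agg_b)) {
    stop("`k` exceeds the number of ranked genes", call. = FALSE)
  }
  top_a <- agg_a$gene[seq_len(k)]
  top_b <- agg_b$gene[seq_len(k)]
  structure(list(k = as.integer(k),
                 genes = sort(intersect(top_a, top_b)),
                 top_a = top_a, top_b = top_b),
            class = "consensus_set")
}

#' Run the full consensus ranking over a split plan
#'
#' Convenience driver for the ranking stage: for every split, rank the
#' training expression by Random Forest and by hybrid Lasso, aggregate each
#' method's rankings across splits, and intersect the two top-k lists.
#'
#' @param cohort a `cohort_table`.
#' @param labeling an `event_labeling` (see [define_event_label()]); used as
#'   the target for the Lasso arm and, by default, the Random Forest arm.
#' @param splits a `split_plan`.
#' @param k consensus top-list size.
#' @param n_trees,cv_folds hyperparameters passed to the rankers.
#' @param rf_labels `"fcm"` to train the forest on the FCM label (default) or
#'   `"recorded"` to use the recorded event indicator.
#' @param seed master seed; per-split, per-method child seeds are derived
#'   with [child_seed()].
#' @return A `consensus_ranking`: list with the two `aggregated_ranking`s,
#'   the `consensus_set`, and the per-split rankings.
#' @export
consensus_rank <- function(cohort, labeling, splits, k = 10L,
                           n_trees = 500L, cv_folds = 5L,
                           rf_labels = c("fcm", "recorded"), seed = 1L) {
  rf_labels <- match.arg(rf_labels)
  genes <- cohort_genes_(cohort)
  expr <- as.matrix(cohort[genes])
  lab_fcm <- labeling$labels
  lab_rf <- if (rf_labels == "fcm") lab_fcm else as.integer(cohort$event)
  rf_list <- vector("list", splits$n_splits)
  lasso_list <- vector("list", splits$n_splits)
  for (i in seq_len(splits$n_splits)) {
    tr <- splits$splits[[i]]$train
    rf_list[[i]] <- rank_random_forest(expr[tr, , drop = FALSE], lab_rf[tr],
                                       n_trees = n_trees,
                                       seed = child_seed(seed, 2L * i))
    lasso_list[[i]] <- rank_hybrid_lasso(expr[tr, , drop = FALSE], lab_fcm[tr],
                                         cv_folds = cv_folds,
                                         seed = child_seed(seed, 2L * i + 1L))
  }
  agg_rf <- aggregate_rankings(rf_list)
  agg_lasso <- aggregate_rankings(lasso_list)
  structure(list(agg_rf = agg_rf, agg_lasso = agg_lasso,
                 consensus = consensus_top_k(agg_rf, agg_lasso, k),
                 rankings_rf = rf_list, rankings_lasso = lasso_list),
            class = "consensus_ranking")
}
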