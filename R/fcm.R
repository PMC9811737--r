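#' Fuzzy C-means clustering of a one-dimensional outcome
#'
#' Classic fuzzy C-means on a numeric vector: alternate the membership update
#' `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))` (with Euclidean distances `d`)
#' and the centroid update as the `u^m`-weighted mean, until the centroids
#' move less than `tol`.  Used to choose the follow-up-time threshold that
#' defines the adverse (early-progression) class for the ML rankers.
#'
#' @param values numeric outcome vector (at least `centers` distinct values).
#' @param centers number of clusters (default 2).
#' @param fuzzifier fuzziness exponent `m` (> 1, default 2).
#' @param tol convergence tolerance on the maximum centroid shift.
#' @param max_iter maximum number of iterations.
#' @return An `fcm_result`: `centroids` (ascending), `memberships` (rows sum
#'   to 1, columns ordered with the centroids), `fuzzifier`, `threshold`
#'   (value of equal membership between the two outer centroids, i.e. their
#'   midpoint in one dimension), `iterations`, and the per-iteration
#'   `objective` values `sum(u^m d^2)`.
#' @examples
#' fit <- fcm_cluster(c(1, 1.2, 0.8, 9.5, 10, 10.5))
#' fit$centroids
#' fit$threshold
#' @export
fcm_cluster <- function(values, centers = 2L, fuzzifier = 2, tol = 1e-8,
                        max_iter = 500L) {
  x <- as.numeric(values)
  if (anyNA(x)) stop("`values` must not contain NA", call. = FALSE)
  if (fuzzifier <= 1) stop("`fuzzifier` must be > 1", call. = FALSE)
  ux <- sort(unique(x))
  if (length(ux) < centers) {
    stop("need at least ", centers, " distinct values to cluster", call. = FALSE)
  }

  # deterministic initialization from evenly spaced quantiles of the
  # distinct values
  centroids <- stats::quantile(ux, probs = seq_len(centers) / (centers + 1),
                               names = FALSE, type = 7)
  if (anyDuplicated(centroids)) {
    centroids <- ux[round(seq(1, length(ux), length.out = centers))]
  }

  expo <- 1 / (fuzzifier - 1)  # exponent on squared distances
  objective <- numeric(0)
  u <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d2 <- outer(x, centroids, function(a, b) (a - b)^2)
    u <- matrix(0, length(x), centers)
    zero <- d2 <= .Machine$double.eps^2
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    if (any(!hit)) {
      w <- d2[!hit, , drop = FALSE]^(-expo)
      u[!hit, ] <- w / rowSums(w)
    }
    objective <- c(objective, sum(u^fuzzifier * d2))
    um <- u^fuzzifier
    new_centroids <- colSums(um * x) / colSums(um)
    shift <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("fuzzy C-means did not converge in ", max_iter, " iterations",
         call. = FALSE)
  }
  ord <- order(centroids)
  centroids <- centroids[ord]
  u <- u[, ord, drop = FALSE]
  if (min(diff(centroids)) <= .Machine$double.eps) {
    stop("degenerate clustering: centroids collapsed", call. = FALSE)
  }
  structure(
    list(centroids = centroids,
         memberships = u,
         fuzzifier = fuzzifier,
         # equal membership between two centroids occurs where the distances
         # are equal; in 1-D that is their midpoint, for any fuzzifier
         threshold = mean(centroids[c(1L, centers)]),
         iterations = iter,
         objective = objective),
    class = "fcm_result"
  )
}

#' Define the binary event label used by the ML rankers
#'
#' In `"fcm"` mode the follow-up times are clustered with [fcm_cluster()]
#' into an early and a late group; a patient is labelled 1 (adverse class)
#' iff a progression event was recorded *and* it occurred no later than the
#' FCM threshold.  Patients censored early therefore stay in class 0.  In
#' `"recorded"` mode the label is the recorded event indicator unchanged.
#'
#' @param cohort a `cohort_table` (needs `time_months` and `event`).
#' @param mode `"fcm"` or `"recorded"`.
#' @return An `event_labeling`: `labels` (0/1 per patient),
#'   `threshold_months` (`NA` in recorded mode), `source`.
#' @export
define_event_label <- function(cohort, mode = c("fcm", "recorded")) {
  mode <- match.arg(mode)
  if (is.null(cohort$time_months) || is.null(cohort$event)) {
    stop("`cohort` must have `time_months` and `event` columns", call. = FALSE)
  }
  if (nrow(cohort) < 2L) {
    stop("need at least 2 patients to define an event label", call. = FALSE)
  }
  if (mode == "recorded") {
    return(structure(list(labels = as.integer(cohort$event),
                          threshold_months = NA_real_,
                          source = "recorded"),
                     class = "event_labeling"))
  }
  fit <- fcm_cluster(cohort$time_months)
  labels <- as.integer(cohort$event == 1 & cohort$time_months <= fit$threshold)
  structure(list(labels = labels,
                 threshold_months = fit$threshold,
                 source = "fcm",
                 fcm = fit),
            class = "event_labeling")
}
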