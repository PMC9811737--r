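test_that("splits preserve the cohort event rate under integer rounding", {
  cohort <- toy_cohort(seq_len(493), rep(c(1, 0), c(93, 400)))
  plan <- make_splits(cohort, n_splits = 5, seed = 2)
  for (sp in plan$splits) {
    ev <- cohort$event[sp$train]
    expect_equal(sum(ev), 62)          # round(0.67 * 93)
    expect_equal(length(ev) - 62, 268) # round(0.67 * 400)
    expect_equal(sort(c(sp$train, sp$test)), seq_len(493))
  }
  # 62/330 = 18.8% vs cohort 18.9%
  expect_equal(62 / 330, 93 / 493, tolerance = 0.01)
})

test_that("splits with exact class rounding keep event counts fixed", {
  cohort <- toy_cohort(seq_len(10), rep(c(1, 0), each = 5))
  plan <- make_splits(cohort, n_splits = 20, train_fraction = 0.6, seed = 1)
  counts <- vapply(plan$splits,
                   function(sp) sum(cohort$event[sp$train]), numeric(1))
  expect_true(all(counts == 3))
})

test_that("degenerate split requests are rejected", {
  cohort <- toy_cohort(seq_len(10), rep(c(1, 0), each = 5))
  expect_error(make_splits(cohort, train_fraction = 1), "train_fraction")
  expect_error(make_splits(toy_cohort(c(1, 2, 3), c(1, 0, 0))), "2 members")
})

test_that("splits are reproducible under the master seed", {
  cohort <- toy_cohort(seq_len(30), rep(c(1, 0), 15))
  expect_identical(make_splits(cohort, n_splits = 4, seed = 9),
                   make_splits(cohort, n_splits = 4, seed = 9))
})

test_that("random forest ranks a perfectly separating gene first", {
  set.seed(31)
  wins <- 0L
  for (rep in 1:20) {
    n <- 60
    labels <- rep(c(0, 1), each = n / 2)
    expr <- matrix(rnorm(n * 8), n, 8,
                   dimnames = list(NULL, paste0("g", 1:8)))
    expr[, "g4"] <- labels * 4 + rnorm(n, 0, 0.1)
    r <- rank_random_forest(expr, labels, n_trees = 200, seed = rep)
    if (r$rank[r$gene == "g4"] == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("a single-gene ranking is the identity and bad labels error", {
  expr <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "only"))
  r <- rank_random_forest(expr, rep(c(0, 1), 20), n_trees = 50, seed = 1)
  expect_identical(r$rank, 1L)
  expect_error(rank_random_forest(expr, rep(0, 40)), "both classes")
  expect_error(rank_hybrid_lasso(expr, rep(1, 40)), "both classes")
})

test_that("forest importance agrees with an independent implementation", {
  set.seed(8)
  n <- 120
  labels <- rep(c(0, 1), each = n / 2)
  expr <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
  expr[, "g2"] <- labels * 2 + rnorm(n, 0, 0.5)
  r <- rank_random_forest(expr, labels, n_trees = 500, seed = 4)
  rf <- randomForest::randomForest(x = as.data.frame(expr),
                                   y = factor(labels), ntree = 500)
  ref_top <- names(which.max(rf$importance[, "MeanDecreaseGini"]))
  expect_identical(r$gene[r$rank == 1L], ref_top)
})

test_that("lasso ranking finds a planted strong gene and shrinks the rest", {
  set.seed(17)
  n <- 150
  expr <- matrix(rnorm(n * 10), n, 10,
                 dimnames = list(NULL, paste0("g", sprintf("%02d", 1:10))))
  lp <- 2.5 * expr[, "g07"]
  labels <- rbinom(n, 1, plogis(lp))
  r <- rank_hybrid_lasso(expr, labels, seed = 5)
  expect_identical(r$gene[r$rank == 1L], "g07")
  expect_gt(r$weight[r$gene == "g07"], 0)
})

test_that("full shrinkage yields a purely alphabetical ranking", {
  set.seed(2)
  expr <- matrix(rnorm(200), 20, 10,
                 dimnames = list(NULL, sample(paste0("g", 1:10))))
  r <- suppressWarnings(rank_hybrid_lasso(expr, rep(c(0, 1), 10),
                                          lambda_grid = c(1e6, 1e5),
                                          seed = 1))
  expect_identical(r$gene[order(r$rank)], sort(r$gene))
  expect_true(all(r$weight == 0))
  expect_error(suppressWarnings(rank_hybrid_lasso(expr, rep(c(0, 1), 10),
                                                  lambda_grid = numeric(0))),
               "empty")
})

test_that("duplicating an informative gene splits its weight but stays deterministic", {
  set.seed(12)
  n <- 300
  expr <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
  lp <- 2 * expr[, "g3"]
  labels <- rbinom(n, 1, plogis(lp))
  base <- rank_hybrid_lasso(expr, labels, seed = 3)
  dup <- cbind(expr, g3dup = expr[, "g3"])
  r1 <- rank_hybrid_lasso(dup, labels, seed = 3)
  r2 <- rank_hybrid_lasso(dup, labels, seed = 3)
  expect_identical(r1, r2)
  combined <- sum(r1$weight[r1$gene %in% c("g3", "g3dup")])
  original <- base$weight[base$gene == "g3"]
  expect_equal(combined, original, tolerance = 0.3)
})

test_that("rank vectors are permutations and aggregation respects tie rules", {
  # ranks (1,3) and (3,1) for genes A and B, with C in between both times
  r_a <- prognokin:::new_feature_ranking_(c("A", "B", "C"), c(3, 1, 2), "m")
  r_b <- prognokin:::new_feature_ranking_(c("A", "B", "C"), c(1, 3, 2), "m")
  expect_identical(sort(r_a$rank), 1:3)
  agg <- aggregate_rankings(list(r_a, r_b))
  expect_equal(agg$mean_rank, c(2, 2, 2))
  expect_identical(agg$gene, c("A", "B", "C"))  # ties broken alphabetically

  single <- aggregate_rankings(list(r_a))
  expect_identical(single$gene, r_a$gene[order(r_a$rank)])

  r_c <- prognokin:::new_feature_ranking_(c("A", "C"), c(1, 2), "m")
  expect_error(aggregate_rankings(list(r_a, r_c)), "different gene sets")
})

test_that("a gene that always ranks first dominates the aggregate", {
  genes <- paste0("g", sprintf("%02d", 1:15))
  set.seed(6)
  always_first <- lapply(1:50, function(i) {
    w <- runif(15)
    w[3] <- 2  # gene g03 always has the top weight
    prognokin:::new_feature_ranking_(genes, w, "m")
  })
  agg <- aggregate_rankings(always_first)
  expect_identical(agg$gene[1L], "g03")
  expect_equal(agg$mean_rank[1L], 1)
  expect_true(all(agg$mean_rank >= 1 & agg$mean_rank <= 15))
})

test_that("consensus is the alphabetical intersection of the two top-k lists", {
  genes <- sprintf("g%02d", 1:20)
  agg_a <- aggregate_rankings(list(
    prognokin:::new_feature_ranking_(genes, rev(seq_along(genes)), "a")))
  agg_b <- aggregate_rankings(list(
    prognokin:::new_feature_ranking_(
      genes, c(rep(0, 4), rev(seq_along(genes))[-(1:4)] + 100), "b")))
  cons <- consensus_top_k(agg_a, agg_b, k = 10)
  expect_identical(cons$genes, sprintf("g%02d", 5:10))

  same <- consensus_top_k(agg_a, agg_a, k = 10)
  expect_length(same$genes, 10L)
  expect_error(consensus_top_k(agg_a, agg_b, k = 0), "positive")
  expect_error(consensus_top_k(agg_a, agg_b, k = 25), "exceeds")
})

test_that("independent random rankings meet the hypergeometric null", {
  # with independent top-k lists over p genes, a fixed gene lands in the
  # consensus with probability (k/p)^2 and the expected consensus size is
  # k^2/p; verified by feeding random permutation rankings through the
  # aggregation/consensus machinery
  set.seed(77)
  p <- 30L
  k <- 5L
  genes <- sprintf("g%02d", seq_len(p))
  reps <- 1500L
  hits <- 0L
  sizes <- numeric(reps)
  for (i in seq_len(reps)) {
    a <- aggregate_rankings(list(
      prognokin:::new_feature_ranking_(genes, sample(p), "a")))
    b <- aggregate_rankings(list(
      prognokin:::new_feature_ranking_(genes, sample(p), "b")))
    cons <- consensus_top_k(a, b, k)
    sizes[i] <- length(cons$genes)
    if ("g01" %in% cons$genes) hits <- hits + 1L
  }
  p_fixed <- (k / p)^2
  se_fixed <- sqrt(p_fixed * (1 - p_fixed) / reps)
  expect_lt(abs(hits / reps - p_fixed), 4 * se_fixed)
  expect_lt(abs(mean(sizes) - k^2 / p), 4 * sd(sizes) / sqrt(reps))
})

test_that("the consensus driver recovers strongly planted genes end to end", {
  cohort <- planted_cohort(n = 250, p = 15,
                           beta = c(GSTRONG = 1.3, HSTRONG = -1.3),
                           seed = 19)
  lab <- define_event_label(cohort, "fcm")
  plan <- make_splits(cohort, n_splits = 6, seed = 3)
  cr <- consensus_rank(cohort, lab, plan, k = 5, n_trees = 200, seed = 4)
  expect_true(all(c("GSTRONG", "HSTRONG") %in% cr$consensus$genes))
  # determinism of the whole ranking stage
  cr2 <- consensus_rank(cohort, lab, plan, k = 5, n_trees = 200, seed = 4)
  expect_identical(cr$agg_rf, cr2$agg_rf)
  expect_identical(cr$agg_lasso, cr2$agg_lasso)
})
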