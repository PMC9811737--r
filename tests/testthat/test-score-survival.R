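# bootstrap-stabilized coefficients of the five-gene multivariable model,
# used as fixed inputs for the score-construction tests
five_gene_model <- function() {
  prognokin:::new_cox_model_(
    features = c("PARP2", "SLC2A4", "CTH", "ALDOB", "FOLH1"),
    beta = c(0.254, -0.733, -0.372, 0.140, -0.0943),
    se = c(0.0914, 0.244, 0.144, 0.0588, 0.110),
    n_boot = 500L
  )
}

test_that("the genetic score keeps significant genes and drops the rest", {
  score <- build_genetic_score(five_gene_model())
  expect_identical(names(score$coefficients),
                   c("PARP2", "SLC2A4", "CTH", "ALDOB"))
  expect_equal(unname(score$coefficients),
               c(0.254, -0.733, -0.372, 0.140))
  expect_match(score$formula_text, "^0.254\\*PARP2 - 0.733\\*SLC2A4")
})

test_that("forcing a non-significant gene adds it with its own coefficient", {
  score <- build_genetic_score(five_gene_model(), force_include = "FOLH1")
  expect_true("FOLH1" %in% names(score$coefficients))
  expect_equal(unname(score$coefficients["FOLH1"]), -0.0943)
  expect_match(score$formula_text, "- 0.0943\\*FOLH1$")
})

test_that("an empty score is an error", {
  model <- prognokin:::new_cox_model_("g1", 0.05, 1)
  expect_error(build_genetic_score(model), "no feature passes")
  expect_error(build_genetic_score(five_gene_model(),
                                   force_include = "NOT_A_GENE"),
               "not in the model")
})

test_that("score application is the stated linear combination", {
  score <- build_genetic_score(five_gene_model())
  ones <- toy_cohort(c(1, 2), c(1, 0),
                     genes = matrix(1, 2, 4,
                                    dimnames = list(NULL,
                                      c("PARP2", "SLC2A4", "CTH", "ALDOB"))))
  st <- apply_score(score, ones)
  expect_equal(st$score, rep(0.254 - 0.733 - 0.372 + 0.140, 2))
  zeros <- toy_cohort(c(1, 2), c(1, 0),
                      genes = matrix(0, 2, 4,
                                     dimnames = list(NULL,
                                       c("PARP2", "SLC2A4", "CTH", "ALDOB"))))
  expect_equal(apply_score(score, zeros)$score, c(0, 0))
  expect_error(apply_score(score, toy_cohort(1:2, c(1, 0))), "lacks")
})

test_that("median dichotomization sends the cutoff score to the high group", {
  model <- prognokin:::new_cox_model_("g", 1, 0.1)
  score <- build_genetic_score(model)
  cohort <- toy_cohort(c(5, 6, 7), c(1, 1, 0),
                       genes = cbind(g = c(-1, 0, 1)))
  st <- apply_score(score, cohort)
  expect_equal(attr(st, "threshold"), 0)
  expect_identical(as.character(st$risk_group), c("low", "high", "high"))
})

test_that("Kaplan-Meier estimates match hand product-limit computations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))[[1]]
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median_survival, 2)

  censored <- km_estimate(c(4, 9, 13), c(0, 0, 0))[[1]]
  expect_true(all(censored$survival == 1))
  expect_true(is.na(censored$median_survival))

  mixed <- km_estimate(c(1, 2, 3), c(1, 0, 1))[[1]]
  expect_equal(mixed$survival[mixed$event_times == 1], 2 / 3)
  expect_equal(mixed$survival[mixed$event_times == 3], 0)

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("KM survival is a non-increasing step function from 1", {
  set.seed(40)
  km <- km_estimate(rexp(80, 0.1), rbinom(80, 1, 0.7))[[1]]
  expect_true(all(km$survival <= 1))
  expect_true(all(diff(km$survival) <= 1e-12))
  # without censoring the estimator equals the empirical survival function
  t_all <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km2 <- km_estimate(t_all, rep(1, 8))[[1]]
  emp <- vapply(km2$event_times, function(t) mean(t_all > t), numeric(1))
  expect_equal(km2$survival, emp)
})

test_that("log-rank behaves at the null and under strong separation", {
  t1 <- c(2, 4, 6, 8)
  e1 <- c(1, 0, 1, 1)
  null <- logrank_test(t1, e1, t1, e1)
  expect_equal(null$chi_square, 0, tolerance = 1e-12)
  expect_equal(null$p, 1)
  # symmetry under group swap
  t2 <- c(1, 3, 5)
  e2 <- c(1, 1, 0)
  expect_equal(logrank_test(t1, e1, t2, e2)$chi_square,
               logrank_test(t2, e2, t1, e1)$chi_square)

  set.seed(60)
  n <- 250
  ta <- rexp(n, 0.02)
  tb <- rexp(n, 0.06)  # hazard ratio 3
  strong <- logrank_test(ta, rep(1, n), tb, rep(1, n))
  expect_lt(strong$p, 1e-4)
  expect_error(logrank_test(t1, rep(0, 4), t1, rep(0, 4)), "no events")
})

test_that("the concordance index matches pair enumeration", {
  t <- c(3, 1, 4, 1.5, 5, 9, 2.6, 6)
  e <- c(1, 1, 0, 1, 1, 0, 1, 1)
  set.seed(3)
  pred <- rnorm(8)
  expect_equal(concordance_index(pred, t, e),
               concordance_brute(pred, t, e))
  expect_equal(concordance_index(-t, t, rep(1, 8)), 1)
  expect_equal(concordance_index(rep(2, 8), t, e), 0.5)
  set.seed(4)
  n <- 2000
  expect_lt(abs(concordance_index(rnorm(n), rexp(n), rep(1, n)) - 0.5),
            0.03)
})

test_that("optimism correction is small when n >> p and large near saturation", {
  well <- planted_cohort(n = 600, p = 2,
                         beta = c(GSTRONG = 1, HSTRONG = -1),
                         seed = 23, event_rate = 0.5)
  cc <- optimism_corrected_cindex(well, attr(well, "genes"), B = 50, seed = 1)
  # optimism is a Monte-Carlo estimate: near zero (either sign) when the
  # model cannot overfit
  expect_lt(abs(cc$apparent - cc$corrected), 0.01)

  small <- planted_cohort(n = 45, p = 8, beta = c(GSTRONG = 0),
                          seed = 29, event_rate = 0.6)
  cc2 <- optimism_corrected_cindex(small, attr(small, "genes"),
                                   B = 80, seed = 2)
  expect_gt(cc2$apparent - cc2$corrected, 0.02)
  expect_lt(cc2$corrected, cc2$apparent)
  expect_error(optimism_corrected_cindex(well, attr(well, "genes"), B = 0),
               "B")
})

test_that("risk-group comparisons use the right tests", {
  x <- c(rnorm(20, 5), rnorm(20, 5))
  g <- rep(c("low", "high"), each = 20)
  same <- compare_risk_groups(data.frame(v = c(x[1:20], x[1:20])), g, "v")
  expect_equal(same$p, 1)
  expect_identical(same$test, "t_test")

  flat <- data.frame(cat = rep(rep(c("a", "b"), each = 50), 2))
  gg <- rep(c("low", "high"), each = 100)
  even <- compare_risk_groups(flat, gg, "cat")
  expect_equal(even$statistic, 0, tolerance = 1e-12)

  skewed <- data.frame(cat = c(rep("a", 90), rep("b", 10),
                               rep("a", 60), rep("b", 40)))
  chi <- compare_risk_groups(skewed, gg, "cat")
  expect_equal(chi$statistic, 24, tolerance = 1e-9)  # sum((O-E)^2/E)
  expect_identical(chi$test, "chi_square")

  empty_cell <- data.frame(cat = c(rep("a", 100), rep("a", 100)))
  expect_error(compare_risk_groups(empty_cell, gg, "cat"), "contingency")
})
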