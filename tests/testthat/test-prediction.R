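two_class_labels <- function(n_pos, n_neg) {
  factor(c(rep("positive", n_pos), rep("negative", n_neg)),
         levels = c("negative", "positive"))
}

test_that("Kruskal-Wallis ranking matches kruskal.test and orders sanely", {
  set.seed(41)
  y <- two_class_labels(8, 12)
  X <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  X[, 3] <- c(rnorm(8, 5, 0.1), rnorm(12, 0, 0.1))  # perfect separation
  X[, 7] <- 1                                        # constant
  rk <- rank_kruskal_wallis(X, y)
  expect_equal(rk$order[1], "f3")
  expect_equal(rk$order[10], "f7")
  expect_equal(rk$flagged_constant, "f7")
  for (k in c(1, 2, 3, 5)) {
    expect_equal(unname(rk$scores[k]),
                 kruskal.test(X[, k], y)$p.value, tolerance = 1e-10)
  }
  # tied p-values resolve to the lower column index
  Xt <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])
  rkt <- rank_kruskal_wallis(Xt, y)
  expect_lt(match("a", rkt$order), match("b", rkt$order))
})

test_that("SVM-RFE eliminates one column per round with the tie rule", {
  set.seed(42)
  y <- two_class_labels(10, 10)
  X2 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  rk2 <- rank_svm_rfe(scale(X2), y)
  expect_equal(sort(rk2$order), c("a", "b"))
  # duplicated column: the later-indexed copy is eliminated first
  X3 <- cbind(sig = c(rnorm(10, 2), rnorm(10, -2)), n1 = rnorm(20))
  X3 <- cbind(X3, copy = X3[, "sig"])
  rk3 <- rank_svm_rfe(scale(X3), y)
  expect_lt(match("sig", rk3$order), match("copy", rk3$order))
})

test_that("an informative feature survives SVM-RFE on planted data", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    y <- two_class_labels(10, 10)
    X <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    X[, 4] <- ifelse(y == "positive", 3, -3) + rnorm(20, sd = 0.3)
    rk <- rank_svm_rfe(scale(X), y)
    if (rk$order[1] == "f4") hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("class weights are inversely proportional to class frequency", {
  w <- svm_class_weights(two_class_labels(8, 24))
  expect_equal(unname(w["negative"] / w["positive"]), 8 / 24)
  expect_equal(unname(w["positive"]), 32 / (2 * 8))
})

test_that("rank-form AUC equals trapezoidal ROC integration", {
  set.seed(43)
  for (r in 1:50) {
    n <- sample(6:20, 1)
    y <- ifelse(runif(n) < 0.4, "positive", "negative")
    if (length(unique(y)) < 2) next
    sc <- round(runif(n), 2)  # ties included
    expect_equal(auc_rank(sc, y), auc_trapezoid(sc, y), tolerance = 1e-12)
  }
})

test_that("LOOCV classification is perfect with an oracle feature", {
  set.seed(44)
  y <- two_class_labels(6, 10)
  X <- matrix(rnorm(16 * 5), 16, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[, 2] <- ifelse(y == "positive", 1, -1) + rnorm(16, sd = 0.01)
  res <- loocv_binary(X, y, method = "kw", k_max = 3)
  expect_equal(res$per_k$accuracy[1], 100)
  expect_equal(res$optimal_k, 1L)
  # metrics identity against the per-fold confusion at the optimal K
  m <- confusion_metrics(res$per_fold$truth, res$per_fold$pred)
  row <- res$per_k[res$per_k$k == res$optimal_k, ]
  expect_equal(row$accuracy, m$accuracy)
  expect_equal(row$f1, 2 * m$precision * (m$sensitivity / 100) /
                 (m$precision + m$sensitivity / 100))
  # every subject appears exactly once as test
  expect_equal(nrow(res$per_fold), 16)
  # determinism
  res2 <- loocv_binary(X, y, method = "kw", k_max = 3)
  expect_identical(res$per_k, res2$per_k)
})

test_that("leaky ranking inflates null accuracy over the honest protocol", {
  set.seed(45)
  y <- two_class_labels(10, 14)
  X <- matrix(rnorm(24 * 60), 24, 60,
              dimnames = list(NULL, paste0("f", 1:60)))
  honest <- loocv_binary(X, y, method = "kw", k_max = 5)
  leaky <- loocv_binary(X, y, method = "kw", k_max = 5, leaky = TRUE)
  expect_gt(max(leaky$per_k$accuracy), max(honest$per_k$accuracy) + 10)
})

test_that("LOOCV regression recovers a noiseless realizable model", {
  set.seed(46)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  delta <- -40 + 8 * X[, 1] - 6 * X[, 2] + 4 * X[, 3]
  res <- loocv_regression(X, delta, method = "kw", k_max = 8)
  best <- res$per_k[res$per_k$k == res$optimal_k, ]
  expect_gt(best$correlation, 0.99)
  expect_lt(best$rmse, 1e-6)
})

test_that("Holm adjustment reproduces the step-down arithmetic", {
  h1 <- correlation_pvalues_holm(0.5, 30)
  expect_equal(h1$adjusted, h1$raw)
  # raw {0.01, 0.04} with m = 2 -> {0.02, 0.04}
  r_for_p <- function(p, n) {
    tq <- qt(1 - p / 2, n - 2)
    tq / sqrt(n - 2 + tq^2)
  }
  rs <- c(r_for_p(0.01, 20), r_for_p(0.04, 20))
  h2 <- correlation_pvalues_holm(rs, 20)
  expect_equal(h2$raw, c(0.01, 0.04), tolerance = 1e-10)
  expect_equal(h2$adjusted, c(0.02, 0.04), tolerance = 1e-10)
  expect_true(all(h2$adjusted >= h2$raw))
  # raw p agrees with cor.test
  set.seed(47)
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(correlation_pvalues_holm(cor(x, y), 25)$raw,
               cor.test(x, y)$p.value, tolerance = 1e-10)
})

test_that("backward elimination drops inert predictors before planted ones", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(2000 + s)
    X <- matrix(rnorm(32 * 8), 32, 8,
                dimnames = list(NULL, c(paste0("sig", 1:3),
                                        paste0("jnk", 1:5))))
    y <- 10 + 5 * X[, 1] - 4 * X[, 2] + 3 * X[, 3] + rnorm(32, sd = 2)
    be <- fullfit_backward_eliminate(X, y)
    removed <- be$steps$removed[1:5]
    if (all(grepl("^jnk", removed[!is.na(removed)]))) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("backward elimination keeps a single predictor unchanged", {
  set.seed(48)
  X <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "only"))
  y <- 2 + 3 * X[, 1] + rnorm(20)
  be <- fullfit_backward_eliminate(X, y)
  expect_equal(be$best$predictors, "only")
  expect_equal(nrow(be$steps), 1)
  expect_equal(unname(be$best$coefficients),
               unname(coef(lm(y ~ X))), tolerance = 1e-10)
})

test_that("ensemble rules implement soft voting and averaging", {
  sv <- ensemble_soft_vote(0.9, 0.3)
  expect_equal(sv$prob, 0.6)
  expect_equal(as.character(sv$label), "positive")
  # boundary 0.5 is positive
  expect_equal(as.character(ensemble_soft_vote(0.5, 0.5)$label), "positive")
  expect_equal(as.character(ensemble_soft_vote(0.4, 0.5)$label), "negative")
  # idempotence with identical members
  p <- c(0.2, 0.7, 0.5)
  expect_equal(ensemble_soft_vote(p, p)$prob, p)
  expect_equal(ensemble_average_prediction(-60, -40), -50)
  expect_equal(ensemble_average_prediction(p, p), p)
  # member B = A + c: ensemble RMSE is |c|/2 when A is perfect
  set.seed(49)
  truth <- rnorm(20)
  ens <- ensemble_average_prediction(truth, truth + 6)
  expect_equal(sqrt(mean((ens - truth)^2)), 3, tolerance = 1e-12)
})

test_that("occurrence counting credits elements and member networks", {
  oc <- feature_occurrence_counts(list(c("pDMN__lVN2", "pDMN__BGN")))
  expect_equal(unname(oc$element[c("pDMN__BGN", "pDMN__lVN2")]), c(1L, 1L))
  expect_equal(unname(oc$network["pDMN"]), 2L)
  expect_equal(unname(oc$network["lVN2"]), 1L)
  expect_equal(unname(oc$network["BGN"]), 1L)
  empty <- feature_occurrence_counts(list())
  expect_equal(length(empty$element), 0)
  # conservation: element counts sum to the total number of selections
  sel <- list(c("a__b", "c__d"), c("a__b", "a__c"), "c__d")
  oc2 <- feature_occurrence_counts(sel)
  expect_equal(sum(oc2$element), length(unlist(sel)))
})
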