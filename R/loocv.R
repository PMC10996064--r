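rank_features <- function(X, labels, method, cost = 1) {
  switch(method,
         kw = rank_kruskal_wallis(X, labels),
         svm_rfe = rank_svm_rfe(X, labels, cost = cost),
         stop("unknown ranking method: ", method))
}

zscore_train_test <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

platt_probability <- function(decision_train, y_train, decision_test) {
  df <- data.frame(d = decision_train, y = as.integer(y_train == "positive"))
  fit <- suppressWarnings(stats::glm(y ~ d, data = df,
                                     family = stats::binomial()))
  as.numeric(suppressWarnings(
    stats::predict(fit, newdata = data.frame(d = decision_test),
                   type = "response")))
}

#' Leave-one-out binary outcome classification with a K sweep
#'
#' For each number of selected features K in `1..k_max` an independent
#' LOOCV is run: within each fold the features are ranked on the training
#' subjects only (Kruskal-Wallis or SVM-RFE), the top K are z-scored by
#' training-fold statistics, a class-weighted linear SVM (penalty
#' inversely proportional to class frequency) is fitted, and the held-out
#' subject is predicted. A positive-class probability is obtained by
#' logistic (Platt) calibration of the training-fold decision values.
#' Metrics (accuracy, sensitivity, specificity in percent; precision, F1,
#' AUC) are pooled over folds per K; the optimal K maximises accuracy,
#' smallest K on ties.
#'
#' @param X n x p numeric feature matrix with column names.
#' @param labels Outcome labels `negative`/`positive` (both classes >= 2).
#' @param method `"kw"` (Kruskal-Wallis, default) or `"svm_rfe"`.
#' @param k_max Largest K (default 20, capped at p).
#' @param cost SVM cost (default 1).
#' @param leaky If `TRUE`, rank features on ALL subjects before the LOOCV
#'   (deliberately breaks fold hygiene; for leakage regression tests only).
#' @return Object of class `loocv_binary`: `per_k` metrics data frame,
#'   `optimal_k`, `per_fold` (predictions at the optimal K),
#'   `selections` (per-K list of per-fold selected features),
#'   `occurrences` (selection counts at the optimal K), `method`.
#' @export
loocv_binary <- function(X, labels, method = c("kw", "svm_rfe"),
                         k_max = 20L, cost = 1, leaky = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- factor(as.character(labels), levels = c("negative", "positive"))
  n <- nrow(X)
  stopifnot(!is.null(colnames(X)), length(y) == n, n >= 4)
  if (min(table(y)) < 2) stop("both classes need at least 2 subjects")
  k_max <- min(k_max, ncol(X))
  ks <- seq_len(k_max)
  leaky_rank <- if (leaky) rank_features(scale(X), y, method, cost) else NULL

  pred <- matrix(NA_character_, n, k_max)
  prob <- matrix(NA_real_, n, k_max)
  selections <- lapply(ks, function(k) vector("list", n))
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      stop("training set of fold ", i, " contains a single class")
    }
    z <- zscore_train_test(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    rk <- if (leaky) leaky_rank else rank_features(z$train, ytr, method, cost)
    cw <- svm_class_weights(ytr)
    for (k in ks) {
      sel <- rk$order[seq_len(k)]
      selections[[k]][[i]] <- sel
      fit <- e1071::svm(z$train[, sel, drop = FALSE], ytr,
                        kernel = "linear", cost = cost,
                        class.weights = cw, scale = FALSE)
      pr_tr <- stats::predict(fit, z$train[, sel, drop = FALSE],
                              decision.values = TRUE)
      d_tr <- drop(attr(pr_tr, "decision.values"))
      pr_te <- stats::predict(fit, z$test[, sel, drop = FALSE],
                              decision.values = TRUE)
      d_te <- drop(attr(pr_te, "decision.values"))
      pred[i, k] <- as.character(pr_te)
      prob[i, k] <- platt_probability(d_tr, ytr, d_te)
    }
  }
  per_k <- do.call(rbind, lapply(ks, function(k) {
    m <- confusion_metrics(y, pred[, k])
    data.frame(k = k, accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, precision = m$precision,
               f1 = m$f1, auc = auc_rank(prob[, k], y))
  }))
  opt <- per_k$k[which.max(per_k$accuracy)]  # which.max takes smallest tie
  ids <- if (is.null(rownames(X))) as.character(seq_len(n)) else rownames(X)
  per_fold <- data.frame(id = ids, truth = as.character(y),
                         pred = pred[, opt], prob = prob[, opt],
                         stringsAsFactors = FALSE)
  occ <- table(unlist(selections[[opt]]))
  structure(list(per_k = per_k, optimal_k = opt, per_fold = per_fold,
                 selections = selections,
                 occurrences = occ, method = method),
            class = "loocv_binary")
}

fit_ols_predict <- function(Xtr, ytr, Xte) {
  Xd <- cbind(1, Xtr)
  fit <- stats::lm.fit(Xd, ytr)
  beta <- fit$coefficients
  dropped <- names(beta)[is.na(beta)]
  beta[is.na(beta)] <- 0
  list(pred = drop(cbind(1, Xte) %*% beta), dropped = dropped)
}

#' Leave-one-out continuous severity-change prediction with a k sweep
#'
#' For each k in `1..k_max`: within each fold, features are ranked on the
#' training subjects (the Kruskal-Wallis selector uses the training fold's
#' binary outcome labels derived from the -50% response threshold), the
#' top k enter an OLS multiple regression fitted on the training fold, and
#' the held-out subject's percent HDRS change is predicted. Per k the
#' Pearson correlation, RMSE and MAE between predicted and actual changes
#' are pooled over folds; the optimal k maximises the correlation.
#'
#' @param X n x p feature matrix with column names.
#' @param delta Actual percent HDRS change per subject.
#' @param method `"kw"` or `"svm_rfe"` ranking (default `"kw"`).
#' @param k_max Largest k (default 20, capped at p and n - 3).
#' @param labels Optional binary labels used by the ranking; default
#'   `label_outcome(delta)`.
#' @param leaky If `TRUE`, rank on all subjects (hygiene tests only).
#' @return Object of class `loocv_regression`: `per_k` (k, correlation,
#'   rmse, mae), `optimal_k`, `predictions` (at optimal k), `selections`,
#'   `method`.
#' @export
loocv_regression <- function(X, delta, method = c("kw", "svm_rfe"),
                             k_max = 20L, labels = NULL, leaky = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(!is.null(colnames(X)), length(delta) == n, n >= 6)
  if (is.null(labels)) labels <- label_outcome(delta)
  y <- factor(as.character(labels), levels = c("negative", "positive"))
  k_max <- min(k_max, ncol(X), n - 3L)
  ks <- seq_len(k_max)
  leaky_rank <- if (leaky) rank_features(scale(X), y, method) else NULL
  pred <- matrix(NA_real_, n, k_max)
  selections <- lapply(ks, function(k) vector("list", n))
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      stop("training set of fold ", i, " contains a single class for ranking")
    }
    z <- zscore_train_test(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    rk <- if (leaky) leaky_rank else rank_features(z$train, ytr, method)
    for (k in ks) {
      sel <- rk$order[seq_len(k)]
      selections[[k]][[i]] <- sel
      fp <- fit_ols_predict(X[-i, sel, drop = FALSE], delta[-i],
                            X[i, sel, drop = FALSE])
      pred[i, k] <- fp$pred
    }
  }
  per_k <- do.call(rbind, lapply(ks, function(k) {
    e <- pred[, k] - delta
    data.frame(k = k,
               correlation = stats::cor(pred[, k], delta),
               rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
  }))
  opt <- per_k$k[which.max(per_k$correlation)]
  structure(list(per_k = per_k, optimal_k = opt,
                 predictions = data.frame(actual = delta,
                                          predicted = pred[, opt]),
                 selections = selections, method = method),
            class = "loocv_regression")
}

#' Holm-adjusted p-values for correlations
#'
#' Two-sided t-test p-value for each Pearson correlation
#' (`t = r * sqrt((n-2)/(1-r^2))`, n - 2 df), step-down Holm-Bonferroni
#' adjusted across the family.
#'
#' @param correlations Correlation coefficients (|r| < 1).
#' @param ns Sample sizes (recycled; each > 3).
#' @param m Family size for the adjustment (default: number of
#'   correlations).
#' @return List with `raw` and `adjusted` p-value vectors.
#' @export
correlation_pvalues_holm <- function(correlations, ns,
                                     m = length(correlations)) {
  stopifnot(all(abs(correlations) < 1), all(ns > 3),
            m >= length(correlations))
  ns <- rep_len(ns, length(correlations))
  tval <- correlations * sqrt((ns - 2) / (1 - correlations^2))
  raw <- 2 * stats::pt(-abs(tval), df = ns - 2)
  list(raw = raw, adjusted = stats::p.adjust(raw, method = "holm", n = m))
}

#' Full-data regression with backward elimination
#'
#' Fits an OLS model of the severity change on all supplied predictors,
#' then repeatedly removes the predictor with the highest p-value (ties:
#' higher column index first), recording the F-statistic, RMSE and
#' adjusted R-squared at every step down to a single predictor. The
#' returned model maximises adjusted R-squared; ties favour the smaller
#' model. For numerically saturated fits (residual variance ~ 0) a
#' predictor's p-value is taken as 1 when its coefficient is numerically
#' zero and 0 otherwise, so inert predictors are eliminated first.
#'
#' @param X n x k numeric predictor matrix with column names (full rank).
#' @param y Severity change (percent) per subject.
#' @return Object of class `backward_elimination`: `steps` data frame
#'   (`n_predictors`, `fstat`, `rmse`, `adj_r2`, `removed`), `best` list
#'   (`predictors`, `coefficients` incl. intercept, `pvalues`, `fstat`,
#'   `rmse`, `adj_r2`).
#' @export
fullfit_backward_eliminate <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(!is.null(colnames(X)), nrow(X) == length(y),
            nrow(X) > ncol(X) + 1)
  remaining <- colnames(X)
  steps <- list()
  models <- list()
  repeat {
    Xd <- cbind("(Intercept)" = 1, X[, remaining, drop = FALSE])
    fit <- stats::lm.fit(Xd, y)
    res <- fit$residuals
    p_pred <- length(remaining)
    df <- length(y) - p_pred - 1
    s2 <- sum(res^2) / df
    XtXinv <- chol2inv(chol(crossprod(Xd)))
    beta <- fit$coefficients
    saturated <- s2 < 1e-18 * max(mean(y^2), 1)
    if (saturated) {
      tol <- 1e-6 * max(1, max(abs(beta)))
      pvals <- ifelse(abs(beta) < tol, 1, 0)
    } else {
      se <- sqrt(s2 * diag(XtXinv))
      pvals <- 2 * stats::pt(-abs(beta / se), df = df)
    }
    names(pvals) <- colnames(Xd)
    tss <- sum((y - mean(y))^2)
    rss <- sum(res^2)
    r2 <- 1 - rss / tss
    adj_r2 <- 1 - (1 - r2) * (length(y) - 1) / df
    fstat <- if (saturated) Inf else
      (tss - rss) / p_pred / s2
    rmse <- sqrt(mean(res^2))
    models[[length(models) + 1]] <- list(predictors = remaining,
                                         coefficients = beta,
                                         pvalues = pvals,
                                         fstat = fstat, rmse = rmse,
                                         adj_r2 = adj_r2)
    if (p_pred == 1L) {
      steps[[length(steps) + 1]] <- data.frame(
        n_predictors = p_pred, fstat = fstat, rmse = rmse,
        adj_r2 = adj_r2, removed = NA_character_)
      break
    }
    pp <- pvals[remaining]
    idx <- match(remaining, colnames(X))
    worst <- remaining[order(-pp, -idx)][1]
    steps[[length(steps) + 1]] <- data.frame(
      n_predictors = p_pred, fstat = fstat, rmse = rmse,
      adj_r2 = adj_r2, removed = worst)
    remaining <- setdiff(remaining, worst)
  }
  steps <- do.call(rbind, steps)
  best_i <- order(-steps$adj_r2, steps$n_predictors)[1]
  structure(list(steps = steps, best = models[[best_i]]),
            class = "backward_elimination")
}

#' Soft-voting ensemble of two classifiers
#'
#' Averages the positive-class probabilities of two member classifiers;
#' the ensemble predicts `positive` when the averaged probability is at
#' least 0.5.
#'
#' @param prob_a,prob_b Positive-class probabilities in 0..1
#'   (vectorised).
#' @return List with `prob` and factor `label`.
#' @export
ensemble_soft_vote <- function(prob_a, prob_b) {
  stopifnot(all(prob_a >= 0 & prob_a <= 1), all(prob_b >= 0 & prob_b <= 1))
  p <- (prob_a + prob_b) / 2
  list(prob = p,
       label = factor(ifelse(p >= 0.5, "positive", "negative"),
                      levels = c("negative", "positive")))
}

#' Prediction-averaging ensemble of two regression models
#'
#' Arithmetic mean of the two members' predicted severity changes.
#'
#' @param pred_a,pred_b Predicted percent HDRS changes (finite).
#' @return Averaged predictions.
#' @export
ensemble_average_prediction <- function(pred_a, pred_b) {
  stopifnot(all(is.finite(pred_a)), all(is.finite(pred_b)))
  (pred_a + pred_b) / 2
}

#' Feature and network occurrence counts
#'
#' Sums how often each feature element was selected across folds and
#' analyses; for pairwise elements (names of the form `A__B`) each
#' selection also increments both member networks' counts.
#'
#' @param selections List (possibly nested) of character vectors of
#'   selected feature names.
#' @return List with named integer vectors `element` and `network`.
#' @export
feature_occurrence_counts <- function(selections) {
  sel <- unlist(selections, use.names = FALSE)
  if (is.null(sel) || length(sel) == 0) {
    return(list(element = integer(0), network = integer(0)))
  }
  element <- table(sel)
  nets <- unlist(strsplit(sel, "__", fixed = TRUE), use.names = FALSE)
  network <- table(nets)
  list(element = stats::setNames(as.integer(element), names(element)),
       network = stats::setNames(as.integer(network), names(network)))
}
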