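#' Kruskal-Wallis feature ranking
#'
#' Ranks feature columns by the Kruskal-Wallis rank test of the two
#' outcome groups, computed column-wise (tie-corrected H statistic,
#' chi-squared p with 1 df). Columns are ordered by ascending p-value,
#' ties broken by descending H, then by column index. Constant columns get
#' p = 1, H = 0, are ranked last and flagged.
#'
#' @param X n x p numeric matrix with column names.
#' @param labels Binary labels (factor or character, two groups).
#' @return List of class `feature_ranking`: `method`, `order` (column
#'   names, best first), `scores` (p-values in original column order),
#'   `h` (H statistics), `flagged_constant`.
#' @export
rank_kruskal_wallis <- function(X, labels) {
  X <- as.matrix(X)
  stopifnot(!is.null(colnames(X)), nrow(X) == length(labels))
  g <- as.integer(factor(labels))
  if (length(unique(g)) != 2) stop("need exactly two label groups")
  n <- nrow(X)
  n1 <- sum(g == 1L)
  n2 <- n - n1
  if (n1 < 1 || n2 < 1) stop("each class needs at least one subject")
  H <- p <- numeric(ncol(X))
  const <- logical(ncol(X))
  for (k in seq_len(ncol(X))) {
    x <- X[, k]
    if (length(unique(x)) == 1L) {
      const[k] <- TRUE
      H[k] <- 0
      p[k] <- 1
      next
    }
    r <- rank(x)
    rbar1 <- mean(r[g == 1L])
    rbar2 <- mean(r[g == 2L])
    h <- 12 / (n * (n + 1)) *
      (n1 * (rbar1 - (n + 1) / 2)^2 + n2 * (rbar2 - (n + 1) / 2)^2)
    ties <- table(x)
    tiecorr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    h <- h / tiecorr
    H[k] <- h
    p[k] <- stats::pchisq(h, df = 1, lower.tail = FALSE)
  }
  ord <- order(p, -H, seq_len(ncol(X)))
  structure(list(method = "kruskal_wallis",
                 order = colnames(X)[ord],
                 scores = stats::setNames(p, colnames(X)),
                 h = stats::setNames(H, colnames(X)),
                 flagged_constant = colnames(X)[const]),
            class = "feature_ranking")
}

svm_weight_vector <- function(model) {
  drop(crossprod(model$coefs, model$SV))
}

#' SVM recursive feature elimination ranking
#'
#' Repeatedly fits a class-weighted linear SVM and removes the column with
#' the smallest absolute weight (one per round); the ranking is the
#' reverse elimination order, so the last surviving column ranks first.
#' Weight-magnitude ties are broken by removing the higher column index.
#' Features are expected to be standardised by the caller.
#'
#' @param X n x p numeric matrix with column names (standardised).
#' @param labels Binary labels.
#' @param cost SVM cost parameter (default 1).
#' @param class_weights Named per-class misclassification weights; default
#'   inverse class frequency via [svm_class_weights()].
#' @return List of class `feature_ranking`: `method`, `order` (best
#'   first), `scores` (elimination round per column; higher = survived
#'   longer).
#' @export
rank_svm_rfe <- function(X, labels, cost = 1, class_weights = NULL) {
  X <- as.matrix(X)
  stopifnot(!is.null(colnames(X)), nrow(X) == length(labels))
  y <- factor(labels)
  if (nlevels(y) != 2) stop("need exactly two label groups")
  if (is.null(class_weights)) class_weights <- svm_class_weights(y)
  remaining <- colnames(X)
  eliminated <- character(0)
  while (length(remaining) > 1) {
    fit <- tryCatch(
      e1071::svm(X[, remaining, drop = FALSE], y, kernel = "linear",
                 cost = cost, class.weights = class_weights,
                 scale = FALSE),
      error = function(e) stop("SVM fit failed during RFE with ",
                               length(remaining), " features: ",
                               conditionMessage(e)))
    w <- abs(svm_weight_vector(fit))
    # ties: drop the higher-indexed (later) column
    idx <- match(remaining, colnames(X))
    drop_k <- remaining[order(w, -idx)][1]
    eliminated <- c(eliminated, drop_k)
    remaining <- setdiff(remaining, drop_k)
  }
  ord <- c(remaining, rev(eliminated))
  rounds <- stats::setNames(match(colnames(X), rev(ord)), colnames(X))
  structure(list(method = "svm_rfe", order = ord, scores = rounds),
            class = "feature_ranking")
}

#' Class weights inversely proportional to class frequency
#'
#' Weight for class c is `n / (2 * n_c)`, so the minority class incurs a
#' proportionally higher misclassification penalty (the majority/minority
#' weight ratio equals the sample-size ratio).
#'
#' @param labels Binary labels.
#' @return Named numeric vector of per-class weights.
#' @export
svm_class_weights <- function(labels) {
  y <- factor(labels)
  tab <- table(y)
  stats::setNames(as.numeric(length(y) / (2 * tab)), names(tab))
}
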