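#' Canonical double-gamma haemodynamic response function
#'
#' SPM-convention HRF: a gamma density peaking at 6 s minus a later
#' undershoot gamma (peak 16 s) scaled by 1/ratio, normalised to unit peak.
#'
#' @param t Time points in seconds (>= 0).
#' @param peak_s Response peak delay (default 6 s).
#' @param under_s Undershoot peak delay (default 16 s).
#' @param ratio Response/undershoot amplitude ratio (default 6).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, under_s = 16, ratio = 6) {
  stopifnot(all(t >= 0))
  h <- stats::dgamma(t, shape = peak_s, rate = 1) -
    stats::dgamma(t, shape = under_s, rate = 1) / ratio
  h / max(h)
}

#' Assemble a task design matrix
#'
#' One boxcar per condition over the block design, convolved with the
#' canonical HRF sampled at the TR, plus an intercept, plus any nuisance
#' columns appended unchanged. Conditions with zero total duration are an
#' error; a rank-deficient result is an error naming the collinear columns.
#'
#' @param block_design Data frame with columns `condition` and `n_volumes`
#'   (one row per block, in scan order), e.g. from [default_block_design()].
#' @param tr_seconds Repetition time in seconds.
#' @param nuisance Optional T x Q numeric matrix of nuisance regressors
#'   (motion, physiological recordings, ...), consumed as given.
#' @param hrf_params Optional list overriding `peak_s`, `under_s`, `ratio`.
#' @return List of class `fmri_design`: `X` (T x P matrix with named
#'   columns, intercept first), `conditions`, `tr_seconds`.
#' @export
build_design <- function(block_design, tr_seconds, nuisance = NULL,
                         hrf_params = list()) {
  stopifnot(is.data.frame(block_design),
            all(c("condition", "n_volumes") %in% names(block_design)))
  n_vol <- sum(block_design$n_volumes)
  conds <- unique(as.character(block_design$condition))
  box <- sapply(conds, function(cc) {
    b <- rep(0, n_vol)
    pos <- 1L
    for (k in seq_len(nrow(block_design))) {
      len <- block_design$n_volumes[k]
      if (len > 0 && as.character(block_design$condition[k]) == cc) {
        b[pos:(pos + len - 1)] <- 1
      }
      pos <- pos + len
    }
    b
  })
  if (any(colSums(box) == 0)) {
    stop("condition with zero duration: ",
         paste(conds[colSums(box) == 0], collapse = ", "))
  }
  hp <- utils::modifyList(list(peak_s = 6, under_s = 16, ratio = 6), hrf_params)
  t_hrf <- seq(0, 32, by = tr_seconds)
  h <- hrf_double_gamma(t_hrf, hp$peak_s, hp$under_s, hp$ratio)
  conv1 <- function(b) {
    full <- stats::convolve(b, rev(h), type = "open")
    full[seq_len(n_vol)]
  }
  Xc <- apply(box, 2, conv1)
  colnames(Xc) <- conds
  X <- cbind(intercept = 1, Xc)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_vol) stop("nuisance rows must match the volume count")
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    }
    X <- cbind(X, nuisance)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, conditions = conds, tr_seconds = tr_seconds),
            class = "fmri_design")
}

#' GLM contrast t-value for one time-series
#'
#' Ordinary least squares fit of the series on the design; the contrast
#' t-value is `c'b / sqrt(s2 * c'(X'X)^-1 c)` with residual degrees of
#' freedom `T - rank(X)`. A numerically zero residual variance with a
#' non-zero contrast estimate yields a signed infinite t, flagged.
#'
#' @param series Numeric series of length T.
#' @param design An `fmri_design` from [build_design()].
#' @param contrast Named numeric vector of contrast weights over design
#'   columns (unnamed columns get weight 0), e.g.
#'   `c(faces = 1, shapes = -1)` for Faces > Shapes.
#' @return List with `t`, `df`, `beta`, `flagged_infinite`.
#' @export
glm_tvalues <- function(series, design, contrast) {
  stopifnot(inherits(design, "fmri_design"))
  X <- design$X
  stopifnot(length(series) == nrow(X))
  cn <- colnames(X)
  cv <- rep(0, ncol(X))
  names(cv) <- cn
  stopifnot(!is.null(names(contrast)), all(names(contrast) %in% cn))
  cv[names(contrast)] <- contrast
  if (all(cv == 0)) stop("contrast is all zero")
  fit <- stats::lm.fit(X, series)
  df <- length(series) - fit$rank
  s2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  est <- sum(cv * fit$coefficients)
  se2 <- s2 * drop(t(cv) %*% XtXinv %*% cv)
  flagged <- FALSE
  if (se2 <= .Machine$double.eps * sum(series^2) / length(series)) {
    tval <- sign(est) * Inf
    flagged <- TRUE
  } else {
    tval <- est / sqrt(se2)
  }
  list(t = tval, df = df, beta = fit$coefficients, flagged_infinite = flagged)
}

#' ROI-mean activation features
#'
#' Mean contrast t-value within each region of interest, for each contrast:
#' with 11 ROIs and the Faces > Shapes / Faces > Rest contrasts this yields
#' the 22 activation feature elements.
#'
#' @param tmaps Named list of per-voxel t-value vectors, one per contrast.
#' @param roi_masks Named list of voxel index vectors, one per ROI.
#' @return Named numeric vector `<roi>_<contrast>` of length
#'   `length(roi_masks) * length(tmaps)`.
#' @export
roi_activation_features <- function(tmaps, roi_masks) {
  stopifnot(is.list(tmaps), is.list(roi_masks),
            !is.null(names(tmaps)), !is.null(names(roi_masks)))
  empty <- names(roi_masks)[vapply(roi_masks, length, 1L) == 0]
  if (length(empty)) stop("empty ROI mask: ", paste(empty, collapse = ", "))
  out <- numeric(0)
  for (cc in names(tmaps)) {
    for (rr in names(roi_masks)) {
      idx <- roi_masks[[rr]]
      if (any(idx < 1 | idx > length(tmaps[[cc]]))) {
        stop("ROI mask out of range: ", rr)
      }
      out[paste(rr, cc, sep = "_")] <- mean(tmaps[[cc]][idx])
    }
  }
  out
}
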