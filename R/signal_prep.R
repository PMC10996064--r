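#' Estimate T2* and S0 from multi-echo signal decay
#'
#' Mono-exponential decay `S(TE) = S0 * exp(-TE / T2*)` is fit per voxel by
#' unweighted least squares on the log signal (`ln S = ln S0 - TE / T2*`).
#' Voxels whose fit yields a non-positive or non-finite T2* (flat or rising
#' decay, non-positive signals) are assigned a fallback value and flagged.
#'
#' @param signals Numeric vector of per-echo signals for one voxel, or a
#'   voxels x echoes matrix.
#' @param te_ms Echo times in milliseconds (length >= 2, all > 0).
#' @param fallback T2* (ms) used for failed fits. `NULL` (default) uses the
#'   median T2* of the valid voxels; with no valid voxel an error is raised.
#' @return List with numeric `t2star_ms`, `s0`, and logical `flagged`
#'   (one element per voxel).
#' @export
fit_t2star <- function(signals, te_ms, fallback = NULL) {
  if (length(te_ms) < 2) stop("at least 2 echoes are required to fit T2*")
  stopifnot(all(te_ms > 0))
  S <- if (is.matrix(signals)) signals else matrix(signals, nrow = 1)
  if (ncol(S) != length(te_ms)) stop("echo count of signals must match te_ms")
  nv <- nrow(S)
  t2 <- s0 <- rep(NA_real_, nv)
  flagged <- rep(FALSE, nv)
  X <- cbind(1, -te_ms)
  XtXinv <- solve(crossprod(X))
  for (v in seq_len(nv)) {
    s <- S[v, ]
    if (any(!is.finite(s)) || any(s <= 0)) {
      flagged[v] <- TRUE
      next
    }
    b <- XtXinv %*% crossprod(X, log(s))
    slope <- b[2]            # = 1 / T2*
    if (!is.finite(slope) || slope <= 1e-9) {  # flat or rising decay
      flagged[v] <- TRUE
      s0[v] <- exp(b[1])
      next
    }
    t2[v] <- 1 / slope
    s0[v] <- exp(b[1])
  }
  if (any(flagged)) {
    fb <- if (is.null(fallback)) {
      if (all(flagged)) stop("all voxels failed the T2* fit and no fallback was given")
      stats::median(t2[!flagged])
    } else {
      fallback
    }
    t2[flagged] <- fb
  }
  list(t2star_ms = t2, s0 = s0, flagged = flagged)
}

#' Echo-combination weights
#'
#' Weight for echo n given a voxel's T2*:
#' `w_n = TE_n * exp(-TE_n/T2*) / sum_i TE_i * exp(-TE_i/T2*)`.
#' Weights are non-negative and sum to one per voxel.
#'
#' @param te_ms Echo times in milliseconds.
#' @param t2star_ms Scalar or per-voxel T2* in milliseconds (> 0).
#' @return Matrix of weights (voxels x echoes); a single voxel gives 1 row.
#' @export
echo_weights <- function(te_ms, t2star_ms) {
  stopifnot(all(te_ms > 0))
  if (any(!is.finite(t2star_ms)) || any(t2star_ms <= 0)) {
    stop("t2star_ms must be positive and finite (resolve failed fits first)")
  }
  w <- outer(t2star_ms, te_ms, function(t2, te) te * exp(-te / t2))
  w / rowSums(w)
}

#' Optimally combine multi-echo time-series
#'
#' Weighted average of the per-echo signals using T2*-dependent weights from
#' [echo_weights()]. The combination is linear and convex, so identical
#' signals across echoes pass through unchanged.
#'
#' @param signals T x E matrix (time points x echoes), or a length-E vector.
#' @param te_ms Echo times in milliseconds, length E.
#' @param t2star_ms Scalar T2* (ms) for this voxel.
#' @return List with the combined `series` (length T) and the `weights` used.
#' @export
combine_echoes <- function(signals, te_ms, t2star_ms) {
  S <- if (is.matrix(signals)) signals else matrix(signals, nrow = 1)
  if (ncol(S) != length(te_ms)) stop("echo count of signals must match te_ms")
  w <- drop(echo_weights(te_ms, t2star_ms))
  list(series = drop(S %*% w), weights = w)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Second-order (by default) Butterworth bandpass applied forward and
#' backward (zero phase shift, squared magnitude response). The series is
#' padded by odd reflection at both ends before filtering to suppress edge
#' transients; output length equals input length.
#'
#' @param x Numeric series.
#' @param tr_seconds Sampling interval in seconds (fMRI TR).
#' @param low_hz,high_hz Passband edges in Hz (defaults 0.01 and 0.2).
#' @param order Butterworth order per edge (default 2).
#' @return Filtered series, same length as `x`.
#' @export
bandpass <- function(x, tr_seconds, low_hz = 0.01, high_hz = 0.2, order = 2L) {
  stopifnot(is.numeric(x), tr_seconds > 0)
  nyq <- 1 / (2 * tr_seconds)
  if (!(0 < low_hz && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyq) {
    stop(sprintf("high cutoff %.3g Hz must be below the Nyquist frequency %.3g Hz",
                 high_hz, nyq))
  }
  n <- length(x)
  if (n <= 3 * order) stop("series too short for the requested filter order")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  # odd reflection: 2*x[1] - x[k..2] prepended, mirrored at the tail
  np <- min(n - 1, 3 * (6 * order + 1))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(np + 1):(np + n)]
}
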