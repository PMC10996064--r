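#' Static functional connectivity (Fisher z)
#'
#' Fisher transform `atanh(r)` of the full-length Pearson correlation
#' between two series. Perfect correlations are capped at `1 - 1e-15` in
#' magnitude before the transform so the result stays finite.
#'
#' @param x,y Numeric series of equal length >= 3.
#' @return Fisher z value.
#' @export
static_fc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance series: static FC undefined")
  }
  r <- stats::cor(x, y)
  r <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  atanh(r)
}

#' Tapered sliding-window specification
#'
#' The window is a rectangle of `width_tr` TRs convolved with a Gaussian
#' (sigma = `gaussian_sigma_tr` TRs, truncated at +/- 3 sigma), then cut to
#' its central `width_tr` samples and normalised to sum 1: a flat-topped
#' taper used as observation weights inside each window.
#'
#' @param width_tr Window width in TRs (default 30, i.e. 40.5 s at
#'   TR = 1.35 s).
#' @param gaussian_sigma_tr Gaussian sigma in TRs (default 3).
#' @param step_tr Slide step in TRs (default 1).
#' @return List of class `sliding_window` with `width_tr`, `step_tr`,
#'   `taper` (length `width_tr`, sums to 1).
#' @export
sliding_window <- function(width_tr = 30L, gaussian_sigma_tr = 3,
                           step_tr = 1L) {
  stopifnot(width_tr >= 2, step_tr >= 1, gaussian_sigma_tr >= 0)
  if (gaussian_sigma_tr > 0) {
    half <- ceiling(3 * gaussian_sigma_tr)
    g <- stats::dnorm(seq(-half, half), sd = gaussian_sigma_tr)
    full <- stats::convolve(rep(1, width_tr), rev(g), type = "open")
    start <- (length(full) - width_tr) %/% 2
    taper <- full[start + seq_len(width_tr)]
  } else {
    taper <- rep(1, width_tr)
  }
  taper <- taper / sum(taper)
  structure(list(width_tr = as.integer(width_tr),
                 step_tr = as.integer(step_tr),
                 gaussian_sigma_tr = gaussian_sigma_tr,
                 taper = taper),
            class = "sliding_window")
}

#' Sliding-window start positions
#'
#' Integer start indices of the windows: starts run from 1 to
#' `T - width` in steps of `step` (the tapered window needs one further
#' sample of slack at the tail), giving `(T - width - 1) %/% step + 1`
#' windows; 380 volumes with width 30 and step 1 give 350 windows.
#'
#' @param n_time Series length in TRs.
#' @param window A [sliding_window()].
#' @return Integer vector of start indices (1-based).
#' @export
window_positions <- function(n_time, window) {
  stopifnot(inherits(window, "sliding_window"))
  if (n_time <= window$width_tr) {
    stop("series must be longer than the window width")
  }
  seq.int(1L, n_time - window$width_tr, by = window$step_tr)
}

weighted_pearson <- function(x, y, w) {
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Dynamic functional connectivity
#'
#' Taper-weighted Pearson correlation of the two series inside each sliding
#' window; the dFC statistic is the population standard deviation of the
#' per-window correlations. Windows with zero weighted variance are flagged:
#' if at most 5% of windows are flagged their correlation is imputed 0,
#' otherwise flagged windows are dropped from the standard deviation.
#'
#' @param x,y Numeric series of equal length.
#' @param window A [sliding_window()] (default: 30-TR width, sigma 3 TRs,
#'   step 1).
#' @param return_series If `TRUE`, also return the per-window correlations.
#' @return dFC value (>= 0), or a list with `dfc`, `window_r`, `n_flagged`
#'   when `return_series = TRUE`.
#' @export
dynamic_fc <- function(x, y, window = sliding_window(), return_series = FALSE) {
  stopifnot(length(x) == length(y))
  starts <- window_positions(length(x), window)
  w <- window$taper
  width <- window$width_tr
  r <- vapply(starts, function(s) {
    idx <- s:(s + width - 1L)
    weighted_pearson(x[idx], y[idx], w)
  }, numeric(1))
  flagged <- !is.finite(r)
  if (any(flagged)) {
    if (mean(flagged) <= 0.05) {
      r[flagged] <- 0
    } else {
      r <- r[!flagged]
    }
  }
  m <- mean(r)
  dfc <- sqrt(mean((r - m)^2))  # population sd
  if (return_series) {
    list(dfc = dfc, window_r = r, n_flagged = sum(flagged))
  } else {
    dfc
  }
}

#' Static and dynamic FC feature tables for one subject
#'
#' Computes [static_fc()] and [dynamic_fc()] for every unordered network
#' pair of a T x N time-series matrix. With 14 networks each table row has
#' 91 elements, named `<netA>__<netB>`.
#'
#' @param ts T x N numeric matrix with network labels as column names.
#' @param window A [sliding_window()].
#' @return List with named numeric vectors `sfc` and `dfc`.
#' @export
fc_features <- function(ts, window = sliding_window()) {
  stopifnot(is.matrix(ts), !is.null(colnames(ts)))
  pg <- pair_grid(colnames(ts))
  up <- pg$unordered
  sfc <- dfc <- stats::setNames(numeric(nrow(up)), up$name)
  for (k in seq_len(nrow(up))) {
    x <- ts[, up$i[k]]
    y <- ts[, up$j[k]]
    sfc[k] <- static_fc(x, y)
    dfc[k] <- dynamic_fc(x, y, window)
  }
  list(sfc = sfc, dfc = dfc)
}
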