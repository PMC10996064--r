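#' Continuous Morlet wavelet transform
#'
#' FFT-based CWT with an analytic Morlet mother wavelet (centre frequency
#' `omega0`, default 6). Scales are derived from the requested Fourier
#' periods via `period = 4*pi*s / (omega0 + sqrt(2 + omega0^2))`.
#'
#' @param x Numeric series.
#' @param dt Sampling interval in seconds.
#' @param periods_s Fourier periods (seconds) at which to evaluate.
#' @param omega0 Morlet centre frequency (default 6).
#' @return List with complex matrix `W` (periods x time), `periods_s`,
#'   `scales_s`, `coi_s` (e-folding time per time point).
#' @export
cwt_morlet <- function(x, dt, periods_s, omega0 = 6) {
  n <- length(x)
  stopifnot(n >= 8, all(is.finite(x)), dt > 0, all(periods_s > 0))
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods_s / fourier_factor
  np <- stats::nextn(n, 2)
  xh <- stats::fft(c(x - mean(x), rep(0, np - n)))
  k <- 0:(np - 1)
  omega <- 2 * pi * ifelse(k <= np / 2, k, k - np) / (np * dt)
  W <- matrix(0i, nrow = length(scales), ncol = n)
  pos <- omega > 0
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi_hat <- numeric(np)
    psi_hat[pos] <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    W[i, ] <- (stats::fft(xh * psi_hat, inverse = TRUE) / np)[seq_len(n)]
  }
  # cone of influence: e-folding distance sqrt(2)*s from either edge
  edge_dist <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt
  list(W = W, periods_s = periods_s, scales_s = scales,
       coi_s = edge_dist / sqrt(2), dt = dt, omega0 = omega0)
}

# Precomputed Gaussian row-smoother for a fixed grid: frequency-domain
# kernels per scale plus edge-correction norms (smoothed all-ones row).
make_row_smoother <- function(n, sd_samples) {
  np <- stats::nextn(2 * n, 2)
  k <- 0:(np - 1)
  om <- 2 * pi * ifelse(k <= np / 2, k, k - np) / np
  ones_hat <- stats::fft(c(rep(1, n), rep(0, np - n)))
  G <- matrix(0, length(sd_samples), np)
  NORM <- matrix(0, length(sd_samples), n)
  for (i in seq_along(sd_samples)) {
    G[i, ] <- exp(-(sd_samples[i] * om)^2 / 2)
    NORM[i, ] <- Re((stats::fft(ones_hat * G[i, ],
                                inverse = TRUE) / np)[seq_len(n)])
  }
  list(n = n, np = np, G = G, NORM = NORM)
}

# Gaussian smoothing of each row of a (complex) matrix, sd given per row in
# samples; FFT-based with zero padding, edge-corrected by normalising with a
# smoothed all-ones row.
smooth_rows_gauss <- function(M, sd_samples, smoother = NULL) {
  n <- ncol(M)
  if (is.null(smoother)) smoother <- make_row_smoother(n, sd_samples)
  np <- smoother$np
  out <- M
  for (i in seq_len(nrow(M))) {
    row_hat <- stats::fft(c(M[i, ], rep(0, np - n)))
    sm <- (stats::fft(row_hat * smoother$G[i, ],
                      inverse = TRUE) / np)[seq_len(n)]
    out[i, ] <- sm / smoother$NORM[i, ]
  }
  out
}

# 3-bin boxcar across rows (scales) with truncation at the edges
smooth_scales_boxcar <- function(M, width = 3L) {
  ns <- nrow(M)
  half <- width %/% 2
  out <- M
  for (i in seq_len(ns)) {
    rows <- max(1L, i - half):min(ns, i + half)
    out[i, ] <- colMeans(M[rows, , drop = FALSE])
  }
  out
}

#' Wavelet coherence between two series
#'
#' Magnitude-squared wavelet coherence and cross-spectrum phase on a
#' log-spaced period grid (default 50 periods from `2*dt` to `n*dt/4`).
#' The cross-spectrum and the two auto-spectra are divided by scale,
#' smoothed in time with a scale-proportional Gaussian and across scale
#' with a 3-bin boxcar before forming the coherence ratio. Positive phase
#' means the first series leads. Pixels inside the cone of influence are
#' marked valid; period bins shorter than `min_period_s` (default 5 s,
#' matching an upstream 0.2 Hz low-pass) are marked not retained.
#'
#' @param x,y Numeric series of equal length >= 64.
#' @param dt Sampling interval in seconds.
#' @param n_periods Number of period bins (default 50).
#' @param omega0 Morlet centre frequency (default 6).
#' @param min_period_s Shortest retained period in seconds (default 5).
#' @param periods_s Optional explicit period grid overriding `n_periods`.
#' @return Object of class `wcoh_map`: matrices `coherence` (in 0..1),
#'   `phase` (radians, (-pi, pi]), logical `coi` (TRUE = inside the cone,
#'   valid) and `retained`; vectors `periods_s`, `times_s`; scalar `dt`.
#' @export
wavelet_coherence <- function(x, y, dt, n_periods = 50L, omega0 = 6,
                              min_period_s = 5, periods_s = NULL) {
  n <- length(x)
  if (n < 64) stop("series too short for wavelet coherence (need >= 64 points)")
  stopifnot(length(y) == n, all(is.finite(x)), all(is.finite(y)))
  if (is.null(periods_s)) {
    periods_s <- exp(seq(log(2 * dt), log(n * dt / 4), length.out = n_periods))
  }
  wx <- cwt_morlet(x, dt, periods_s, omega0)
  wy <- cwt_morlet(y, dt, periods_s, omega0)
  scales <- wx$scales_s
  smoother <- make_row_smoother(n, scales / dt)
  Sxx <- smoothed_autospectrum(wx, smoother)
  Syy <- smoothed_autospectrum(wy, smoother)
  wcoh_from_cwt(wx, wy, Sxx, Syy, smoother, min_period_s)
}

smoothed_autospectrum <- function(w, smoother) {
  M <- (Mod(w$W)^2 + 0i) / w$scales_s
  Re(smooth_scales_boxcar(smooth_rows_gauss(M, smoother = smoother)))
}

wcoh_from_cwt <- function(wx, wy, Sxx, Syy, smoother, min_period_s) {
  n <- ncol(wx$W)
  scales <- wx$scales_s
  periods_s <- wx$periods_s
  Sxy <- smooth_scales_boxcar(
    smooth_rows_gauss((wx$W * Conj(wy$W)) / scales, smoother = smoother))
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  coh[!is.finite(coh)] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  coi <- outer(scales, wx$coi_s, function(s, cs) s <= cs)
  retained <- matrix(periods_s >= min_period_s, nrow = length(periods_s),
                     ncol = n)
  dt <- wx$dt
  structure(list(coherence = coh, phase = Arg(Sxy), coi = coi,
                 retained = retained, periods_s = periods_s,
                 times_s = (seq_len(n) - 1) * dt, dt = dt,
                 omega0 = wx$omega0),
            class = "wcoh_map")
}

#' Classify wavelet-coherence pixels by phase relation
#'
#' Pixels with coherence below the threshold, outside the cone of
#' influence, or in discarded period bins are labelled `none`. Remaining
#' pixels are classified by phase phi: `|phi| <= pi/4` in-phase;
#' `phi in (pi/4, 3pi/4)` the first series leads (`lead_12`);
#' `phi in (-3pi/4, -pi/4)` the second leads (`lead_21`);
#' `|phi| >= 3pi/4` anti-phase.
#'
#' @param map A `wcoh_map` from [wavelet_coherence()].
#' @param threshold Coherence cutoff in (0, 1) defining "any coherence"
#'   (default 0.5).
#' @param connectivity Pixel adjacency for downstream clustering, 4 or 8
#'   (default 8).
#' @param include_coi If `TRUE`, pixels outside the cone of influence are
#'   classified too (default `FALSE`).
#' @return Object of class `phase_class_map`: integer matrix `labels` with
#'   levels `none, in_phase, lead_12, lead_21, anti_phase` (codes 0-4),
#'   logical `valid`, plus the grid metadata.
#' @export
classify_phases <- function(map, threshold = 0.5, connectivity = 8L,
                            include_coi = FALSE) {
  stopifnot(inherits(map, "wcoh_map"), threshold > 0, threshold < 1,
            connectivity %in% c(4L, 8L))
  valid <- map$retained & (include_coi | map$coi)
  phi <- map$phase
  lab <- matrix(0L, nrow = nrow(phi), ncol = ncol(phi))
  coherent <- valid & map$coherence >= threshold
  ap <- abs(phi)
  lab[coherent & ap <= pi / 4] <- 1L                      # in_phase
  lab[coherent & ap > pi / 4 & ap < 3 * pi / 4 & phi > 0] <- 2L  # lead_12
  lab[coherent & ap > pi / 4 & ap < 3 * pi / 4 & phi < 0] <- 3L  # lead_21
  lab[coherent & ap >= 3 * pi / 4] <- 4L                  # anti_phase
  structure(list(labels = lab, valid = valid, threshold = threshold,
                 connectivity = as.integer(connectivity),
                 periods_s = map$periods_s, dt = map$dt,
                 retained_bins = map$retained[, 1]),
            class = "phase_class_map")
}

phase_class_levels <- function() {
  c("none", "in_phase", "lead_12", "lead_21", "anti_phase")
}

# Connected-component labelling of a logical matrix by flood fill.
# Returns an integer matrix of component ids (0 = background).
label_components <- function(fg, connectivity = 8L) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  }
  comp <- 0L
  idx <- which(fg)
  for (p in idx) {
    if (lab[p] != 0L) next
    comp <- comp + 1L
    stack <- p
    lab[p] <- comp
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- ((q - 1L) %% nr) + 1L
      c0 <- ((q - 1L) %/% nr) + 1L
      rr <- r0 + dr
      cc <- c0 + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[fg[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- comp
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Number of coherence clusters (nCC)
#'
#' Binarises the phase-class map (label 1 wherever any type of coherence
#' was assigned) and counts connected components over valid pixels under
#' the map's pixel connectivity. Components smaller than
#' `min_cluster_size` pixels are excluded (default 1: a lone coherent
#' pixel counts as a cluster).
#'
#' @param pmap A `phase_class_map` from [classify_phases()].
#' @param min_cluster_size Minimum component size in pixels (default 1).
#' @return Integer cluster count >= 0.
#' @export
count_coherence_clusters <- function(pmap, min_cluster_size = 1L) {
  stopifnot(inherits(pmap, "phase_class_map"))
  fg <- pmap$labels != 0L & pmap$valid
  lab <- label_components(fg, pmap$connectivity)
  if (max(lab) == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_cluster_size)
}

#' Lead coherence (leadCoh)
#'
#' For each retained period bin, the total time (pixel count times the
#' sampling interval) during which the requested series phase-leads the
#' other; leadCoh is the mean of these per-bin durations over the retained
#' bins, in seconds.
#'
#' @param pmap A `phase_class_map` from [classify_phases()].
#' @param direction `"1->2"` (first series leads, default) or `"2->1"`.
#' @return Lead coherence in seconds (>= 0).
#' @export
lead_coherence <- function(pmap, direction = c("1->2", "2->1")) {
  stopifnot(inherits(pmap, "phase_class_map"))
  direction <- match.arg(direction)
  code <- if (direction == "1->2") 2L else 3L
  keep <- pmap$retained_bins
  if (!any(keep)) stop("no retained period bins")
  lead <- (pmap$labels == code) & pmap$valid
  per_bin <- rowSums(lead[keep, , drop = FALSE]) * pmap$dt
  mean(per_bin)
}

#' Phase-class occupancy
#'
#' Number of valid pixels assigned to each phase class.
#'
#' @param pmap A `phase_class_map`.
#' @return Named integer vector over
#'   `in_phase, lead_12, lead_21, anti_phase`.
#' @export
phase_occupancy <- function(pmap) {
  stopifnot(inherits(pmap, "phase_class_map"))
  lv <- phase_class_levels()[-1]
  stats::setNames(vapply(1:4, function(k) {
    sum(pmap$labels == k & pmap$valid)
  }, integer(1)), lv)
}

#' Wavelet features for all network pairs of one subject
#'
#' Computes wavelet coherence for every unordered pair of the T x N
#' time-series matrix, classifies phases, and returns the nCC value per
#' unordered pair plus the leadCoh value per ordered pair. With 14
#' networks: 91 nCC and 182 leadCoh elements. Per-network wavelet
#' transforms are computed once and reused across pairs.
#'
#' @param ts T x N numeric matrix with network labels as column names.
#' @param tr_seconds Sampling interval in seconds.
#' @param threshold Coherence cutoff (default 0.5).
#' @param connectivity Pixel adjacency, 4 or 8 (default 8).
#' @param min_cluster_size Minimum cluster size (default 1).
#' @param n_periods Number of period bins (default 50).
#' @param omega0 Morlet centre frequency (default 6).
#' @param min_period_s Shortest retained period (default 5 s).
#' @return List with named numeric vectors `ncc` (unordered pairs) and
#'   `leadcoh` (ordered pairs; name `A__B` = time A leads B).
#' @export
pairwise_wavelet_features <- function(ts, tr_seconds, threshold = 0.5,
                                      connectivity = 8L,
                                      min_cluster_size = 1L,
                                      n_periods = 50L, omega0 = 6,
                                      min_period_s = 5) {
  stopifnot(is.matrix(ts), !is.null(colnames(ts)), ncol(ts) >= 2)
  pg <- pair_grid(colnames(ts))
  up <- pg$unordered
  ncc <- stats::setNames(numeric(nrow(up)), up$name)
  leadcoh <- stats::setNames(numeric(nrow(pg$ordered)), pg$ordered$name)
  n <- nrow(ts)
  if (n < 64) stop("series too short for wavelet coherence (need >= 64 points)")
  periods_s <- exp(seq(log(2 * tr_seconds), log(n * tr_seconds / 4),
                       length.out = n_periods))
  # per-network transforms and smoothed auto-spectra, reused across pairs
  cwts <- lapply(seq_len(ncol(ts)), function(i) {
    cwt_morlet(ts[, i], tr_seconds, periods_s, omega0)
  })
  smoother <- make_row_smoother(n, cwts[[1]]$scales_s / tr_seconds)
  autos <- lapply(cwts, smoothed_autospectrum, smoother = smoother)
  for (k in seq_len(nrow(up))) {
    i <- up$i[k]; j <- up$j[k]
    map <- wcoh_from_cwt(cwts[[i]], cwts[[j]], autos[[i]], autos[[j]],
                         smoother, min_period_s)
    pmap <- classify_phases(map, threshold, connectivity)
    ncc[k] <- count_coherence_clusters(pmap, min_cluster_size)
    ni <- pg$networks[i]; nj <- pg$networks[j]
    leadcoh[paste(ni, nj, sep = "__")] <- lead_coherence(pmap, "1->2")
    leadcoh[paste(nj, ni, sep = "__")] <- lead_coherence(pmap, "2->1")
  }
  list(ncc = ncc, leadcoh = leadcoh)
}
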