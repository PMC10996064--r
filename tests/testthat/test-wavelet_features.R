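make_map <- function(coherence, phase, periods_s = NULL, dt = 1.35,
                     coi = NULL) {
  np <- nrow(coherence)
  n <- ncol(coherence)
  if (is.null(periods_s)) periods_s <- seq(5, 100, length.out = np)
  if (is.null(coi)) coi <- matrix(TRUE, np, n)
  structure(list(coherence = coherence, phase = phase, coi = coi,
                 retained = matrix(periods_s >= 5, np, n),
                 periods_s = periods_s, times_s = (seq_len(n) - 1) * dt,
                 dt = dt, omega0 = 6),
            class = "wcoh_map")
}

test_that("coherent sinusoids give near-unit coherence at their period", {
  tr <- 1.35
  t <- (0:379) * tr
  x <- cos(2 * pi * t / 20)
  m <- wavelet_coherence(x, x + 0, tr)
  expect_equal(length(m$periods_s), 50)
  bin <- which.min(abs(m$periods_s - 20))
  inco <- m$coi[bin, ]
  expect_gt(mean(m$coherence[bin, inco]), 0.95)
  expect_lt(mean(abs(m$phase[bin, inco])), 0.1)
  # discarded short periods are excluded by the retained mask
  expect_true(all(!m$retained[m$periods_s < 5, ]))
  expect_true(all(m$coherence >= 0 & m$coherence <= 1))
})

test_that("a quarter-period delay appears as +pi/2 lead of the first series", {
  tr <- 1.35
  t <- (0:379) * tr
  x <- cos(2 * pi * t / 20)
  y <- cos(2 * pi * (t - 5) / 20)  # delayed: x leads
  m <- wavelet_coherence(x, y, tr)
  bin <- which.min(abs(m$periods_s - 20))
  expect_equal(mean(m$phase[bin, m$coi[bin, ]]), pi / 2, tolerance = 0.05)
  # classified as lead_12 at that period
  p <- classify_phases(m)
  expect_true(all(p$labels[bin, p$valid[bin, ]] == 2L))
})

test_that("independent noise keeps mean in-cone coherence below 0.5", {
  set.seed(14)
  m <- wavelet_coherence(rnorm(380), rnorm(380), 1.35)
  expect_lt(mean(m$coherence[m$coi]), 0.5)
})

test_that("phase classification follows the quadrant rule with boundaries", {
  co <- matrix(1, 4, 6)
  ph <- matrix(rep(c(0, pi / 2, -pi / 2, pi), 6), 4, 6)
  p <- classify_phases(make_map(co, ph), threshold = 0.5)
  expect_equal(unique(p$labels[1, ]), 1L)  # in phase
  expect_equal(unique(p$labels[2, ]), 2L)  # +pi/2 exactly -> lead_12
  expect_equal(unique(p$labels[3, ]), 3L)
  expect_equal(unique(p$labels[4, ]), 4L)
  # pi/4 boundary is in-phase (closed), 3pi/4 is anti-phase (closed)
  pb <- classify_phases(make_map(matrix(1, 2, 2),
                                 matrix(c(pi / 4, 3 * pi / 4), 2, 2)))
  expect_equal(unique(pb$labels[1, ]), 1L)
  expect_equal(unique(pb$labels[2, ]), 4L)
  # sub-threshold coherence is 'none' everywhere
  p0 <- classify_phases(make_map(matrix(0.2, 4, 6), ph), threshold = 0.5)
  expect_true(all(p0$labels == 0L))
  # exactly one class per valid coherent pixel (occupancy conservation)
  expect_equal(sum(phase_occupancy(p)), sum(p$labels != 0L & p$valid))
})

test_that("raising the threshold never adds coherent pixels", {
  set.seed(15)
  m <- wavelet_coherence(rnorm(380), rnorm(380), 1.35)
  n_low <- sum(classify_phases(m, 0.4)$labels != 0L)
  n_high <- sum(classify_phases(m, 0.7)$labels != 0L)
  expect_lte(n_high, n_low)
})

test_that("cluster counting matches hand-built maps", {
  lab <- matrix(0L, 20, 50)
  expect_equal(count_coherence_clusters(make_pmap(lab)), 0L)
  lab[3:4, 5:6] <- 1L
  lab[10:11, 30:31] <- 2L
  expect_equal(count_coherence_clusters(make_pmap(lab)), 2L)
  expect_equal(count_coherence_clusters(make_pmap(lab + 0L,
                                                  connectivity = 4L)), 2L)
  full <- matrix(1L, 20, 50)
  expect_equal(count_coherence_clusters(make_pmap(full)), 1L)
  # min_cluster_size filters lone pixels
  lone <- matrix(0L, 10, 10); lone[5, 5] <- 1L; lone[1:2, 1:2] <- 4L
  expect_equal(count_coherence_clusters(make_pmap(lone)), 2L)
  expect_equal(count_coherence_clusters(make_pmap(lone),
                                        min_cluster_size = 2), 1L)
  # diagonal touch merges under 8- but not 4-connectivity
  diag2 <- matrix(0L, 4, 4); diag2[1, 1] <- 1L; diag2[2, 2] <- 1L
  expect_equal(count_coherence_clusters(make_pmap(diag2)), 1L)
  expect_equal(count_coherence_clusters(make_pmap(diag2,
                                                  connectivity = 4L)), 2L)
  # invalid pixels cannot join clusters
  vmask <- matrix(TRUE, 20, 50); vmask[, 5:6] <- FALSE
  lab2 <- matrix(0L, 20, 50); lab2[3, 4:7] <- 1L
  expect_equal(count_coherence_clusters(make_pmap(lab2, valid = vmask)), 2L)
})

test_that("flood-fill labelling agrees with the graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(16)
  for (r in 1:100) {
    fg <- matrix(runif(15 * 30) < runif(1, 0.2, 0.6), 15, 30)
    conn <- if (r %% 2 == 0) 4L else 8L
    lab <- matrix(0L, 15, 30)
    lab[fg] <- 1L
    expect_equal(count_coherence_clusters(make_pmap(lab, connectivity = conn)),
                 count_components_igraph(fg, conn))
  }
})

test_that("lead coherence measures directional lead time per bin", {
  lab <- matrix(0L, 10, 40)
  p0 <- make_pmap(lab)
  expect_equal(lead_coherence(p0, "1->2"), 0)
  # saturation: every valid pixel leads 1->2
  lab12 <- matrix(2L, 10, 40)
  p12 <- make_pmap(lab12, dt = 1.35)
  expect_equal(lead_coherence(p12, "1->2"), 40 * 1.35)
  expect_equal(lead_coherence(p12, "2->1"), 0)
  # averaging over retained bins only
  labm <- matrix(0L, 4, 10)
  labm[1, 1:5] <- 2L
  pm <- make_pmap(labm, retained_bins = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(lead_coherence(pm, "1->2"), 5 * 1.35 / 2)
  expect_error(lead_coherence(make_pmap(labm,
                                        retained_bins = rep(FALSE, 4))),
               "retained")
})

test_that("planted lead produces directional leadCoh asymmetry", {
  spec <- cohort_spec(n_subjects = 1, n_networks = 2, seed = 23,
                      coherence_plan = list(
                        list(pair = c(1, 2), phase_class = "lead_12",
                             period_s = 20, epochs = list(c(40, 180),
                                                          c(220, 360)),
                             amplitude = 3)))
  ts <- generate_timeseries(spec, 1)
  m <- wavelet_coherence(ts[, 1], ts[, 2], 1.35)
  p <- classify_phases(m)
  expect_gt(lead_coherence(p, "1->2"), lead_coherence(p, "2->1"))
})

test_that("pairwise feature tables have the category dimensions", {
  spec <- cohort_spec(n_subjects = 1, n_networks = 4, seed = 19)
  ts <- generate_timeseries(spec, 1)
  wf <- pairwise_wavelet_features(ts, 1.35)
  expect_equal(length(wf$ncc), 6)   # 4 choose 2
  expect_equal(length(wf$leadcoh), 12)
  # swapping the two members of a pair: nCC invariant, leadCoh swapped
  ts2 <- ts[, c(2, 1, 3, 4)]
  wf2 <- pairwise_wavelet_features(ts2, 1.35)
  expect_equal(wf$ncc[["net1__net2"]], wf2$ncc[["net2__net1"]])
  expect_equal(wf$leadcoh[["net1__net2"]], wf2$leadcoh[["net1__net2"]])
  expect_equal(wf$leadcoh[["net2__net1"]], wf2$leadcoh[["net2__net1"]])
  expect_identical(wf, pairwise_wavelet_features(ts, 1.35))
})
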