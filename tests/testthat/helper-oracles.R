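# Independent oracles used across tests.

# Connected-component count via igraph on the pixel adjacency graph.
count_components_igraph <- function(fg, connectivity = 8L) {
  idx <- which(fg)
  if (!length(idx)) return(0L)
  nr <- nrow(fg)
  nc <- ncol(fg)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  if (connectivity == 4L) {
    shifts <- list(c(1L, 0L), c(0L, 1L))
  } else {
    shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  }
  edges <- integer(0)
  co <- arrayInd(idx, dim(fg))
  for (sh in shifts) {
    r2 <- co[, 1] + sh[1]
    c2 <- co[, 2] + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- fg[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      edges <- c(edges, rbind(id[idx[ok]], id[cbind(r2[ok], c2[ok])]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# Trapezoidal ROC integration (threshold sweep over unique scores).
auc_trapezoid <- function(scores, truth) {
  truth <- as.character(truth)
  pos <- truth == "positive"
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), 1), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), 1), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Minimal hand-built phase-class map for cluster/lead tests.
make_pmap <- function(labels, valid = NULL, dt = 1.35, connectivity = 8L,
                      retained_bins = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(labels), ncol(labels))
  if (is.null(retained_bins)) retained_bins <- rep(TRUE, nrow(labels))
  structure(list(labels = labels, valid = valid, threshold = 0.5,
                 connectivity = as.integer(connectivity),
                 periods_s = seq_len(nrow(labels)), dt = dt,
                 retained_bins = retained_bins),
            class = "phase_class_map")
}

# Features-only planted cohort: interaction counts + outcomes.
make_counts_cohort <- function(n = 32, seed = 5, noise_sd = 10) {
  spec <- cohort_spec(n_subjects = n, seed = seed,
                      outcome_model = default_outcome_model(noise_sd))
  coh <- generate_cohort(spec, plant_timeseries = FALSE)
  list(spec = spec, X = coh$ground_truth$counts,
       delta = coh$subjects$delta3m, labels = coh$subjects$label3m,
       planted = coh$subjects$delta_planted)
}

acq_te_ms <- c(11.3, 31.8, 52.3)
eq4_coefs <- c(SMN__pVN = -4.51, pDMN__lVN2 = -3.24, SMN__CN = -2.96,
               pDMN__BGN = -2.64, MTN__BGN = -2.54)
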