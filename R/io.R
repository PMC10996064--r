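fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read network time-series TSV
#'
#' Tab-separated, UTF-8, '.' decimal; header row holds the network labels,
#' one row per volume. Numbers are written with 17 significant digits so a
#' round trip is exact to within 1e-12 relative error.
#'
#' @param ts T x N numeric matrix with column names.
#' @param path File path.
#' @return `write_timeseries_tsv` returns `path` invisibly;
#'   `read_timeseries_tsv` returns the matrix.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(is.matrix(ts), !is.null(colnames(ts)))
  out <- apply(ts, 2, fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = colnames(ts))
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  first <- readLines(path, n = 1)
  toks <- strsplit(sub("\r$", "", first), "\t", fixed = TRUE)[[1]]
  if (all(!is.na(suppressWarnings(as.numeric(toks))))) {
    stop("missing header row in ", path)
  }
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!apply(df, 1, function(r) {
      all(!is.na(suppressWarnings(as.numeric(r))))
    }))[1]
    stop("malformed row ", bad + 1, " in ", path)
  }
  m
}

#' Write / read a subject table CSV
#'
#' Comma-separated with a header row and an `id` column.
#'
#' @param df Data frame of subject records.
#' @param path File path.
#' @export
write_subject_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  if (!"id" %in% names(df)) df <- cbind(id = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("subject table not found: ", path)
  utils::read.csv(path, check.names = FALSE)
}

#' Write / read a feature table CSV
#'
#' Subjects x feature-elements matrix as CSV; first column `id`, numeric
#' values written with full precision.
#'
#' @param X Numeric matrix with feature-element column names.
#' @param path File path.
#' @export
write_feature_table <- function(X, path) {
  stopifnot(is.matrix(X) || is.data.frame(X))
  X <- as.matrix(X)
  ids <- if (is.null(rownames(X))) seq_len(nrow(X)) else rownames(X)
  out <- cbind(id = ids, apply(X, 2, fmt_num))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(m) <- df$id
  m
}

roi_labels <- function() {
  c("amygdala_l", "amygdala_r", "hippocampus_l", "hippocampus_r",
    "parahippocampal_l", "parahippocampal_r", "fusiform_l", "fusiform_r",
    "vmPFC", "ACC", "sgACC")
}

# Synthetic ROI time-series: task-modulated signal per ROI (subject-specific
# condition amplitudes) on unit Gaussian noise, for the activation features.
generate_roi_series <- function(spec, subject_index) {
  design <- build_design(spec$block_design, spec$tr_seconds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_seed(spec, subject_index) + 13L)
  rois <- roi_labels()
  ts <- sapply(rois, function(r) {
    b_faces <- stats::rnorm(1, 1, 0.5)
    b_shapes <- stats::rnorm(1, 0.5, 0.3)
    design$X[, "faces"] * b_faces + design$X[, "shapes"] * b_shapes +
      stats::rnorm(spec$n_volumes)
  })
  colnames(ts) <- rois
  ts
}

# Activation features (11 ROIs x Faces>Shapes / Faces>Rest) for one subject.
activation_features <- function(roi_ts, spec) {
  design <- build_design(spec$block_design, spec$tr_seconds)
  contrasts <- list(FacesGtShapes = c(faces = 1, shapes = -1),
                    FacesGtRest = c(faces = 1, rest = -1))
  out <- numeric(0)
  for (cc in names(contrasts)) {
    for (r in colnames(roi_ts)) {
      tv <- glm_tvalues(roi_ts[, r], design, contrasts[[cc]])
      out[paste(r, cc, sep = "_")] <- tv$t
    }
  }
  out
}

#' Pipeline configuration
#'
#' Resolved set of knobs for [run_pipeline()], validated up front.
#'
#' @param n_subjects Cohort size (default 32).
#' @param seed RNG seed.
#' @param followups Follow-ups to analyse, subset of `c("3m", "6m")`.
#' @param selectors Feature selectors, subset of `c("kw", "svm_rfe")`.
#' @param categories Feature categories to run, subset of
#'   `c("demo_clin", "act", "sfc", "dfc", "leadcoh", "ncc")`.
#' @param k_max Feature-count sweep upper bound (default 20).
#' @param wca List of wavelet parameters (`threshold`, `connectivity`,
#'   `omega0`, `min_cluster_size`, `min_period_s`).
#' @param window `sliding_window()` parameters as a list (`width_tr`,
#'   `gaussian_sigma_tr`, `step_tr`).
#' @param filter Bandpass parameters (`low_hz`, `high_hz`, `order`).
#' @param out_dir Optional output directory; when given, all tables plus
#'   the resolved configuration are written there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 32L, seed = 1L,
                            followups = c("3m", "6m"),
                            selectors = "kw",
                            categories = c("demo_clin", "act", "sfc",
                                           "dfc", "leadcoh", "ncc"),
                            k_max = 20L,
                            wca = list(), window = list(), filter = list(),
                            out_dir = NULL) {
  stopifnot(all(followups %in% c("3m", "6m")),
            all(selectors %in% c("kw", "svm_rfe")),
            all(categories %in% c("demo_clin", "act", "sfc", "dfc",
                                  "leadcoh", "ncc")),
            k_max >= 1)
  wca <- utils::modifyList(list(threshold = 0.5, connectivity = 8L,
                                omega0 = 6, min_cluster_size = 1L,
                                min_period_s = 5), wca)
  window <- utils::modifyList(list(width_tr = 30L, gaussian_sigma_tr = 3,
                                   step_tr = 1L), window)
  filter <- utils::modifyList(list(low_hz = 0.01, high_hz = 0.2,
                                   order = 2L), filter)
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), followups = followups,
                 selectors = selectors, categories = categories,
                 k_max = as.integer(k_max), wca = wca, window = window,
                 filter = filter, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end synthetic-cohort pipeline
#'
#' Generates a synthetic cohort, bandpass-filters the network series,
#' extracts the six feature tables (demo+clin 20, Act 22, sFC 91, dFC 91,
#' leadCoh 182, nCC 91 elements), computes outcomes and labels, and runs
#' the prediction stack (per-category LOOCV binary classification and
#' continuous regression, soft-voting and prediction-averaging ensembles
#' with the demo+clin member fixed) for every requested follow-up and
#' selector. With `out_dir` set, feature tables, the subject table,
#' per-K metrics and the resolved configuration (JSON, including the seed)
#' are written out.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `config`, `cohort`,
#'   `features` (named list of matrices), `predictions` (nested by
#'   follow-up / selector / category, each with `binary` and
#'   `regression`), `ensembles`, `occurrences`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- cohort_spec(n_subjects = config$n_subjects, seed = config$seed)
  need_ts <- any(c("sfc", "dfc", "leadcoh", "ncc") %in% config$categories)
  cohort <- generate_cohort(spec, plant_timeseries = need_ts)
  n <- spec$n_subjects

  features <- list()
  if ("demo_clin" %in% config$categories) {
    features$demo_clin <- as.matrix(
      cohort$subjects[, seq_len(20), drop = FALSE])
  }
  if ("act" %in% config$categories) {
    features$act <- t(sapply(seq_len(n), function(s) {
      activation_features(generate_roi_series(spec, s), spec)
    }))
  }
  if (need_ts) {
    win <- sliding_window(config$window$width_tr,
                          config$window$gaussian_sigma_tr,
                          config$window$step_tr)
    filt <- lapply(cohort$timeseries, function(ts) {
      apply(ts, 2, bandpass, tr_seconds = spec$tr_seconds,
            low_hz = config$filter$low_hz, high_hz = config$filter$high_hz,
            order = config$filter$order)
    })
    if (any(c("sfc", "dfc") %in% config$categories)) {
      fcs <- lapply(filt, fc_features, window = win)
      if ("sfc" %in% config$categories) {
        features$sfc <- t(sapply(fcs, `[[`, "sfc"))
      }
      if ("dfc" %in% config$categories) {
        features$dfc <- t(sapply(fcs, `[[`, "dfc"))
      }
    }
    if (any(c("leadcoh", "ncc") %in% config$categories)) {
      wfs <- lapply(filt, function(ts) {
        pairwise_wavelet_features(
          ts, spec$tr_seconds, threshold = config$wca$threshold,
          connectivity = config$wca$connectivity,
          min_cluster_size = config$wca$min_cluster_size,
          omega0 = config$wca$omega0,
          min_period_s = config$wca$min_period_s)
      })
      if ("leadcoh" %in% config$categories) {
        features$leadcoh <- t(sapply(wfs, `[[`, "leadcoh"))
      }
      if ("ncc" %in% config$categories) {
        features$ncc <- t(sapply(wfs, `[[`, "ncc"))
      }
    }
  }
  for (nm in names(features)) rownames(features[[nm]]) <- seq_len(n)

  predictions <- list()
  ensembles <- list()
  occurrences <- list()
  for (fu in config$followups) {
    labels <- cohort$subjects[[paste0("label", fu)]]
    delta <- cohort$subjects[[paste0("delta", fu)]]
    for (selm in config$selectors) {
      method <- if (selm == "kw") "kw" else "svm_rfe"
      for (cat in names(features)) {
        key <- paste(fu, selm, cat, sep = ".")
        bin <- loocv_binary(features[[cat]], labels, method = method,
                            k_max = config$k_max)
        reg <- loocv_regression(features[[cat]], delta, method = method,
                                k_max = config$k_max, labels = labels)
        predictions[[key]] <- list(binary = bin, regression = reg)
        occurrences[[key]] <- feature_occurrence_counts(
          bin$selections[[bin$optimal_k]])
      }
      if ("demo_clin" %in% names(features)) {
        base <- predictions[[paste(fu, selm, "demo_clin", sep = ".")]]
        for (cat in setdiff(names(features), "demo_clin")) {
          other <- predictions[[paste(fu, selm, cat, sep = ".")]]
          sv <- ensemble_soft_vote(base$binary$per_fold$prob,
                                   other$binary$per_fold$prob)
          em <- confusion_metrics(labels, sv$label)
          em$auc <- auc_rank(sv$prob, labels)
          ep <- ensemble_average_prediction(
            base$regression$predictions$predicted,
            other$regression$predictions$predicted)
          er <- list(correlation = stats::cor(ep, delta),
                     rmse = sqrt(mean((ep - delta)^2)),
                     mae = mean(abs(ep - delta)))
          ensembles[[paste(fu, selm, cat, sep = ".")]] <-
            list(binary = em, regression = er)
        }
      }
    }
  }

  result <- structure(list(config = config, cohort = cohort,
                           features = features, predictions = predictions,
                           ensembles = ensembles,
                           occurrences = occurrences),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  dir.create(result$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- result$config$out_dir
  write_subject_table(result$cohort$subjects, file.path(od, "subjects.csv"))
  for (nm in names(result$features)) {
    write_feature_table(result$features[[nm]],
                        file.path(od, paste0("features_", nm, ".csv")))
  }
  for (key in names(result$predictions)) {
    utils::write.csv(result$predictions[[key]]$binary$per_k,
                     file.path(od, paste0("binary_", key, ".csv")),
                     row.names = FALSE)
    utils::write.csv(result$predictions[[key]]$regression$per_k,
                     file.path(od, paste0("regression_", key, ".csv")),
                     row.names = FALSE)
  }
  cfg <- result$config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(od, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(od)
}
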