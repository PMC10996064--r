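#' Default task block design
#'
#' The emotional face-matching paradigm: 19 blocks of 20 volumes each
#' (7 rest, 6 shapes, 6 faces; 380 volumes total at TR = 1.35 s). Rest
#' blocks separate gaps each holding one shapes block followed by one faces
#' block, so the task sequence alternates S, F, S, F, ...
#'
#' @param volumes_per_block Volumes per block (default 20).
#' @return Data frame with columns `condition` (`rest`/`shapes`/`faces`)
#'   and `n_volumes`, one row per block in scan order.
#' @export
default_block_design <- function(volumes_per_block = 20L) {
  conds <- c(rep(c("rest", "shapes", "faces"), 6), "rest")
  data.frame(condition = conds,
             n_volumes = rep(as.integer(volumes_per_block), length(conds)),
             stringsAsFactors = FALSE)
}

#' Default outcome model linking interaction counts to severity change
#'
#' Linear model for the percent change in HDRS at follow-up as a function
#' of five nCC (coherence-cluster count) features:
#' `191 - 4.51*SMN__pVN - 3.24*pDMN__lVN2 - 2.96*SMN__CN - 2.64*pDMN__BGN
#'  - 2.54*MTN__BGN`, plus Gaussian noise.
#'
#' @param noise_sd Residual standard deviation in percent points
#'   (default 10).
#' @return List with `intercept`, named `coefficients`, `noise_sd`.
#' @export
default_outcome_model <- function(noise_sd = 10) {
  stopifnot(noise_sd >= 0)
  list(intercept = 191,
       coefficients = c(SMN__pVN = -4.51, pDMN__lVN2 = -3.24,
                        SMN__CN = -2.96, pDMN__BGN = -2.64,
                        MTN__BGN = -2.54),
       noise_sd = noise_sd)
}

#' Cohort generation specification
#'
#' Bundles everything the generator needs: cohort size, scan geometry,
#' block design, planted pairwise-coherence epochs, the outcome model, and
#' the RNG seed. Invariants are checked here: block volumes must sum to
#' `n_volumes`, planted epochs must lie within the scan, and planted
#' periods must be at or above 2 TR (the resolvable limit).
#'
#' @param n_subjects Number of subjects (default 32).
#' @param n_networks Number of networks (default 14, labelled per
#'   [fbn_labels()]).
#' @param n_volumes Volumes per scan (default 380).
#' @param tr_seconds Repetition time (default 1.35 s).
#' @param block_design Block design data frame
#'   (default [default_block_design()]).
#' @param coherence_plan List of planted epochs; each entry is a list with
#'   `pair` (two network labels or indices), `phase_class` (one of
#'   `in_phase`, `lead_12`, `lead_21`, `anti_phase`), `period_s`,
#'   `epochs` (list of `c(start, end)` volume windows, 1-based inclusive),
#'   `amplitude`.
#' @param outcome_model As from [default_outcome_model()].
#' @param noise_sd Standard deviation of the independent Gaussian noise in
#'   each network series (default 1).
#' @param seed Integer RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 32L, n_networks = 14L,
                        n_volumes = 380L, tr_seconds = 1.35,
                        block_design = default_block_design(),
                        coherence_plan = list(),
                        outcome_model = default_outcome_model(),
                        noise_sd = 1, seed = 1L) {
  stopifnot(n_subjects >= 1, n_networks >= 2, n_volumes >= 8,
            tr_seconds > 0, noise_sd >= 0,
            is.numeric(seed), length(seed) == 1)
  if (sum(block_design$n_volumes) != n_volumes) {
    stop("block design volumes (", sum(block_design$n_volumes),
         ") must sum to n_volumes (", n_volumes, ")")
  }
  networks <- if (n_networks == 14L) fbn_labels() else
    paste0("net", seq_len(n_networks))
  for (p in coherence_plan) {
    validate_plan_entry(p, networks, n_volumes, tr_seconds)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_networks = as.integer(n_networks),
                 networks = networks,
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 block_design = block_design,
                 coherence_plan = coherence_plan,
                 outcome_model = outcome_model,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

validate_plan_entry <- function(p, networks, n_volumes, tr_seconds) {
  stopifnot(is.list(p),
            all(c("pair", "phase_class", "period_s", "epochs",
                  "amplitude") %in% names(p)))
  if (is.character(p$pair)) stopifnot(all(p$pair %in% networks))
  stopifnot(length(p$pair) == 2,
            p$phase_class %in% c("in_phase", "lead_12", "lead_21",
                                 "anti_phase"))
  if (p$period_s < 2 * tr_seconds) {
    stop("planted period ", p$period_s, " s is below 2*TR = ",
         2 * tr_seconds, " s and cannot be resolved")
  }
  for (e in p$epochs) {
    if (e[1] < 1 || e[2] > n_volumes || e[1] > e[2]) {
      stop("epoch [", e[1], ", ", e[2], "] outside the scan (1..",
           n_volumes, ")")
    }
  }
  invisible(TRUE)
}

subject_seed <- function(spec, subject_index) {
  as.integer((abs(spec$seed) + 7919 * subject_index) %% 2147483629)
}

#' Generate one subject's network time-series
#'
#' T x N Gaussian noise with planted pairwise oscillations: inside each
#' planted epoch both members of the pair carry a cosine at the planted
#' period, with relative phase 0 (in_phase), the second series delayed by a
#' quarter period (lead_12: the first series leads), advanced by a quarter
#' period (lead_21), or in anti-phase (pi). Outside epochs the pair is
#' independent noise. Deterministic given the spec seed and subject index.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Subject number in 1..n_subjects.
#' @return T x N numeric matrix, columns named by network.
#' @export
generate_timeseries <- function(spec, subject_index = 1L) {
  stopifnot(inherits(spec, "cohort_spec"),
            subject_index >= 1, subject_index <= spec$n_subjects)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_seed(spec, subject_index))
  n <- spec$n_volumes
  ts <- matrix(stats::rnorm(n * spec$n_networks, sd = spec$noise_sd),
               nrow = n, ncol = spec$n_networks,
               dimnames = list(NULL, spec$networks))
  tsec <- (seq_len(n) - 1) * spec$tr_seconds
  for (p in spec$coherence_plan) {
    idx <- if (is.character(p$pair)) match(p$pair, spec$networks) else p$pair
    omega <- 2 * pi / p$period_s
    shift <- switch(p$phase_class,
                    in_phase = 0,
                    lead_12 = -pi / 2,   # series 2 delayed: series 1 leads
                    lead_21 = pi / 2,
                    anti_phase = pi)
    for (e in p$epochs) {
      win <- e[1]:e[2]
      phi0 <- stats::runif(1, 0, 2 * pi)
      ts[win, idx[1]] <- ts[win, idx[1]] +
        p$amplitude * cos(omega * tsec[win] + phi0)
      ts[win, idx[2]] <- ts[win, idx[2]] +
        p$amplitude * cos(omega * tsec[win] + phi0 + shift)
    }
  }
  ts
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate demographic and clinical features
#'
#' Samples the 20 demographic/clinical elements: age, sex, education;
#' anxiety and childhood-trauma questionnaire scores; number of lifetime
#' episodes and age at first onset; duration of the current episode and
#' baseline HDRS; 6 medication flags (any antidepressant, SSRI, SNRI,
#' NASSA, TCA, SARI) and 5 treatment flags (any non-antidepressant
#' treatment, CBT, individual/group psychotherapy, paramedical therapy,
#' mental-health-institution support). Continuous defaults follow the
#' cohort moments (age 43.8 +/- 13.4, education 1.5 +/- 0.88, 2.03 +/-
#' 0.69 episodes, onset 33.8 +/- 13.4 y, duration 11.5 +/- 6.33 months,
#' baseline HDRS 24.5 +/- 4.59 truncated to 0..52).
#'
#' @param spec A [cohort_spec()] (uses `n_subjects` and `seed`).
#' @param model Optional list overriding distribution parameters; entries
#'   `age`, `education`, `episodes`, `onset`, `duration`, `hdrs`,
#'   `anxiety`, `trauma` are `c(mean, sd)` pairs, `p_female` and
#'   `p_flags` (length 11) are probabilities.
#' @return Data frame with `n_subjects` rows and exactly 20 columns; flag
#'   columns are 0/1.
#' @export
generate_demo_clin <- function(spec, model = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- utils::modifyList(list(
    age = c(43.8, 13.4), p_female = 20 / 32,
    education = c(1.5, 0.88), anxiety = c(50, 10), trauma = c(45, 15),
    episodes = c(2.03, 0.69), onset = c(33.8, 13.4),
    duration = c(11.5, 6.33), hdrs = c(24.5, 4.59),
    p_flags = c(0.6, 0.45, 0.2, 0.1, 0.1, 0.1, 0.5, 0.3, 0.4, 0.15, 0.3)
  ), model)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_subjects
  flags <- matrix(vapply(m$p_flags, function(p) stats::rbinom(n, 1, p),
                         numeric(n)), nrow = n)
  colnames(flags) <- c("med_any_ad", "med_ssri", "med_snri", "med_nassa",
                       "med_tca", "med_sari", "treat_any_nonad",
                       "treat_cbt", "treat_psychotherapy",
                       "treat_paramedical", "treat_mhi_support")
  out <- data.frame(
    age = rtrunc_norm(n, m$age[1], m$age[2], 18, 65),
    sex = stats::rbinom(n, 1, m$p_female),
    education = round(rtrunc_norm(n, m$education[1], m$education[2], 1, 5)),
    anxiety_score = rtrunc_norm(n, m$anxiety[1], m$anxiety[2], 20, 80),
    trauma_score = rtrunc_norm(n, m$trauma[1], m$trauma[2], 25, 125),
    n_lifetime_episodes = pmax(1, round(stats::rnorm(n, m$episodes[1],
                                                     m$episodes[2]))),
    first_onset_age = rtrunc_norm(n, m$onset[1], m$onset[2], 10, 65),
    episode_duration_months = rtrunc_norm(n, m$duration[1], m$duration[2],
                                          0.5, 24),
    hdrs_baseline = rtrunc_norm(n, m$hdrs[1], m$hdrs[2], 0, 52)
  )
  cbind(out, as.data.frame(flags))
}

#' Generate HDRS outcomes from planted features
#'
#' Baseline HDRS is drawn from a truncated normal (mean 24.5, sd 4.59,
#' bounds 0..52) unless supplied. The planted percent change is the
#' outcome model's linear predictor on the given features; Gaussian noise
#' is added, the follow-up score `baseline * (1 + delta/100)` is clipped
#' to 0..52, and the realised percent change is recomputed from the
#' clipped score. Follow-up scores are kept continuous so the noiseless
#' model is exactly recoverable by least squares. The 3- and 6-month
#' follow-ups share the linear predictor but have independent noise.
#'
#' @param spec A [cohort_spec()] (uses `outcome_model` and `seed`).
#' @param features Data frame or matrix containing the columns named by
#'   the outcome model's coefficients.
#' @param baseline Optional baseline HDRS vector.
#' @return Data frame with `hdrs_baseline`, `hdrs_fu3m`, `hdrs_fu6m`,
#'   realised `delta3m`, `delta6m`, planted (pre-noise, pre-clip)
#'   `delta_planted`, and outcome labels `label3m`, `label6m`.
#' @export
generate_outcomes <- function(spec, features, baseline = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  om <- spec$outcome_model
  features <- as.data.frame(features)
  missing_cols <- setdiff(names(om$coefficients), names(features))
  if (length(missing_cols)) {
    stop("features are missing outcome-model column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(features)
  X <- as.matrix(features[, names(om$coefficients), drop = FALSE])
  planted <- om$intercept + drop(X %*% om$coefficients)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 1L)
  if (is.null(baseline)) {
    baseline <- rtrunc_norm(n, 24.5, 4.59, 0, 52)
  }
  stopifnot(length(baseline) == n, all(baseline > 0), all(baseline <= 52))
  one_fu <- function() {
    delta <- planted + stats::rnorm(n, 0, om$noise_sd)
    fu <- pmin(pmax(baseline * (1 + delta / 100), 0), 52)
    fu
  }
  fu3 <- one_fu()
  fu6 <- one_fu()
  d3 <- delta_hdrs(baseline, fu3)
  d6 <- delta_hdrs(baseline, fu6)
  data.frame(hdrs_baseline = baseline, hdrs_fu3m = fu3, hdrs_fu6m = fu6,
             delta3m = d3, delta6m = d6, delta_planted = planted,
             label3m = label_outcome(d3), label6m = label_outcome(d6))
}

#' Generate multi-echo voxel signals
#'
#' Mono-exponential decay `S = S0 * exp(-TE / T2*)` per voxel and echo,
#' plus Gaussian noise. Deterministic given the seed.
#'
#' @param te_ms Echo times in ms (>= 2 echoes, all > 0).
#' @param t2star_ms Per-voxel T2* in ms (all > 0).
#' @param s0 Per-voxel equilibrium signal (recycled if scalar).
#' @param noise_sd Additive noise sd (default 0).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return Voxels x echoes matrix of signals.
#' @export
generate_multiecho <- function(te_ms, t2star_ms, s0, noise_sd = 0,
                               seed = 1L) {
  if (length(te_ms) < 2) stop("need at least 2 echo times")
  if (any(te_ms <= 0)) stop("echo times must be positive")
  if (any(t2star_ms <= 0)) stop("T2* must be positive everywhere")
  nv <- length(t2star_ms)
  s0 <- rep_len(s0, nv)
  S <- outer(seq_len(nv), seq_along(te_ms),
             function(v, e) s0[v] * exp(-te_ms[e] / t2star_ms[v]))
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    S <- S + matrix(stats::rnorm(length(S), 0, noise_sd), nrow = nv)
  }
  dimnames(S) <- list(NULL, paste0("echo", seq_along(te_ms)))
  S
}

#' Generate planted interaction counts for all network pairs
#'
#' Per-subject integer counts of coherence epochs for every unordered
#' network pair, drawn from a rounded normal (default mean 13.9, sd 3.1,
#' the cohort's observed cluster-count moments, clipped to 5..25). All 91
#' pairs get counts; only the pairs named in the outcome model carry
#' non-zero coefficients downstream.
#'
#' @param spec A [cohort_spec()].
#' @param mean_count,sd_count,min_count,max_count Count distribution.
#' @return n_subjects x n_pairs integer matrix with `A__B` column names.
#' @export
generate_interaction_counts <- function(spec, mean_count = 13.9,
                                        sd_count = 3.1, min_count = 5,
                                        max_count = 25) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 2L)
  pg <- pair_grid(spec$networks)
  npair <- nrow(pg$unordered)
  cnt <- matrix(pmin(pmax(round(stats::rnorm(spec$n_subjects * npair,
                                             mean_count, sd_count)),
                          min_count), max_count),
                nrow = spec$n_subjects,
                dimnames = list(NULL, pg$unordered$name))
  cnt
}

# Build a per-subject coherence plan that plants `count` epochs for a pair.
plant_epochs_for_pair <- function(pair, count, n_volumes, tr_seconds,
                                  phase_classes = c("in_phase", "lead_12",
                                                    "lead_21", "anti_phase"),
                                  amplitude = 3) {
  if (count < 1) return(NULL)
  bounds <- round(seq(1, n_volumes + 1, length.out = count + 1))
  epochs <- vector("list", count)
  plan <- vector("list", count)
  for (k in seq_len(count)) {
    lo <- bounds[k]; hi <- bounds[k + 1] - 1
    len <- hi - lo + 1
    period <- stats::runif(1, max(4 * tr_seconds, 8),
                           max(10, len * tr_seconds / 2))
    plan[[k]] <- list(pair = pair,
                      phase_class = sample(phase_classes, 1),
                      period_s = period,
                      epochs = list(c(lo, hi)),
                      amplitude = amplitude)
  }
  plan
}

#' Generate a full synthetic cohort
#'
#' Ties the generator pieces together: demographic/clinical features,
#' planted interaction counts for all network pairs, HDRS outcomes from
#' the outcome model applied to the planted counts, and per-subject
#' network time-series in which the outcome-model pairs carry their
#' planted number of coherence epochs (random phase class, period and
#' placement per epoch). Ground truth (counts, plans, model, planted
#' percent changes) is returned for verification.
#'
#' @param spec A [cohort_spec()].
#' @param plant_timeseries If `TRUE` (default), plant the epochs into the
#'   time-series; `FALSE` skips series generation (features-only cohorts,
#'   much faster).
#' @param epoch_amplitude Planted oscillation amplitude (default 3, i.e.
#'   3x the unit noise sd).
#' @return List of class `synthetic_cohort`: `spec`, `subjects` (demo+clin
#'   plus HDRS scores, percent changes and labels), `timeseries` (list of
#'   T x N matrices or `NULL`), `ground_truth`.
#' @export
generate_cohort <- function(spec, plant_timeseries = TRUE,
                            epoch_amplitude = 3) {
  stopifnot(inherits(spec, "cohort_spec"))
  demo <- generate_demo_clin(spec)
  counts <- generate_interaction_counts(spec)
  outcomes <- generate_outcomes(spec, as.data.frame(counts),
                                baseline = demo$hdrs_baseline)
  ts_list <- NULL
  plans <- NULL
  if (plant_timeseries) {
    planted_pairs <- names(spec$outcome_model$coefficients)
    plans <- vector("list", spec$n_subjects)
    ts_list <- vector("list", spec$n_subjects)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    for (s in seq_len(spec$n_subjects)) {
      set.seed(subject_seed(spec, s) + 1L)
      plan_s <- list()
      for (pname in planted_pairs) {
        pair <- strsplit(pname, "__", fixed = TRUE)[[1]]
        plan_s <- c(plan_s,
                    plant_epochs_for_pair(pair, counts[s, pname],
                                          spec$n_volumes, spec$tr_seconds,
                                          amplitude = epoch_amplitude))
      }
      plans[[s]] <- plan_s
      spec_s <- spec
      spec_s$coherence_plan <- c(spec$coherence_plan, plan_s)
      ts_list[[s]] <- generate_timeseries(spec_s, s)
    }
  }
  structure(list(spec = spec, subjects = cbind(demo, outcomes[, -1]),
                 timeseries = ts_list,
                 ground_truth = list(counts = counts,
                                     outcome_model = spec$outcome_model,
                                     plans = plans,
                                     delta_planted = outcomes$delta_planted,
                                     labels3m = outcomes$label3m,
                                     labels6m = outcomes$label6m)),
            class = "synthetic_cohort")
}
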