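test_that("default block design has the paradigm structure", {
  bd <- default_block_design()
  expect_equal(nrow(bd), 19)
  expect_equal(sum(bd$n_volumes), 380)
  expect_true(all(bd$n_volumes == 20))
  expect_equal(as.list(table(bd$condition)),
               list(faces = 6L, rest = 7L, shapes = 6L))
  # rest separates the task blocks and opens/closes the run
  expect_equal(bd$condition[1], "rest")
  expect_equal(bd$condition[19], "rest")
  task <- bd$condition[bd$condition != "rest"]
  expect_equal(task, rep(c("shapes", "faces"), 6))
})

test_that("planted epochs produce the requested coupling", {
  spec <- cohort_spec(n_subjects = 1, seed = 3, coherence_plan = list(
    list(pair = c(1, 2), phase_class = "in_phase", period_s = 20,
         epochs = list(c(100, 250)), amplitude = 5)))
  ts <- generate_timeseries(spec, 1)
  expect_gt(cor(ts[100:250, 1], ts[100:250, 2]), 0.8)
  # outside the epoch the pair stays uncoupled
  expect_lt(abs(cor(ts[260:380, 1], ts[260:380, 2])), 0.3)
})

test_that("empty plan yields uncoupled noise and bitwise determinism", {
  spec <- cohort_spec(n_subjects = 2, seed = 11)
  ts <- generate_timeseries(spec, 1)
  expect_identical(ts, generate_timeseries(spec, 1))
  expect_false(identical(ts, generate_timeseries(spec, 2)))
  r <- cor(ts)
  expect_lt(max(abs(r[upper.tri(r)])), 0.2)
})

test_that("invalid plans are rejected", {
  expect_error(cohort_spec(coherence_plan = list(
    list(pair = c(1, 2), phase_class = "in_phase", period_s = 20,
         epochs = list(c(370, 390)), amplitude = 1))), "outside the scan")
  expect_error(cohort_spec(coherence_plan = list(
    list(pair = c(1, 2), phase_class = "in_phase", period_s = 2,
         epochs = list(c(1, 50)), amplitude = 1))), "cannot be resolved")
  expect_error(cohort_spec(n_volumes = 100), "must sum to")
})

test_that("outcome generation follows the planted linear model", {
  # degenerate: zero noise, zero features, intercept -50
  spec <- cohort_spec(n_subjects = 6, seed = 2,
                      outcome_model = list(intercept = -50,
                                           coefficients = c(f1 = 0),
                                           noise_sd = 0))
  out <- generate_outcomes(spec, data.frame(f1 = rep(0, 6)))
  expect_equal(out$delta3m, rep(-50, 6), tolerance = 1e-12)
  # planted linear predictor with all five counts at 15
  om <- default_outcome_model(noise_sd = 0)
  spec5 <- cohort_spec(n_subjects = 4, seed = 2, outcome_model = om)
  feats <- as.data.frame(matrix(15, 4, 5,
                                dimnames = list(NULL, names(om$coefficients))))
  out5 <- generate_outcomes(spec5, feats)
  expect_equal(out5$delta_planted, rep(-47.35, 4), tolerance = 1e-10)
  # missing column named in the error
  expect_error(generate_outcomes(spec5, feats[, -2]), "pDMN__lVN2")
})

test_that("higher planted counts give lower severity change", {
  cc <- make_counts_cohort(n = 32, seed = 9, noise_sd = 10)
  s <- rowSums(cc$X[, names(eq4_coefs)])
  expect_lt(cor(s, cc$delta, method = "spearman"), 0)
})

test_that("noiseless outcomes are exactly recoverable by OLS", {
  cc <- make_counts_cohort(n = 32, seed = 4, noise_sd = 0)
  fit <- lm(cc$delta ~ cc$X[, names(eq4_coefs)])
  expect_equal(unname(coef(fit)),
               unname(c(191, eq4_coefs)), tolerance = 1e-8)
})

test_that("demographic table has the 20 elements with sane moments", {
  spec <- cohort_spec(n_subjects = 1000, seed = 21)
  d <- generate_demo_clin(spec)
  expect_equal(ncol(d), 20)
  flags <- d[, grepl("^med_|^treat_", names(d))]
  expect_equal(ncol(flags), 11)
  expect_true(all(unlist(flags) %in% c(0, 1)))
  expect_lt(abs(mean(d$age) - 43.8), 3 * 13.4 / sqrt(1000) + 1)
  expect_true(all(d$hdrs_baseline >= 0 & d$hdrs_baseline <= 52))
  expect_lt(abs(mean(d$hdrs_baseline) - 24.5), 1)
})

test_that("multi-echo generator matches the decay law", {
  S <- generate_multiecho(acq_te_ms, t2star_ms = 30, s0 = 100)
  expect_equal(unname(S[1, 1]), 100 * exp(-11.3 / 30), tolerance = 1e-12)
  expect_equal(unname(S[1, ]), 100 * exp(-acq_te_ms / 30), tolerance = 1e-12)
  # TE -> 0 limit approaches S0
  S0lim <- generate_multiecho(c(1e-6, 2e-6), 30, 100)
  expect_equal(unname(S0lim[1, ]), c(100, 100), tolerance = 1e-4)
  # noiseless log-linear fit recovers T2* exactly
  fit <- fit_t2star(S[1, ], acq_te_ms)
  expect_equal(fit$t2star_ms, 30, tolerance = 1e-9)
  expect_error(generate_multiecho(c(-1, 2), 30, 100), "positive")
  expect_error(generate_multiecho(acq_te_ms, -5, 100), "positive")
  expect_identical(generate_multiecho(acq_te_ms, 30, 100, 1, seed = 4),
                   generate_multiecho(acq_te_ms, 30, 100, 1, seed = 4))
})

test_that("full cohort generation is deterministic and self-consistent", {
  spec <- cohort_spec(n_subjects = 2, seed = 17)
  coh <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_identical(coh$timeseries, coh2$timeseries)
  expect_identical(coh$subjects, coh2$subjects)
  expect_equal(length(coh$timeseries), 2)
  expect_equal(dim(coh$timeseries[[1]]), c(380, 14))
  expect_identical(coh$ground_truth$outcome_model, spec$outcome_model)
  # ground-truth counts drive the stored linear predictor exactly
  om <- spec$outcome_model
  lp <- om$intercept +
    drop(coh$ground_truth$counts[, names(om$coefficients)] %*%
           om$coefficients)
  expect_equal(coh$ground_truth$delta_planted, lp, tolerance = 1e-12)
})
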