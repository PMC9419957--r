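test_that("ground truth injects effects on the requested targets only", {
  cfg18 <- cohort_config(n_rois = 3, effect_model_id = 18, seed = 1)
  t18 <- make_ground_truth(cfg18)
  for (t in 1:6)
    expect_equal(pack_params(t18$per_timespan_params[[t]]),
                 pack_params(t18$base_params))
  cfg7 <- cohort_config(n_rois = 3, effect_model_id = 7,
                        effect_targets = "decay", effect_size = 0.3, seed = 1)
  t7 <- make_ground_truth(cfg7)
  expect_equal(t7$per_timespan_params[[1]]$decay,
               t7$base_params$decay + 0.3 * 2 / 3)
  expect_equal(t7$per_timespan_params[[3]]$decay,
               t7$base_params$decay - 0.3 / 3)
  # only decay moved
  th_base <- pack_params(t7$base_params)
  th_1 <- pack_params(t7$per_timespan_params[[1]])
  moved <- names(th_1)[th_1 != th_base]
  expect_identical(moved, "decay")
  # stability of every per-timespan system
  for (cfg in list(cfg18, cfg7)) {
    tr <- make_ground_truth(cfg)
    for (t in 1:6)
      expect_lt(max(Re(eigen(effective_A(tr$per_timespan_params[[t]]),
                             only.values = TRUE)$values)), 0)
  }
  # amplitude effects land on alpha_v
  cfgA <- cohort_config(n_rois = 3, effect_model_id = 2,
                        effect_targets = "csd_amplitude", effect_size = 0.2,
                        seed = 2)
  tA <- make_ground_truth(cfgA)
  expect_equal(tA$per_timespan_params[[2]]$alpha_v,
               tA$base_params$alpha_v + 0.2 * 5 / 6)
})

test_that("subject simulation is deterministic and respects zero noise", {
  cfg <- cohort_config(n_rois = 2, n_volumes = 128, seed = 3,
                       between_subject_sd = 0)
  tr <- make_ground_truth(cfg)
  r1 <- simulate_subject(tr, 2, "LR", 7)
  r2 <- simulate_subject(tr, 2, "LR", 7)
  expect_identical(r1$series[[1]], r2$series[[1]])
  expect_identical(r1$mid_scan_time, r2$mid_scan_time)
  # different session, same subject: different noise
  r3 <- simulate_subject(tr, 2, "RL", 7)
  expect_false(identical(r1$series[[1]], r3$series[[1]]))
  expect_false(anyNA(r1$series[[1]]))
  expect_equal(ncol(r1$confounds[[1]]), 14)
  # both noise sources off: the system stays at its fixpoint
  cfg0 <- cohort_config(n_rois = 2, n_volumes = 128, seed = 3,
                        between_subject_sd = 0, noise_scale_v = 0,
                        noise_scale_e = 0)
  tr0 <- make_ground_truth(cfg0)
  r0 <- simulate_subject(tr0, 1, "LR", 1)
  expect_lt(max(abs(sweep(r0$series[[1]], 2, colMeans(r0$series[[1]])))),
            1e-10)
})

test_that("cohorts have the configured structure and are reproducible", {
  cfg <- cohort_config(n_rois = 2, n_subjects_per_timespan = 4,
                       n_volumes = 128, seed = 4)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 4 * 6 * 2)
  expect_identical(allocate_timespan(co$mid_scan_time), co$timespan)
  # one mid-scan time and one parameter draw per subject
  per_subj <- dplyr::summarise(
    dplyr::group_by(co, subject_id),
    one_time = dplyr::n_distinct(mid_scan_time) == 1,
    one_params = length(unique(lapply(params, pack_params))) == 1)
  expect_true(all(per_subj$one_time))
  expect_true(all(per_subj$one_params))
  co2 <- simulate_cohort(cfg)
  expect_identical(co$series, co2$series)
})

test_that("simulated spectra converge to the analytic cross-spectrum", {
  cfg <- cohort_config(n_rois = 2, n_subjects_per_timespan = 1,
                       n_volumes = 2^17, between_subject_sd = 0, seed = 3)
  tr <- make_ground_truth(cfg)
  rec <- simulate_subject(tr, 1, "LR", 1)
  fr <- seq(0.005, 0.095, length.out = 12)
  Sw <- welch_csd(rec$series[[1]], fr, cfg$TR, window_length = 1024)
  Sm <- predict_csd(tr$per_timespan_params[[1]], fr)
  ratios <- c(Re(Sw$S[1, 1, ]) / Re(Sm$S[1, 1, ]),
              Re(Sw$S[2, 2, ]) / Re(Sm$S[2, 2, ]))
  expect_lt(stats::median(abs(ratios - 1)), 0.15)
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("subject-level parameter draws track the injected group profile", {
  cfg <- cohort_config(n_rois = 2, n_subjects_per_timespan = 32,
                       n_volumes = 128, effect_model_id = 7,
                       effect_targets = "decay", effect_size = 0.3,
                       between_subject_sd = 0.1, sessions = "LR", seed = 6)
  co <- simulate_cohort(cfg)
  decays <- vapply(co$params, function(p) p$decay, numeric(1))
  means <- tapply(decays, co$timespan, mean)
  expect_gt(stats::cor(as.numeric(means), time_effect_column(7)), 0.9)
})

test_that("power-law noise has the requested spectral density", {
  set.seed(7)
  dt <- 0.5
  x <- powerlaw_noise(2^15, dt, alpha = 0.4, beta = 0, n_series = 1)
  f <- seq(0.05, 0.8, length.out = 9)
  S <- welch_csd(x, f, dt, window_length = 1024)
  expect_lt(stats::median(abs(Re(S$S[1, 1, ]) /
                                innovation_spectrum(0.4, 0, f) - 1)), 0.15)
  expect_equal(powerlaw_noise(64, 1, 0, 0, scale = 0), matrix(0, 64, 1))
})

test_that("cohorts serialize with a manifest and ground truth", {
  cfg <- cohort_config(n_rois = 2, n_subjects_per_timespan = 1,
                       n_volumes = 128, seed = 8)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man), nrow(co))
  first <- utils::read.table(file.path(dir, man$file[1]), header = TRUE,
                             sep = "\t")
  expect_equal(as.matrix(first), co$series[[1]], ignore_attr = TRUE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(unlist(gt$base_params),
               pack_params(attr(co, "ground_truth")$base_params))
})
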