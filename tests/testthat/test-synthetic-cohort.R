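test_that("generator configuration is validated", {
  expect_error(eeg_gen_config(channels = c("F3", "F4")), "asymmetry electrode")
  expect_error(eeg_gen_config(fs_hz = 300), "multiple")
  tm <- canonical_templates()
  expect_error(eeg_gen_config(true_maps = 2 * tm), "unit norm")
  bad_trans <- matrix(0.5, 4, 4)
  expect_error(eeg_gen_config(transition_matrix = bad_trans), "diagonal|sum")
})

test_that("the same seed reproduces every generated modality exactly", {
  cfg <- eeg_gen_config()
  r1 <- generate_microstate_eeg(cfg, 1, seed = 5)
  r2 <- generate_microstate_eeg(cfg, 1, seed = 5)
  expect_identical(r1$data, r2$data)
  expect_identical(attr(r1, "ground_truth"), attr(r2, "ground_truth"))
  acfg <- autonomic_gen_config()
  expect_identical(generate_rr_series(acfg, 1, seed = 3),
                   generate_rr_series(acfg, 1, seed = 3))
  expect_identical(generate_scl_trace(acfg, 1, seed = 3),
                   generate_scl_trace(acfg, 1, seed = 3))
  qcfg <- quest_gen_config()
  expect_identical(generate_questionnaires(qcfg, c(2, 2, 2), seed = 3),
                   generate_questionnaires(qcfg, c(2, 2, 2), seed = 3))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_microstate_eeg(cfg, 1, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("a one-state noise-free recording is proportional to its map", {
  ch <- default_montage()
  map <- canonical_templates(ch)[1, , drop = FALSE]
  cfg <- eeg_gen_config(true_maps = map,
                        mean_durations_ms = 100,
                        alpha_rms_uV = 0, snr_db = Inf)
  rec <- generate_microstate_eeg(cfg, 1, seed = 9)
  nz <- colSums(rec$data^2) > 1e-12
  cc <- abs(cor(rec$data[, nz], as.numeric(map)))
  expect_true(all(cc > 1 - 1e-9))
})

test_that("realized mean durations converge to their targets", {
  # mean 15 samples at 125 Hz = 120 ms
  cfg <- eeg_gen_config(mean_durations_ms = rep(120, 4))
  rec <- generate_microstate_eeg(cfg, 5, seed = 17)
  gt <- attr(rec, "ground_truth")
  overall <- rowMeans(gt$realized_durations_ms)
  expect_true(all(abs(overall / 120 - 1) < 0.05))

  # state-specific targets, 5-minute recording, within 5% of target
  cfg2 <- eeg_gen_config()
  rec2 <- generate_microstate_eeg(cfg2, 5, seed = 18)
  gt2 <- attr(rec2, "ground_truth")
  overall2 <- rowMeans(gt2$realized_durations_ms)
  expect_true(all(abs(overall2 / c(40, 60, 80, 100) - 1) < 0.05))
  # realized durations are measured from the recorded state sequence
  r <- rle(gt2$state_seq[1:(60 * 125)])
  expect_equal(mean(r$lengths[r$values == 1]) * 8,
               gt2$realized_durations_ms[1, 1])
})

test_that("the injected alpha offset equals a direct power-ratio oracle", {
  cfg <- eeg_gen_config(alpha_asym_log_offset = c(anterior = 0.3,
                                                  posterior = -0.2))
  rec <- generate_microstate_eeg(cfg, 1, seed = 21)
  av <- attr(rec, "ground_truth")$alpha_channel_var
  cl <- asymmetry_clusters()
  expect_equal(log(mean(av[cl$anterior_right]) /
                   mean(av[cl$anterior_left])), 0.3, tolerance = 1e-6)
  expect_equal(log(mean(av[cl$posterior_right]) /
                   mean(av[cl$posterior_left])), -0.2, tolerance = 1e-6)
})

test_that("planted duration boosts apply to induction minutes only", {
  cfg <- eeg_gen_config(lkm_boost_ms = c(0, 20, 0, 0))
  rec <- generate_microstate_eeg(cfg, 3, seed = 23,
                                 labels = c("B", "LKM2", "LKM3"))
  tgt <- attr(rec, "ground_truth")$target_durations_ms
  expect_equal(unname(tgt[, "B"]), c(40, 60, 80, 100))
  expect_equal(unname(tgt[, "LKM2"]), c(40, 80, 80, 100))
})

test_that("RR series follow the configured sinusoidal modulation", {
  cfg <- autonomic_gen_config(mean_hr_bpm = 60, hf_mod_depth_ms = 0,
                              rr_noise_ms = 0)
  rr <- generate_rr_series(cfg, 1, seed = 2)
  expect_true(all(abs(rr$rr_ms - 1000) < 1e-9))
  expect_gte(max(rr$time_s), 60)
  # modulation raises HF power at least tenfold over the depth-0 case
  cfg_m <- autonomic_gen_config(hf_mod_depth_ms = 50, rr_noise_ms = 5)
  cfg_0 <- autonomic_gen_config(hf_mod_depth_ms = 0, rr_noise_ms = 5)
  hf_m <- hf_power(generate_rr_series(cfg_m, 2, seed = 4), c(0, 60))
  hf_0 <- hf_power(generate_rr_series(cfg_0, 2, seed = 4), c(0, 60))
  expect_gt(hf_m, 10 * hf_0)
})

test_that("SCL traces place arousal events at the configured minutes", {
  cfg <- autonomic_gen_config(scl_event_minutes = integer(0),
                              scl_drift_uS_per_min = 0, scl_noise_uS = 0)
  tr <- generate_scl_trace(cfg, 2, seed = 3)
  expect_equal(diff(range(tr$uS)), 0)
  cfg2 <- autonomic_gen_config(scl_event_minutes = c(1, 7),
                               scl_drift_uS_per_min = 0)
  tr2 <- generate_scl_trace(cfg2, 11, seed = 3)
  mins <- tapply(tr2$uS, findInterval(tr2$time_s, 0:10 * 60), mean)
  expect_setequal(order(mins, decreasing = TRUE)[1:2], c(1, 7))
})

test_that("questionnaire profiles force the intended classifications", {
  all5 <- quest_gen_config(pcl_item_probs = list(
    nPTSD = c(1, 0, 0, 0, 0), sPTSD = c(1, 0, 0, 0, 0),
    fPTSD = c(0, 0, 0, 0, 1)))
  q <- generate_questionnaires(all5, c(nPTSD = 3, sPTSD = 1, fPTSD = 3),
                               seed = 11)
  cl <- classify_cohort(q)
  expect_true(all(cl$group[cl$group_true == "fPTSD"] == "fPTSD"))
  expect_true(all(cl$group[cl$group_true == "nPTSD"] == "nPTSD"))
  # the default subsyndromal profile: intrusion + hyperarousal, low avoidance
  qd <- generate_questionnaires(quest_gen_config(), c(2, 10, 2), seed = 12)
  cld <- classify_cohort(qd)
  sp <- cld[cld$group_true == "sPTSD", ]
  expect_gt(mean(sp$group == "sPTSD"), 0.7)
  # items stay in the Likert range
  expect_true(all(as.matrix(qd[, paste0("pcl_", 1:17)]) %in% 1:5))
  expect_true(all(as.matrix(qd[, paste0("dass_", 1:42)]) %in% 0:3))
})

test_that("recordings round-trip through EDF within 16-bit precision", {
  cfg <- eeg_gen_config()
  rec <- generate_microstate_eeg(cfg, 1, seed = 41)
  path <- file.path(tempdir(), "roundtrip.edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$channels, rec$channels)
  expect_equal(back$fs_hz, rec$fs_hz)
  expect_equal(back$annotations$label, rec$annotations$label)
  qstep <- (apply(rec$data, 1, max) - apply(rec$data, 1, min)) / 65535
  err <- apply(abs(back$data - rec$data), 1, max)
  expect_true(all(err <= qstep + 1e-9))
  gt <- attr(back, "ground_truth")
  expect_equal(gt$alpha_asym_log_offset[["anterior"]], 0)
  unlink(c(path, paste0(path, ".json")))
})

test_that("a small cohort simulates and writes coherently", {
  cc <- cohort_config(n_per_group = c(nPTSD = 1, sPTSD = 1, fPTSD = 1),
                      seed = 3, n_lkm_minutes = 2, post = FALSE)
  cohort <- simulate_cohort(cc, eeg = FALSE)
  expect_equal(nrow(cohort$questionnaires), 3)
  expect_equal(cohort$minute_labels, c("B", "LKM1", "LKM2"))
  expect_length(cohort$subjects, 3)
  s1 <- cohort$subjects[[1]]
  expect_gte(max(s1$rr$time_s), 3 * 60)
  expect_equal(nrow(s1$scl),
               3 * 60 * cc$autonomic$scl_fs_hz)
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "questionnaires.csv")))
  expect_true(file.exists(file.path(dir, "S001_rr.csv")))
  back <- utils::read.csv(file.path(dir, "S001_rr.csv"))
  expect_equal(back$rr_ms, s1$rr$rr_ms, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
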