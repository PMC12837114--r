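test_that("forced repetition counts give exactly 10 flashes per target", {
  cfg <- test_cfg(reps_min = 10, reps_max = 10)
  sched <- build_block_schedule(cfg, cued_target = 2, seed = 5)
  expect_equal(nrow(sched), 60)
  expect_true(all(table(sched$stimulus_target) == 10))
})

test_that("schedules respect count, gap and round-structure legality", {
  cfg <- test_cfg()
  for (seed in 1:5) {
    sched <- build_block_schedule(cfg, cued_target = 0, seed = seed)
    counts <- table(sched$stimulus_target)
    expect_true(all(counts >= 10 & counts <= 15))
    gaps <- diff(sched$onset_ms)
    expect_true(all(gaps >= 150 & gaps <= 250))
    # no target flashes twice in a row, also across round boundaries
    expect_true(all(sched$stimulus_target[-1] !=
                      sched$stimulus_target[-nrow(sched)]))
    # the first 10 rounds contain every target exactly once each
    for (r in 1:10) {
      round_targets <- sched$stimulus_target[((r - 1) * 6 + 1):(r * 6)]
      expect_setequal(round_targets, 0:5)
    }
  }
  expect_error(build_block_schedule(cfg, cued_target = 6), "cued_target")
})

test_that("synthesized responses honor jitter, attention gating and peaks", {
  cfg <- test_cfg(sfreq = 1000)
  prof <- condition_profile("covert", p3_jitter_sd_ms = 0,
                            gaze_strategy = "fixate_center")
  comps <- default_erp_components()

  # no jitter: the P3 peak sits exactly at its mean latency on Pz
  sig <- synth_epoch_signal(comps, prof, is_target = TRUE,
                            gaze_offset_deg = 50, cfg = cfg)
  pz <- which(cfg$channels$name == "Pz")
  t_ms <- seq(-200, 999, by = 1)
  expect_equal(t_ms[which.max(sig$waveform[pz, ])], 400)
  expect_equal(sig$true_shift_ms, 0)

  # non-target with attention-only components: all-zero waveform
  p3_only <- comps[vapply(comps, function(c) c$modulation == "attention",
                          logical(1))]
  sig0 <- synth_epoch_signal(p3_only, prof, is_target = FALSE, cfg = cfg)
  expect_true(all(sig0$waveform == 0))
  expect_true(is.na(sig0$true_shift_ms))

  # drawn latency shifts match the configured jitter SD within 10%
  prof60 <- condition_profile("covert", p3_jitter_sd_ms = 60,
                              gaze_strategy = "fixate_center")
  set.seed(31)
  shifts <- replicate(1000, synth_epoch_signal(
    p3_only, prof60, is_target = TRUE, cfg = test_cfg())$true_shift_ms)
  expect_lt(abs(sd(shifts) - 60) / 60, 0.10)
})

test_that("gaze traces follow strategy, noise and dropout settings", {
  cfg <- test_cfg()
  pos <- target_positions(cfg)

  set.seed(1)
  exact <- condition_profile("overt", gaze_strategy = "fixate_target",
                             gaze_noise_sd_deg = 0,
                             dropout_prob_per_eye = 0)
  g <- simulate_gaze(exact, cued_target = 3, c(0, 5000), cfg)
  expect_true(all(g$lx == pos$x[4]) && all(g$ly == pos$y[4]))
  expect_true(all(g$rx == pos$x[4]) && all(g$l_valid) && all(g$r_valid))

  drop_left <- condition_profile("overt", gaze_strategy = "fixate_target",
                                 dropout_prob_per_eye = 0)
  g2 <- simulate_gaze(drop_left, 0, c(0, 5000), cfg)
  g2$l_valid <- FALSE   # emulate a fully dropped left eye downstream
  fused <- fuse_binocular(g2)
  expect_true(all(fused$source == "right"))

  # mixture strategy: per-block Bernoulli(p_overt) choice
  mix <- condition_profile("free", gaze_strategy = "mixture",
                           p_overt = 0.5)
  set.seed(9)
  picks <- replicate(1000, attr(simulate_gaze(mix, 0, c(0, 100), cfg),
                                "strategy_used"))
  frac <- mean(picks == "fixate_target")
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("sessions have the full block layout and complete ground truth", {
  ses <- noisy_session()   # single-condition session: 6 blocks
  expect_equal(nrow(ses$blocks), 6)
  per_block <- table(ses$events$block_id)
  expect_true(all(per_block >= 60 & per_block <= 90))
  expect_equal(nrow(ses$ground_truth), nrow(ses$events))
  expect_true(all(ses$events$event_id %in% ses$ground_truth$event_id))
  # every event onset maps inside the recording
  expect_true(all(ses$events$onset_ms >= 0 &
                    ses$events$onset_ms < ncol(ses$eeg) / ses$sfreq * 1000))
})

test_that("identical seeds reproduce sessions byte for byte", {
  cfg <- test_cfg(conditions = c("overt", "covert"))
  a <- simulate_session(cfg, seed = 77)
  b <- simulate_session(cfg, seed = 77)
  expect_identical(a$events, b$events)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$gaze, b$gaze)
})

test_that("noise-free contrast equals the attention-component waveform", {
  # widely spaced flashes so event responses never overlap
  cfg <- test_cfg(isi_nominal_ms = 1500, isi_jitter_ms = 50,
                  reps_min = 3, reps_max = 3)
  ses <- simulate_session(cfg, profiles = covert_profile(jitter = 0),
                          noise = noise_spec(sd_uv = 0), seed = 55)
  ep <- extract_epochs(ses, tmin = -0.2, tmax = 1.0)
  con <- erp_contrast(ep)

  prof <- covert_profile(jitter = 0)$covert
  p3_only <- Filter(function(c) c$modulation == "attention",
                    default_erp_components())
  expected <- synth_epoch_signal(p3_only, prof, is_target = TRUE,
                                 cfg = cfg)$waveform
  ch_eeg <- which(cfg$channels$type == "eeg")
  got <- matrix(con$contrast_uv, nrow = length(unique(con$channel)))
  expect_lt(max(abs(got - expected[ch_eeg, ])), 1e-9)
})
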