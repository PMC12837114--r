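# Minimal session-like object for filter tests: known sinusoids.
fake_session <- function(eeg, sfreq = 250, channels = default_channels()) {
  structure(list(eeg = eeg, sfreq = sfreq,
                 channels = channels[seq_len(nrow(eeg)), ]),
            class = "bci_session")
}

test_that("band-pass keeps the passband and rejects stopband and DC", {
  sfreq <- 250
  t <- seq(0, 20, by = 1 / sfreq)[-1]
  mid <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  rms <- function(x) sqrt(mean(x^2))

  chans <- default_channels()[1:3, ]
  eeg <- rbind(sin(2 * pi * 50 * t),   # stopband
               sin(2 * pi * 5 * t),    # passband
               rep(2, length(t)))      # DC
  out <- bandpass(fake_session(eeg, sfreq, chans))$eeg
  expect_lt(20 * log10(rms(out[1, mid]) / rms(eeg[1, mid])), -20)
  expect_lt(abs(20 * log10(rms(out[2, mid]) / rms(eeg[2, mid]))), 1)
  expect_lt(max(abs(out[3, mid])), 1e-4)

  expect_error(bandpass(fake_session(eeg, sfreq = 30, chans)), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(4)
  sfreq <- 250
  n <- 2000
  chans <- default_channels()[1:2, ]
  x <- matrix(rnorm(2 * n), 2)
  y <- matrix(rnorm(2 * n), 2)
  fx <- bandpass(fake_session(x, sfreq, chans))$eeg
  fy <- bandpass(fake_session(y, sfreq, chans))$eeg
  fxy <- bandpass(fake_session(2 * x - 3 * y, sfreq, chans))$eeg
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-9)
})

test_that("RANSAC flags disconnected and constant channels only", {
  # spatially correlated recording: all channels share structure except
  # the corrupted ones
  ses <- fake_session(
    vsabci:::make_noise(noise_spec(sd_uv = 5, spatial_decay = 3),
                        default_channels(), 20 * 250))
  set.seed(8)
  clean <- detect_bad_channels(ses, n_resamples = 15, window_s = 5)
  expect_true(all(!clean$bad))

  bad_ses <- ses
  bad_ses$eeg[4, ] <- rnorm(ncol(ses$eeg), 0, 5)  # independent noise
  bad_ses$eeg[9, ] <- 1.5                         # flatline
  rep <- detect_bad_channels(bad_ses, n_resamples = 15, window_s = 5)
  expect_setequal(rep$name[rep$bad],
                  default_channels()$name[c(4, 9)])
})

test_that("mastoid re-reference zeroes the reference mean, idempotently", {
  ses <- noisy_session()
  ref <- rereference_mastoids(ses)
  m <- match(c("TP9", "TP10"), ref$channels$name)
  expect_lt(max(abs(colMeans(ref$eeg[m, ]))), 1e-10)

  twice <- rereference_mastoids(ref)
  expect_equal(twice$eeg, ref$eeg)

  # differences among non-reference EEG channels are preserved
  i <- match(c("Cz", "Pz"), ses$channels$name)
  expect_equal(ref$eeg[i[1], ] - ref$eeg[i[2], ],
               ses$eeg[i[1], ] - ses$eeg[i[2], ])

  no_tp10 <- ses
  keep <- ses$channels$name != "TP10"
  no_tp10$channels <- ses$channels[keep, ]
  no_tp10$eeg <- ses$eeg[keep, ]
  expect_error(rereference_mastoids(no_tp10), "TP10")
})

test_that("epoch extraction follows the half-open window convention", {
  ses <- noisy_session()
  ep <- extract_epochs(ses, tmin = -0.1, tmax = 0.9)
  expect_equal(dim(ep$data)[3], round(1.0 * ses$sfreq))
  expect_equal(mean(ep$info$is_target), 1 / 6, tolerance = 0.05)
  expect_equal(ep$n_dropped, 0)

  # an event too close to the end of the recording is dropped and counted
  short <- ses
  sf <- ses$sfreq
  last_onset <- max(ses$events$onset_ms)
  # cut one sample before the last event's window can complete
  req_end <- round(last_onset * sf / 1000) + 1 + round(-0.1 * sf) +
    round(1.0 * sf) - 1
  short$eeg <- ses$eeg[, seq_len(req_end - 1)]
  ep2 <- extract_epochs(short, tmin = -0.1, tmax = 0.9)
  expect_equal(ep2$n_dropped, 1)
  expect_equal(nrow(ep2$info), nrow(ses$events) - 1)
})

test_that("ERP contrast is zero for identical classes and baselined", {
  ep <- extract_epochs(separable_session(), tmin = -0.2, tmax = 1.0)

  # identical target and non-target content -> all-zero contrast
  same <- ep
  same$data[] <- 1.5
  con0 <- erp_contrast(same)
  expect_true(all(abs(con0$contrast_uv) < 1e-12))

  # real contrast: baseline window mean is ~0 per channel
  con <- erp_contrast(ep)
  bl <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(con, t_s < 0), channel),
    m = mean(contrast_uv))
  expect_lt(max(abs(bl$m)), 1e-9)

  only_t <- vsabci:::subset_epochs(ep, ep$info$is_target)
  expect_error(erp_contrast(only_t), "both")
})

test_that("repetition truncation keeps the first k per target and block", {
  ep <- cached("ep_trunc", extract_epochs(noisy_session()))
  kept <- drop_excess_repetitions(ep, 10)
  counts <- dplyr::count(kept$info, block_id, stimulus_target)
  expect_true(all(counts$n == 10))
  # kept epochs are the earliest ones
  expect_true(all(kept$info$rep_index <= 10))

  one <- drop_excess_repetitions(ep, 1)
  expect_true(all(dplyr::count(one$info, block_id)$n == 6))

  ten <- drop_excess_repetitions(kept, 10)
  expect_identical(ten$info, kept$info)
})
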