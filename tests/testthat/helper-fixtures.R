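# Shared fixtures, built in code and cached per test run. Test sessions
# use 250 Hz sampling to keep the suite fast; the generator's timing
# bounds and block structure are sampling-rate independent.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

test_cfg <- function(conditions = "covert", sfreq = 250, ...) {
  paradigm_config(sfreq = sfreq, conditions = conditions, ...)
}

covert_profile <- function(jitter = 60, scale = 1) {
  list(covert = condition_profile("covert", p3_amplitude_scale = scale,
                                  p3_jitter_sd_ms = jitter,
                                  gaze_strategy = "fixate_center"))
}

# Noise-free covert session with zero latency jitter: fully separable,
# used for algebraic identities and perfect-decoding checks.
separable_session <- function() {
  cached("separable", simulate_session(
    test_cfg(), profiles = covert_profile(jitter = 0),
    noise = noise_spec(sd_uv = 0), seed = 101))
}

separable_epochs <- function() {
  cached("separable_ep", {
    ses <- separable_session()
    drop_excess_repetitions(extract_epochs(ses), 10)
  })
}

# Moderate-noise covert session with the default profile set.
noisy_session <- function() {
  cached("noisy", simulate_session(test_cfg(), seed = 202))
}

noisy_epochs <- function() {
  cached("noisy_ep", {
    ses <- rereference_mastoids(bandpass(noisy_session()))
    drop_excess_repetitions(extract_epochs(ses), 10)
  })
}

# Wide epochs whose attended response is shifted by known offsets drawn in
# +/-100 ms, plus weak white noise; non-targets carry no attended response.
# Ground truth is returned alongside for latency-recovery checks.
make_shifted_epochs <- function(n_target = 60, n_nontarget = 240,
                                shift_range = c(-100, 100),
                                noise_sd = 0.5, seed = 7) {
  set.seed(seed)
  cfg <- test_cfg()
  prof <- covert_profile(jitter = 0)$covert
  ch_eeg <- which(cfg$channels$type == "eeg")
  shifts <- stats::runif(n_target, shift_range[1], shift_range[2])
  make_one <- function(shift, is_t) {
    w <- synth_epoch_signal(default_erp_components(), prof, is_t,
                            gaze_offset_deg = cfg$hex_radius_deg,
                            cfg = cfg, shift_ms = shift)$waveform
    # crop the -0.2..1.0 s support to the -0.1..0.9 s wide epoch
    w <- w[ch_eeg, (0.1 * cfg$sfreq + 1):(1.1 * cfg$sfreq)]
    w + matrix(stats::rnorm(length(w), 0, noise_sd), nrow(w))
  }
  n <- n_target + n_nontarget
  arr <- array(0, c(n, length(ch_eeg), cfg$sfreq))
  for (i in seq_len(n_target)) arr[i, , ] <- make_one(shifts[i], TRUE)
  for (i in seq_len(n_nontarget)) {
    arr[n_target + i, , ] <- make_one(0, FALSE)
  }
  info <- tibble::tibble(
    block_id = 1L, condition = "covert", cued_target = 0L,
    stimulus_target = c(rep(0L, n_target), rep(1L, n_nontarget)),
    onset_ms = seq_len(n) * 1000, rep_index = 1L, event_id = seq_len(n),
    is_target = c(rep(TRUE, n_target), rep(FALSE, n_nontarget))
  )
  ep <- structure(list(
    data = arr, info = info, tmin = -0.1, tmax = 0.9, sfreq = cfg$sfreq,
    channel_names = cfg$channels$name[ch_eeg],
    baseline_corrected = FALSE, n_dropped = 0L
  ), class = "epoch_set")
  list(epochs = ep, shifts = shifts, n_target = n_target)
}

# Independent shrinkage-LDA oracle: unstructured pooled covariance with
# the same analytic scaled-identity shrinkage convention, written from
# the published formulas without reusing package internals.
oracle_shrinkage_lda <- function(X, y, shrinkage = NULL) {
  y <- as.logical(y)
  mu1 <- colMeans(X[y, , drop = FALSE])
  mu0 <- colMeans(X[!y, , drop = FALSE])
  Xc <- rbind(sweep(X[y, , drop = FALSE], 2, mu1),
              sweep(X[!y, , drop = FALSE], 2, mu0))
  n <- nrow(Xc)
  S <- t(Xc) %*% Xc / n
  nu <- mean(diag(S))
  if (is.null(shrinkage)) {
    sum_w2 <- t(Xc^2) %*% (Xc^2)
    var_s <- (n / (n - 1)^3) * (sum_w2 - n * S^2)
    denom <- sum((S - diag(nu, ncol(S)))^2)
    shrinkage <- if (denom <= 0) 0 else min(1, max(0, sum(var_s) / denom))
  }
  Sigma <- (1 - shrinkage) * S + shrinkage * diag(nu, ncol(S))
  w <- solve(Sigma, mu1 - mu0)
  list(w = as.numeric(w), b = -sum(w * (mu1 + mu0) / 2))
}

# Run one covert session end to end and return the CV accuracy of a
# decoder; used by the multi-seed decoder comparisons.
covert_cv_accuracy <- function(seed, decoder, jitter = 60, scale = 1,
                               sd_uv = 1) {
  ses <- simulate_session(test_cfg(), profiles = covert_profile(jitter,
                                                                scale),
                          noise = noise_spec(sd_uv = sd_uv), seed = seed)
  ep <- drop_excess_repetitions(
    extract_epochs(rereference_mastoids(bandpass(ses))), 10)
  blockwise_cv(ep, decoder, condition = "covert",
               n_boot = 200)$accuracy$accuracy
}
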