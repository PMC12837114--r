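# Preprocessing chain: band-pass filter, RANSAC bad-channel detection,
# mastoid re-reference, optional EOG regression, epoch extraction,
# visualization contrasts, repetition truncation.

eeg_idx <- function(session) which(session$channels$type == "eeg")

#' Zero-phase band-pass filter a session's continuous EEG
#'
#' 4th-order Butterworth applied forward-backward ([signal::filtfilt()]),
#' so the passband is preserved without phase distortion and the sample
#' count is unchanged. All channels (EEG and EOG) are filtered.
#'
#' @param session A `bci_session`.
#' @param lo,hi Band edges (Hz); defaults 0.5 and 16.
#' @return The session with filtered `eeg`.
#' @export
bandpass <- function(session, lo = 0.5, hi = 16) {
  if (hi >= session$sfreq / 2) {
    stop("upper band edge ", hi, " Hz must be below Nyquist (",
         session$sfreq / 2, " Hz)")
  }
  stopifnot(lo > 0, lo < hi)
  # Second-order-section cascade: a direct-form band-pass with a 0.5 Hz
  # edge at EEG sampling rates is numerically ill-conditioned.
  hp <- butter_sos(4, lo / (session$sfreq / 2), "high")
  lp <- butter_sos(4, hi / (session$sfreq / 2), "low")
  pad <- min(ncol(session$eeg) - 1, round(3 / lo * session$sfreq))
  session$eeg <- t(apply(session$eeg, 1, function(x)
    sos_filtfilt(lp, sos_filtfilt(hp, x, pad), pad)))
  session
}

# Butterworth design split into biquad sections (paired conjugate roots),
# stable where the high-order polynomial form is not.
butter_sos <- function(n, w, type) {
  zpg <- signal::as.Zpg(signal::butter(n, w, type))
  pair_up <- function(r) {
    used <- rep(FALSE, length(r)); out <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      cand <- which(!used & seq_along(r) != i & abs(r - Conj(r[i])) < 1e-6)
      if (length(cand) == 0) {
        out[[length(out) + 1]] <- c(1, -Re(r[i])); used[i] <- TRUE
      } else {
        j <- cand[1]
        out[[length(out) + 1]] <- c(1, -2 * Re(r[i]), Mod(r[i])^2)
        used[c(i, j)] <- TRUE
      }
    }
    out
  }
  as_ <- pair_up(zpg$pole)
  bs_ <- pair_up(zpg$zero)
  secs <- lapply(seq_along(as_), function(i)
    list(b = if (i <= length(bs_)) bs_[[i]] else 1, a = as_[[i]]))
  list(secs = secs, gain = zpg$gain)
}

# Zero-phase filtering of one channel with odd-reflection end padding so
# edge transients decay inside the pads, not the data.
sos_filtfilt <- function(sos, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- ext * sos$gain^2   # forward-backward application squares the gain
  for (s in sos$secs) y <- signal::filtfilt(s$b, s$a, y)
  y[(pad + 1):(pad + n)]
}

#' Detect bad channels by RANSAC spatial prediction
#'
#' In sliding windows, each EEG channel is predicted from random subsets of
#' the other EEG channels by least-squares spatial regression; the channel's
#' per-window score is the correlation between the median prediction across
#' subsets and the actual signal. A channel is flagged bad when its score
#' falls below `corr_threshold` in more than `bad_fraction` of windows.
#' Channels with (near-)zero variance correlate with nothing and are
#' flagged.
#'
#' @param session A `bci_session`.
#' @param n_resamples Random channel subsets per window.
#' @param subset_frac Fraction of the other channels in each subset.
#' @param corr_threshold Minimum within-window correlation to count as
#'   predictable.
#' @param bad_fraction Maximum tolerated fraction of unpredictable windows.
#' @param window_s Window length (seconds).
#' @return A `channel_quality` tibble: `name`, `score` (median window
#'   correlation), `bad_window_fraction`, `bad`, with the parameters as
#'   attributes.
#' @export
detect_bad_channels <- function(session, n_resamples = 50,
                                subset_frac = 0.25, corr_threshold = 0.75,
                                bad_fraction = 0.4, window_s = 5) {
  ei <- eeg_idx(session)
  if (length(ei) < 8) stop("need at least 8 EEG channels")
  x <- session$eeg[ei, , drop = FALSE]
  n_ch <- nrow(x)
  subset_size <- max(3L, round(subset_frac * (n_ch - 1)))
  if (subset_size >= n_ch) stop("subset_size must be below channel count")

  win <- max(2L, round(window_s * session$sfreq))
  starts <- seq(1, ncol(x) - win + 1, by = win)
  scores <- matrix(NA_real_, n_ch, length(starts))
  for (w in seq_along(starts)) {
    seg <- x[, starts[w]:(starts[w] + win - 1), drop = FALSE]
    for (c in seq_len(n_ch)) {
      others <- setdiff(seq_len(n_ch), c)
      preds <- matrix(0, n_resamples, win)
      for (r in seq_len(n_resamples)) {
        sub <- sample(others, subset_size)
        A <- t(seg[sub, , drop = FALSE])
        beta <- tryCatch(qr.solve(A, seg[c, ]),
                         error = function(e) rep(0, ncol(A)))
        preds[r, ] <- A %*% beta
      }
      med <- apply(preds, 2, stats::median)
      sc <- suppressWarnings(stats::cor(med, seg[c, ]))
      scores[c, w] <- if (is.na(sc)) 0 else sc
    }
  }
  bad_frac <- rowMeans(scores < corr_threshold)
  rep <- tibble::tibble(
    name = session$channels$name[ei],
    score = apply(scores, 1, stats::median),
    bad_window_fraction = bad_frac,
    bad = bad_frac > bad_fraction
  )
  attr(rep, "params") <- list(n_resamples = n_resamples,
                              subset_size = subset_size,
                              corr_threshold = corr_threshold,
                              bad_fraction = bad_fraction,
                              window_s = window_s)
  class(rep) <- c("channel_quality", class(rep))
  rep
}

#' Re-reference EEG to the average of the mastoid electrodes
#'
#' Subtracts the samplewise mean of the two reference channels (default
#' TP9/TP10) from every EEG channel; EOG channels are untouched. Applying
#' the operation twice equals applying it once.
#'
#' @param session A `bci_session`.
#' @param refs Names of the two reference channels.
#' @return The re-referenced session.
#' @export
rereference_mastoids <- function(session, refs = c("TP9", "TP10")) {
  miss <- setdiff(refs, session$channels$name)
  if (length(miss) > 0) {
    stop("reference channel(s) missing: ", paste(miss, collapse = ", "))
  }
  ri <- match(refs, session$channels$name)
  ref <- colMeans(session$eeg[ri, , drop = FALSE])
  ei <- eeg_idx(session)
  session$eeg[ei, ] <- sweep(session$eeg[ei, , drop = FALSE], 2, ref)
  session
}

#' Regress EOG activity out of the EEG channels
#'
#' Optional ocular-artifact attenuation stage: each EEG channel has its
#' least-squares projection onto the EOG channels subtracted. Off by
#' default in the standard chain.
#'
#' @param session A `bci_session`.
#' @return The cleaned session.
#' @export
regress_eog <- function(session) {
  oi <- which(session$channels$type == "eog")
  if (length(oi) == 0) stop("no EOG channels present")
  ei <- eeg_idx(session)
  E <- t(session$eeg[oi, , drop = FALSE])
  beta <- qr.solve(E, t(session$eeg[ei, , drop = FALSE]))
  session$eeg[ei, ] <- session$eeg[ei, , drop = FALSE] - t(E %*% beta)
  session
}

#' Cut stimulus-locked epochs from a session
#'
#' Half-open sample windows `[onset + tmin, onset + tmax)` with the onset
#' sample included, so each epoch has `round((tmax - tmin) * sfreq)`
#' samples. Events whose window falls outside the recording are dropped
#' and counted. Labels follow `stimulus_target == cued_target`. Channels
#' named in `exclude` (e.g. RANSAC-flagged ones) are left out of the
#' epoch array.
#'
#' @param session A filtered, re-referenced `bci_session`.
#' @param tmin,tmax Epoch window relative to onset (seconds).
#' @param exclude Channel names to exclude (besides EOG, which is always
#'   excluded from epochs).
#' @return An `epoch_set`: `data` (epochs x channels x samples), `info`
#'   tibble (one row per epoch), `tmin`, `tmax`, `sfreq`, `channel_names`,
#'   `baseline_corrected`, `n_dropped`.
#' @export
extract_epochs <- function(session, tmin = -0.1, tmax = 0.9,
                           exclude = character(0)) {
  ei <- eeg_idx(session)
  keep <- setdiff(session$channels$name[ei], exclude)
  ci <- match(keep, session$channels$name)
  sf <- session$sfreq
  n_samp <- round((tmax - tmin) * sf)
  onset_sample <- round(session$events$onset_ms * sf / 1000) + 1L
  start <- onset_sample + round(tmin * sf)
  ok <- start >= 1 & (start + n_samp - 1) <= ncol(session$eeg)
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("no events with a complete epoch window")

  ev <- session$events[ok, ]
  st <- start[ok]
  data <- array(0, c(nrow(ev), length(ci), n_samp))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- session$eeg[ci, st[i]:(st[i] + n_samp - 1)]
  }
  structure(list(
    data = data,
    info = dplyr::mutate(ev, is_target = .data$stimulus_target ==
                           .data$cued_target),
    tmin = tmin, tmax = tmax, sfreq = sf,
    channel_names = keep,
    baseline_corrected = FALSE,
    n_dropped = n_dropped
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$data)[1], " epochs x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples  [", x$tmin, ", ", x$tmax,
      ") s @ ", x$sfreq, " Hz\n", sep = "")
  cat("  targets: ", sum(x$info$is_target), " / ", nrow(x$info),
      if (x$n_dropped > 0) paste0("  (", x$n_dropped, " events dropped)"),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy epoch_set
#' @export
tidy.epoch_set <- function(x, ...) x$info

subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$info <- epochs$info[idx, ]
  epochs
}

baseline_correct <- function(epochs, window = c(epochs$tmin, 0)) {
  t_rel <- epochs$tmin + (seq_len(dim(epochs$data)[3]) - 1) / epochs$sfreq
  bi <- which(t_rel >= window[1] & t_rel < window[2])
  bl <- apply(epochs$data[, , bi, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(bl, dim(epochs$data))
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Target-minus-nontarget ERP contrast
#'
#' For visualization: each epoch is baseline-corrected by subtracting its
#' pre-stimulus mean, then the per-channel average non-target waveform is
#' subtracted from the average target waveform. Intended for wide epochs
#' (e.g. -0.2 to 1.0 s).
#'
#' @param epochs An `epoch_set` containing both classes.
#' @param baseline Baseline window (seconds, relative to onset).
#' @return A tibble `channel, t_s, contrast_uv`.
#' @export
erp_contrast <- function(epochs, baseline = c(epochs$tmin, 0)) {
  if (!any(epochs$info$is_target) || all(epochs$info$is_target)) {
    stop("both target and non-target epochs are required")
  }
  epochs <- baseline_correct(epochs, baseline)
  tgt <- apply(epochs$data[epochs$info$is_target, , , drop = FALSE],
               c(2, 3), mean)
  ntg <- apply(epochs$data[!epochs$info$is_target, , , drop = FALSE],
               c(2, 3), mean)
  con <- tgt - ntg
  t_s <- epochs$tmin + (seq_len(ncol(con)) - 1) / epochs$sfreq
  tibble::tibble(
    channel = rep(epochs$channel_names, times = ncol(con)),
    t_s = rep(t_s, each = nrow(con)),
    contrast_uv = as.vector(con)
  )
}

#' Keep only the first k intensifications of each target per block
#'
#' Mirrors the analysis rule that only the first 10 intensifications of
#' each target in a block enter decoding, even though 10 to 15 were
#' presented.
#'
#' @param epochs An `epoch_set` whose `info` carries `rep_index`.
#' @param keep Number of repetitions to retain per (block, target).
#' @return The truncated `epoch_set`.
#' @export
drop_excess_repetitions <- function(epochs, keep = 10) {
  idx <- which(epochs$info$rep_index <= keep)
  subset_epochs(epochs, idx)
}
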