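# Synthetic session generation: event responses, gaze traces, colored
# noise, and the full 18-block session assembly.

# Support of the inserted per-event response, seconds relative to onset.
# Wide enough to cover the widest analysis epoch (-0.2 .. 1.0 s).
EVENT_SUPPORT <- c(-0.2, 1.0)

#' Synthesize the noise-free multichannel response to one flash
#'
#' Sums the configured ERP components: each is a scalp topography times a
#' Gaussian temporal kernel (truncated at 4 SDs) at a drawn latency.
#' Attention components are included only for attended-target flashes,
#' scaled by the profile's `p3_amplitude_scale`, and share a single latency
#' shift drawn from `N(0, p3_jitter_sd_ms)` - that shift is the ground
#' truth returned for latency-estimation benchmarks. Visual components are
#' scaled by `exp(-gaze_offset^2 / (2 * visual_sigma_deg^2))` and use their
#' own `jitter_sd_ms`.
#'
#' @param components List of [erp_component()].
#' @param profile A [condition_profile()].
#' @param is_target Is this flash the attended target?
#' @param gaze_offset_deg Distance (degrees) between the gaze fixation
#'   point and the flashed stimulus.
#' @param cfg A [paradigm_config()] (sampling rate, channel table,
#'   `visual_sigma_deg`).
#' @param shift_ms Optional forced attention-latency shift (ms); when
#'   `NULL` the shift is drawn from the profile's jitter distribution.
#' @return List with `waveform` (channels x samples matrix, microvolt, on
#'   the support -0.2..1.0 s relative to onset), `support` (that range,
#'   seconds) and `true_shift_ms` (the attention-component latency shift;
#'   `NA` when no attention component was inserted).
#' @export
synth_epoch_signal <- function(components, profile, is_target,
                               gaze_offset_deg = 0, cfg = paradigm_config(),
                               shift_ms = NULL) {
  stopifnot(gaze_offset_deg >= 0)
  ch <- cfg$channels
  n_ch <- nrow(ch)
  t_ms <- seq(EVENT_SUPPORT[1], EVENT_SUPPORT[2] - 1 / cfg$sfreq,
              by = 1 / cfg$sfreq) * 1000
  wave <- matrix(0, n_ch, length(t_ms))
  true_shift <- NA_real_

  for (comp in components) {
    if (comp$modulation == "attention") {
      if (!is_target) next
      amp <- comp$amplitude_uv * profile$p3_amplitude_scale
      if (is.na(true_shift)) {
        true_shift <- if (!is.null(shift_ms)) shift_ms else
          stats::rnorm(1, 0, profile$p3_jitter_sd_ms)
      }
      shift <- true_shift
    } else if (comp$modulation == "visual") {
      amp <- comp$amplitude_uv *
        exp(-gaze_offset_deg^2 / (2 * cfg$visual_sigma_deg^2))
      shift <- if (comp$jitter_sd_ms > 0)
        stats::rnorm(1, 0, comp$jitter_sd_ms) else 0
    } else {
      amp <- comp$amplitude_uv
      shift <- if (comp$jitter_sd_ms > 0)
        stats::rnorm(1, 0, comp$jitter_sd_ms) else 0
    }
    if (amp == 0) next
    dt <- t_ms - (comp$latency_ms + shift)
    kern <- exp(-dt^2 / (2 * comp$kernel_width_ms^2))
    kern[abs(dt) > 4 * comp$kernel_width_ms] <- 0
    topo <- numeric(n_ch)
    idx <- match(names(comp$topography), ch$name)
    if (anyNA(idx)) {
      stop("topography names not in channel table: ",
           paste(names(comp$topography)[is.na(idx)], collapse = ", "))
    }
    topo[idx] <- comp$topography
    wave <- wave + amp * (topo %o% kern)
  }
  list(waveform = wave, support = EVENT_SUPPORT, true_shift_ms = true_shift)
}

#' Simulate a binocular gaze trace for one block
#'
#' The fixation point follows the profile's strategy: the cued target
#' (`fixate_target`), the screen center (`fixate_center`), or a per-block
#' Bernoulli(`p_overt`) choice between the two (`mixture`). Each eye's
#' samples get independent Gaussian position noise and are independently
#' dropped (validity flag cleared) with `dropout_prob_per_eye`.
#'
#' @param profile A [condition_profile()].
#' @param cued_target Cued target id.
#' @param block_span_ms Length-2 numeric, block start and end time (ms).
#' @param cfg A [paradigm_config()].
#' @return A tibble `t_ms, lx, ly, rx, ry, l_valid, r_valid` with attribute
#'   `"strategy_used"` ("fixate_target" or "fixate_center").
#' @export
simulate_gaze <- function(profile, cued_target, block_span_ms, cfg) {
  strategy <- profile$gaze_strategy
  if (strategy == "mixture") {
    strategy <- if (stats::runif(1) < profile$p_overt)
      "fixate_target" else "fixate_center"
  }
  pos <- target_positions(cfg)
  fix <- if (strategy == "fixate_target") {
    unlist(pos[pos$target == cued_target, c("x", "y")])
  } else c(x = 0, y = 0)

  t_ms <- seq(block_span_ms[1], block_span_ms[2], by = 1000 / cfg$gaze_sfreq)
  n <- length(t_ms)
  sd <- profile$gaze_noise_sd_deg
  g <- tibble::tibble(
    t_ms = t_ms,
    lx = fix[["x"]] + stats::rnorm(n, 0, sd),
    ly = fix[["y"]] + stats::rnorm(n, 0, sd),
    rx = fix[["x"]] + stats::rnorm(n, 0, sd),
    ry = fix[["y"]] + stats::rnorm(n, 0, sd),
    l_valid = stats::runif(n) >= profile$dropout_prob_per_eye,
    r_valid = stats::runif(n) >= profile$dropout_prob_per_eye
  )
  attr(g, "strategy_used") <- strategy
  g
}

# Spatially correlated AR(1) noise, channels x samples. Stationary SD per
# channel equals spec$sd_uv.
make_noise <- function(spec, channels, n_samples) {
  n_ch <- nrow(channels)
  if (spec$sd_uv == 0) return(matrix(0, n_ch, n_samples))
  d <- as.matrix(stats::dist(channels[, c("x", "y")]))
  cov <- exp(-d / spec$spatial_decay)
  L <- chol(cov)
  innov_sd <- spec$sd_uv * sqrt(1 - spec$ar^2)
  z <- matrix(stats::rnorm(n_ch * n_samples, 0, innov_sd), n_ch, n_samples)
  mixed <- crossprod(L, z)
  t(apply(mixed, 1, function(x)
    as.numeric(stats::filter(x, spec$ar, method = "recursive"))))
}

#' Simulate a complete oddball BCI session
#'
#' Generates the full study layout by default: one block per (condition,
#' cued target) pair - 3 conditions x 6 targets = 18 blocks - presented in
#' randomized order, concatenated into one continuous recording. The EEG is
#' the superposition of per-event component responses ([synth_epoch_signal()])
#' and colored background noise ([noise_spec()]); the gaze trace follows
#' each block's strategy. A ground-truth table records every event's true
#' attention-latency shift and amplitude scalings. Output is byte-identical
#' for identical seeds.
#'
#' @param cfg A [paradigm_config()].
#' @param components List of [erp_component()]; default
#'   [default_erp_components()].
#' @param profiles Named list of [condition_profile()], one per condition in
#'   `cfg$conditions`; default [default_condition_profiles()].
#' @param noise A [noise_spec()]; use `noise_spec(sd_uv = 0)` for noise-free
#'   sessions.
#' @param seed Master seed; per-block child seeds are derived from it so
#'   block content is stable under reordering.
#' @return A `bci_session` object: list with `eeg` (channels x samples,
#'   microvolt), `sfreq`, `channels`, `events`, `gaze`, `blocks`,
#'   `ground_truth`, `config`, `seed`.
#' @export
simulate_session <- function(cfg = paradigm_config(),
                             components = default_erp_components(),
                             profiles = default_condition_profiles(),
                             noise = noise_spec(),
                             seed = 1L) {
  missing_prof <- setdiff(cfg$conditions, names(profiles))
  if (length(missing_prof) > 0) {
    stop("no condition_profile for: ", paste(missing_prof, collapse = ", "))
  }
  set.seed(seed)
  plan <- tidyr::expand_grid(condition = cfg$conditions,
                             cued_target = seq_len(cfg$n_targets) - 1L)
  plan <- plan[sample.int(nrow(plan)), ]
  plan$block_id <- seq_len(nrow(plan))
  plan$block_seed <- sample.int(.Machine$integer.max, nrow(plan))

  pos <- target_positions(cfg)
  sup_lo <- EVENT_SUPPORT[1] * 1000

  events <- list(); gaze <- list(); gt <- list(); blocks <- list()
  segs <- list()
  t0 <- 0
  for (i in seq_len(nrow(plan))) {
    b <- plan[i, ]
    set.seed(b$block_seed)
    sched <- build_block_schedule(cfg, b$cued_target, b$condition,
                                  block_id = b$block_id, t0_ms = t0)
    prof <- profiles[[b$condition]]
    t_end <- max(sched$onset_ms) + cfg$block_end_pad_ms
    n_samp <- round((t_end - t0) * cfg$sfreq / 1000)
    seg <- matrix(0, nrow(cfg$channels), n_samp)

    g <- simulate_gaze(prof, b$cued_target, c(t0, t_end), cfg)
    strategy <- attr(g, "strategy_used")
    fix <- if (strategy == "fixate_target") {
      unlist(pos[pos$target == b$cued_target, c("x", "y")])
    } else c(x = 0, y = 0)

    shifts <- numeric(nrow(sched)); vis <- numeric(nrow(sched))
    for (j in seq_len(nrow(sched))) {
      stim <- sched$stimulus_target[j]
      off <- sqrt((fix[["x"]] - pos$x[stim + 1])^2 +
                    (fix[["y"]] - pos$y[stim + 1])^2)
      sig <- synth_epoch_signal(components, prof, sched$is_target[j],
                                gaze_offset_deg = off, cfg = cfg)
      start <- round((sched$onset_ms[j] - t0 + sup_lo) * cfg$sfreq / 1000) + 1
      idx <- seq(start, length.out = ncol(sig$waveform))
      keep <- idx >= 1 & idx <= n_samp
      seg[, idx[keep]] <- seg[, idx[keep]] + sig$waveform[, keep]
      shifts[j] <- sig$true_shift_ms
      vis[j] <- exp(-off^2 / (2 * cfg$visual_sigma_deg^2))
    }
    seg <- seg + make_noise(noise, cfg$channels, n_samp)

    segs[[i]] <- seg
    events[[i]] <- sched
    attr(g, "strategy_used") <- NULL
    gaze[[i]] <- g
    gt[[i]] <- dplyr::mutate(sched, true_shift_ms = shifts,
                             p3_scale = prof$p3_amplitude_scale,
                             visual_scale = vis)
    blocks[[i]] <- tibble::tibble(
      block_id = b$block_id, condition = b$condition,
      cued_target = b$cued_target, t_start_ms = t0, t_end_ms = t_end,
      gaze_strategy_used = strategy, block_seed = b$block_seed
    )
    t0 <- t_end
  }

  events <- dplyr::bind_rows(events)
  events$event_id <- seq_len(nrow(events))
  gt <- dplyr::bind_rows(gt)
  gt$event_id <- events$event_id

  structure(list(
    eeg = do.call(cbind, segs),
    sfreq = cfg$sfreq,
    channels = cfg$channels,
    events = events,
    gaze = dplyr::bind_rows(gaze),
    blocks = dplyr::bind_rows(blocks),
    ground_truth = gt,
    config = cfg,
    seed = seed
  ), class = "bci_session")
}

#' @export
print.bci_session <- function(x, ...) {
  cat("<bci_session> ", nrow(x$blocks), " blocks, ", nrow(x$events),
      " events, ", ncol(x$eeg), " samples @ ", x$sfreq, " Hz (",
      round(ncol(x$eeg) / x$sfreq, 1), " s), seed ", x$seed, "\n", sep = "")
  print(dplyr::count(x$blocks, .data$condition))
  invisible(x)
}

#' @rdname tidy.bci_session
#' @method glance bci_session
#' @export
glance.bci_session <- function(x, ...) {
  tibble::tibble(
    n_blocks = nrow(x$blocks),
    n_events = nrow(x$events),
    n_channels = nrow(x$channels),
    sfreq = x$sfreq,
    duration_s = ncol(x$eeg) / x$sfreq,
    seed = x$seed
  )
}

#' Tidiers for simulated sessions
#'
#' `tidy()` returns the event table joined with ground truth; `glance()` a
#' one-row session summary.
#'
#' @param x A `bci_session`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bci_session
#' @export
tidy.bci_session <- function(x, ...) {
  dplyr::left_join(
    x$events,
    dplyr::select(x$ground_truth, "event_id", "true_shift_ms",
                  "p3_scale", "visual_scale"),
    by = "event_id"
  )
}
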