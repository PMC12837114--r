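#' Paradigm configuration for a hexagonal 6-target oddball BCI
#'
#' Describes the stimulation geometry and timing of a Hex-o-Spell-style
#' visual oddball speller: six circular targets on the vertices of a regular
#' hexagon, intensified one at a time in pseudorandom round order. Values
#' default to the study paradigm this package emulates: 100 ms flashes at a
#' stimulus-onset asynchrony of 200 ms with uniform +/- 50 ms jitter, 10 to
#' 15 intensifications per target and block, and one block per (cued target,
#' attention condition) pair.
#'
#' @param n_targets Number of stimulus positions (hexagon vertices).
#' @param hex_radius_deg Hexagon radius in degrees of visual angle.
#' @param target_diameter_deg Resting target diameter (degrees).
#' @param intensified_diameter_deg Target diameter while flashed (degrees).
#' @param flash_duration_ms Duration of one intensification (ms).
#' @param isi_nominal_ms Nominal onset-to-onset spacing between successive
#'   flashes (ms). Interpreted as stimulus-onset asynchrony so that the
#'   100 ms flash never overlaps the next at the minimum spacing.
#' @param isi_jitter_ms Half-width of the uniform jitter added to the
#'   nominal spacing (ms).
#' @param reps_min,reps_max Bounds of the per-target intensification count,
#'   drawn uniformly per block.
#' @param conditions Ordered character vector of visuospatial-attention
#'   (VSA) conditions.
#' @param sfreq EEG sampling frequency (Hz).
#' @param gaze_sfreq Eye-tracker sampling frequency (Hz).
#' @param channels Channel table as returned by [default_channels()];
#'   must contain columns `name`, `type` ("eeg"/"eog") and unit-disc head
#'   coordinates `x`, `y` used for topographies and spatial noise.
#' @param block_start_pad_ms,block_end_pad_ms Silence before the first and
#'   after the last flash of each block (ms); the end pad leaves room for
#'   the widest epoch window.
#' @param visual_sigma_deg Scale (degrees) of the Gaussian fall-off of
#'   gaze-dependent early visual components with distance between the gaze
#'   position and the flashed stimulus.
#'
#' @return A `paradigm_config` list.
#' @export
paradigm_config <- function(n_targets = 6L,
                            hex_radius_deg = 12.28,
                            target_diameter_deg = 4.15,
                            intensified_diameter_deg = 5.50,
                            flash_duration_ms = 100,
                            isi_nominal_ms = 200,
                            isi_jitter_ms = 50,
                            reps_min = 10L,
                            reps_max = 15L,
                            conditions = c("overt", "covert", "free"),
                            sfreq = 1000,
                            gaze_sfreq = 30,
                            channels = default_channels(),
                            block_start_pad_ms = 1000,
                            block_end_pad_ms = 1500,
                            visual_sigma_deg = 6) {
  stopifnot(
    n_targets >= 2L,
    reps_min <= reps_max, reps_min >= 1L,
    hex_radius_deg > 0, target_diameter_deg > 0, intensified_diameter_deg > 0,
    flash_duration_ms > 0, isi_jitter_ms >= 0,
    sfreq > 0, gaze_sfreq > 0,
    all(c("name", "type", "x", "y") %in% names(channels))
  )
  if (flash_duration_ms >= isi_nominal_ms - isi_jitter_ms) {
    stop("flash_duration_ms must be below the minimum onset-to-onset spacing")
  }
  cfg <- list(
    n_targets = as.integer(n_targets),
    hex_radius_deg = hex_radius_deg,
    target_diameter_deg = target_diameter_deg,
    intensified_diameter_deg = intensified_diameter_deg,
    flash_duration_ms = flash_duration_ms,
    isi_nominal_ms = isi_nominal_ms,
    isi_jitter_ms = isi_jitter_ms,
    reps_min = as.integer(reps_min),
    reps_max = as.integer(reps_max),
    conditions = conditions,
    sfreq = sfreq,
    gaze_sfreq = gaze_sfreq,
    channels = channels,
    block_start_pad_ms = block_start_pad_ms,
    block_end_pad_ms = block_end_pad_ms,
    visual_sigma_deg = visual_sigma_deg
  )
  structure(cfg, class = "paradigm_config")
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat("<paradigm_config> ", x$n_targets, " targets, hex radius ",
      x$hex_radius_deg, " deg\n", sep = "")
  cat("  SOA ", x$isi_nominal_ms, " +/- ", x$isi_jitter_ms, " ms, flash ",
      x$flash_duration_ms, " ms, reps ", x$reps_min, "-", x$reps_max, "\n",
      sep = "")
  cat("  conditions: ", paste(x$conditions, collapse = ", "),
      "; EEG at ", x$sfreq, " Hz, gaze at ", x$gaze_sfreq, " Hz\n", sep = "")
  invisible(x)
}

#' Default 18-channel 10-20 montage plus bipolar EOG
#'
#' Approximate 2-D head positions on the unit disc (x toward the right ear,
#' y toward the nasion) are used to build component topographies and the
#' distance-decay spatial covariance of the background noise. TP9/TP10 are
#' the mastoid reference sites.
#'
#' @return A tibble with columns `name`, `type`, `x`, `y`.
#' @export
default_channels <- function() {
  tibble::tribble(
    ~name,   ~type, ~x,     ~y,
    "Fp1",   "eeg", -0.31,  0.95,
    "Fp2",   "eeg",  0.31,  0.95,
    "F7",    "eeg", -0.81,  0.59,
    "F3",    "eeg", -0.40,  0.52,
    "Fz",    "eeg",  0.00,  0.50,
    "F4",    "eeg",  0.40,  0.52,
    "F8",    "eeg",  0.81,  0.59,
    "T7",    "eeg", -1.00,  0.00,
    "C3",    "eeg", -0.50,  0.00,
    "Cz",    "eeg",  0.00,  0.00,
    "C4",    "eeg",  0.50,  0.00,
    "T8",    "eeg",  1.00,  0.00,
    "TP9",   "eeg", -0.95, -0.35,
    "P3",    "eeg", -0.40, -0.52,
    "Pz",    "eeg",  0.00, -0.50,
    "P4",    "eeg",  0.40, -0.52,
    "TP10",  "eeg",  0.95, -0.35,
    "Oz",    "eeg",  0.00, -1.00,
    "hEOG",  "eog", -1.10,  1.00,
    "vEOG",  "eog",  1.10,  1.00
  )
}

#' Screen positions of the hexagon targets
#'
#' Targets are indexed 0..n-1 starting at the top vertex and proceeding
#' clockwise. Coordinates are degrees of visual angle with the origin at
#' the screen center.
#'
#' @param cfg A [paradigm_config()].
#' @return A tibble with columns `target`, `x`, `y`.
#' @export
target_positions <- function(cfg) {
  k <- seq_len(cfg$n_targets) - 1L
  ang <- (90 - 60 * k) * pi / 180
  tibble::tibble(
    target = k,
    x = cfg$hex_radius_deg * cos(ang),
    y = cfg$hex_radius_deg * sin(ang)
  )
}

#' Specify one ERP component of the generative model
#'
#' The simulator builds event responses as a sum of components, each the
#' outer product of a fixed scalp topography and a Gaussian temporal kernel
#' placed at a (possibly jittered) latency.
#'
#' @param name Component label, e.g. "P1", "N1", "P3".
#' @param topography Named numeric vector of per-channel weights (names must
#'   be EEG channel names); unnamed channels get weight 0.
#' @param kernel_width_ms Gaussian kernel standard deviation (ms).
#' @param latency_ms Mean latency of the kernel peak after stimulus
#'   onset (ms).
#' @param jitter_sd_ms Trial-to-trial latency jitter SD (ms). For
#'   attention-modulated components this is overridden by the condition
#'   profile's `p3_jitter_sd_ms`.
#' @param amplitude_uv Peak amplitude (microvolt) before modulation.
#' @param modulation One of `"attention"` (present only on attended-target
#'   flashes; scaled by the condition profile), `"visual"` (present on every
#'   flash, scaled by a Gaussian fall-off with gaze distance to the flashed
#'   stimulus), or `"unmodulated"`.
#' @return An `erp_component` list.
#' @export
erp_component <- function(name, topography, kernel_width_ms, latency_ms,
                          jitter_sd_ms = 0, amplitude_uv = 1,
                          modulation = c("attention", "visual", "unmodulated")) {
  modulation <- match.arg(modulation)
  stopifnot(kernel_width_ms > 0, jitter_sd_ms >= 0,
            length(topography) >= 1, any(topography != 0))
  structure(
    list(name = name, topography = topography,
         kernel_width_ms = kernel_width_ms, latency_ms = latency_ms,
         jitter_sd_ms = jitter_sd_ms, amplitude_uv = amplitude_uv,
         modulation = modulation),
    class = "erp_component"
  )
}

#' Default generative ERP model
#'
#' Three components: an occipital P1 and an occipito-parietal N1, both
#' gaze-dependent ("visual": their amplitude falls off with the distance
#' between gaze and the flashed stimulus), and a centro-parietal P3 elicited
#' only by attended targets, whose amplitude and latency jitter are set by
#' the condition profile.
#'
#' @return A list of [erp_component()] objects.
#' @export
default_erp_components <- function() {
  list(
    erp_component(
      "P1",
      topography = c(Oz = 1.0, Pz = 0.4, P3 = 0.45, P4 = 0.45),
      kernel_width_ms = 25, latency_ms = 110, amplitude_uv = 3,
      modulation = "visual"
    ),
    erp_component(
      "N1",
      topography = c(Oz = 0.9, P3 = 0.7, P4 = 0.7, Pz = 0.4,
                     T7 = 0.2, T8 = 0.2),
      kernel_width_ms = 35, latency_ms = 180, amplitude_uv = -4,
      modulation = "visual"
    ),
    erp_component(
      "P3",
      topography = c(Pz = 1.0, Cz = 0.7, P3 = 0.6, P4 = 0.6,
                     C3 = 0.35, C4 = 0.35, Oz = 0.3, Fz = 0.2),
      kernel_width_ms = 60, latency_ms = 400, amplitude_uv = 5,
      modulation = "attention"
    )
  )
}

#' Specify a visuospatial-attention condition profile
#'
#' A profile sets how one VSA condition modulates the generative model:
#' the P3 amplitude multiplier, the P3 latency jitter SD, and the gaze
#' behavior used for the eye-tracking trace and for the gaze-distance
#' scaling of visual components.
#'
#' @param condition Condition label.
#' @param p3_amplitude_scale Multiplier on attention-component amplitude.
#' @param p3_jitter_sd_ms Latency jitter SD (ms) of attention components.
#' @param gaze_strategy `"fixate_target"` (gaze on the cued target),
#'   `"fixate_center"` (gaze on the screen center), or `"mixture"` (per
#'   block a Bernoulli(`p_overt`) choice between the two).
#' @param p_overt Probability of target fixation under `"mixture"`.
#' @param gaze_noise_sd_deg Gaussian gaze position noise per eye (degrees).
#' @param dropout_prob_per_eye Per-sample probability that an eye's gaze
#'   sample is missing (validity flag cleared), independently per eye.
#' @return A `condition_profile` list.
#' @export
condition_profile <- function(condition,
                              p3_amplitude_scale = 1,
                              p3_jitter_sd_ms = 20,
                              gaze_strategy = c("fixate_target",
                                                "fixate_center", "mixture"),
                              p_overt = 0.7,
                              gaze_noise_sd_deg = 1,
                              dropout_prob_per_eye = 0.05) {
  gaze_strategy <- match.arg(gaze_strategy)
  stopifnot(p3_amplitude_scale >= 0, p3_jitter_sd_ms >= 0,
            p_overt >= 0, p_overt <= 1,
            dropout_prob_per_eye >= 0, dropout_prob_per_eye <= 1)
  structure(
    list(condition = condition,
         p3_amplitude_scale = p3_amplitude_scale,
         p3_jitter_sd_ms = p3_jitter_sd_ms,
         gaze_strategy = gaze_strategy,
         p_overt = p_overt,
         gaze_noise_sd_deg = gaze_noise_sd_deg,
         dropout_prob_per_eye = dropout_prob_per_eye),
    class = "condition_profile"
  )
}

#' Default condition profiles for overt, covert and free VSA
#'
#' Overt VSA: gaze on the cued target, full P3 amplitude, small latency
#' jitter. Covert VSA: central fixation, attenuated P3, large latency
#' jitter (the dual-task cost of holding fixation while counting peripheral
#' flashes). Free VSA: per-block mixture leaning overt (p_overt = 0.7),
#' intermediate amplitude and jitter, reflecting users who keep some gaze
#' control and use it when uninstructed.
#'
#' @return Named list of [condition_profile()] objects
#'   (overt, covert, free).
#' @export
default_condition_profiles <- function() {
  list(
    overt = condition_profile("overt", p3_amplitude_scale = 1.0,
                              p3_jitter_sd_ms = 20,
                              gaze_strategy = "fixate_target"),
    covert = condition_profile("covert", p3_amplitude_scale = 0.65,
                               p3_jitter_sd_ms = 60,
                               gaze_strategy = "fixate_center"),
    free = condition_profile("free", p3_amplitude_scale = 0.85,
                             p3_jitter_sd_ms = 35,
                             gaze_strategy = "mixture", p_overt = 0.7)
  )
}

#' Background-noise specification
#'
#' Spatially correlated, temporally colored Gaussian noise: white
#' innovations mixed by the Cholesky factor of a distance-decay channel
#' covariance `exp(-d / decay)` (d in unit-head-radius units), then passed
#' through an AR(1) recursion with coefficient `ar` to give the 1/f-like
#' spectrum of resting EEG. `sd_uv` is the stationary per-channel standard
#' deviation in microvolt before band-pass filtering.
#'
#' @param sd_uv Per-channel noise SD (microvolt).
#' @param ar AR(1) coefficient in (0, 1).
#' @param spatial_decay Distance-decay length of inter-channel correlation.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sd_uv = 5, ar = 0.97, spatial_decay = 0.5) {
  stopifnot(sd_uv >= 0, ar >= 0, ar < 1, spatial_decay > 0)
  structure(list(sd_uv = sd_uv, ar = ar, spatial_decay = spatial_decay),
            class = "noise_spec")
}

#' Build the stimulation schedule of one block
#'
#' Per-target intensification counts are drawn uniformly in
#' `[reps_min, reps_max]`. The order is round-structured pseudorandom: each
#' round is a random permutation of the targets that still have
#' intensifications left, with the constraint that no target flashes twice
#' in a row across a round boundary. Onset-to-onset gaps are uniform in
#' `isi_nominal_ms +/- isi_jitter_ms`, snapped to the EEG sample grid.
#'
#' @param cfg A [paradigm_config()].
#' @param cued_target Attended target id in `0..n_targets-1`.
#' @param condition Condition label stored with each event.
#' @param block_id Integer block identifier.
#' @param t0_ms Recording time of the block start (before the start pad).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return A tibble with one row per flash: `onset_ms`, `block_id`,
#'   `condition`, `cued_target`, `stimulus_target`, `is_target`,
#'   `rep_index` (1-based intensification count of that target so far).
#' @export
build_block_schedule <- function(cfg, cued_target, condition = "overt",
                                 block_id = 1L, t0_ms = 0, seed = NULL) {
  if (!is.numeric(cued_target) || length(cued_target) != 1 ||
      cued_target < 0 || cued_target > cfg$n_targets - 1) {
    stop("cued_target must be a single id in 0..", cfg$n_targets - 1)
  }
  cued_target <- as.integer(cued_target)
  if (!is.null(seed)) set.seed(seed)

  n <- cfg$n_targets
  vals <- seq(cfg$reps_min, cfg$reps_max)
  # Redraw until the tail rounds cannot force an immediate repeat: a
  # target whose count exceeds the runner-up by 2+ would occupy two
  # consecutive singleton rounds.
  repeat {
    counts <- vals[sample.int(length(vals), n, replace = TRUE)]
    top2 <- sort(counts, decreasing = TRUE)[1:2]
    if (top2[1] - top2[2] <= 1) break
  }
  # Per-round permutations with no immediate repeat across boundaries;
  # a singleton tail round can still collide, in which case the whole
  # round sequence is resampled (guaranteed feasible by the count rule).
  repeat {
    rounds <- list()
    prev_last <- -1L
    for (r in seq_len(max(counts))) {
      active <- which(counts >= r) - 1L
      if (length(active) == 0) break
      perm <- sample_permutation_no_lead(active, prev_last)
      rounds[[length(rounds) + 1]] <- perm
      prev_last <- perm[length(perm)]
    }
    order <- unlist(rounds)
    if (all(order[-1] != order[-length(order)])) break
  }

  gap_ms <- round(stats::runif(length(order) - 1,
                               cfg$isi_nominal_ms - cfg$isi_jitter_ms,
                               cfg$isi_nominal_ms + cfg$isi_jitter_ms) *
                    cfg$sfreq / 1000) * 1000 / cfg$sfreq
  onset <- t0_ms + cfg$block_start_pad_ms + c(0, cumsum(gap_ms))
  onset <- round(onset * cfg$sfreq / 1000) * 1000 / cfg$sfreq

  sched <- tibble::tibble(
    onset_ms = onset,
    block_id = as.integer(block_id),
    condition = condition,
    cued_target = cued_target,
    stimulus_target = order,
    is_target = order == cued_target
  )
  dplyr::mutate(
    dplyr::group_by(sched, .data$stimulus_target),
    rep_index = dplyr::row_number(),
    .keep = "all"
  ) |> dplyr::ungroup()
}

# Random permutation of `ids` whose first element differs from `avoid`
# (possible whenever length(ids) > 1; for a single id equal to `avoid`
# the repeat is unavoidable and accepted).
sample_permutation_no_lead <- function(ids, avoid) {
  if (length(ids) == 1) return(ids)
  repeat {
    perm <- sample(ids)
    if (perm[1] != avoid) return(perm)
  }
}
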