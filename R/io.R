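# Session persistence: 16-bit EDF for the continuous EEG (written and read
# directly; the format is a fixed-width ASCII header plus little-endian
# int16 data records), TSV for events / gaze / blocks / ground truth, and
# a JSON sidecar for sampling metadata and the paradigm configuration.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# Write channels x samples matrix (physical units uV) as EDF. One data
# record per second; the last record is zero-padded. Returns the physical
# ranges used (for quantization accounting).
write_edf <- function(eeg, sfreq, labels, path) {
  stopifnot(sfreq == round(sfreq))
  n_ch <- nrow(eeg); n_samp <- ncol(eeg)
  n_rec <- ceiling(n_samp / sfreq)
  phys_max <- pmax(1, ceiling(apply(abs(eeg), 1, max) * 10) / 10)
  dig_max <- 32767; dig_min <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic session", 80),
    edf_pad("vsabci simulated EEG", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (n_ch + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(n_ch, 4)
  )
  fields <- c(
    vapply(labels, edf_pad, "", width = 16),
    vapply(rep("", n_ch), edf_pad, "", width = 80),
    vapply(rep("uV", n_ch), edf_pad, "", width = 8),
    vapply(-phys_max, edf_pad, "", width = 8),
    vapply(phys_max, edf_pad, "", width = 8),
    vapply(rep(dig_min, n_ch), edf_pad, "", width = 8),
    vapply(rep(dig_max, n_ch), edf_pad, "", width = 8),
    vapply(rep("", n_ch), edf_pad, "", width = 80),
    vapply(rep(sfreq, n_ch), edf_pad, "", width = 8),
    vapply(rep("", n_ch), edf_pad, "", width = 32)
  )
  writeChar(paste0(hdr, paste(fields, collapse = "")), con, eos = NULL)

  scale <- (dig_max - dig_min) / (2 * phys_max)
  padded <- cbind(eeg, matrix(0, n_ch, n_rec * sfreq - n_samp))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * sfreq + 1):(r * sfreq)
    dig <- round((padded[, cols, drop = FALSE] + phys_max) * scale) + dig_min
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(phys_max)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w))
  version <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  if (is.na(n_ch) || is.na(n_rec) || version != "0") {
    stop("not a valid EDF file: ", path)
  }
  rdv <- function(w) vapply(seq_len(n_ch), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates not supported")

  eeg <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = n_ch * spr[1], size = 2,
                   signed = TRUE, endian = "little")
    m <- matrix(raw, nrow = spr[1], ncol = n_ch)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    eeg[, cols] <- t((m - matrix(dig_min, spr[1], n_ch, byrow = TRUE)) *
                       matrix((phys_max - phys_min) / (dig_max - dig_min),
                              spr[1], n_ch, byrow = TRUE) +
                       matrix(phys_min, spr[1], n_ch, byrow = TRUE))
  }
  list(eeg = eeg, labels = labels, sfreq = spr[1] / rec_dur)
}

read_tsv_checked <- function(path, required, na_ok = character(0)) {
  if (!file.exists(path)) stop("missing file: ", path)
  x <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  )
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    stop("parse error in ", basename(path), " at line ", prob$row[1] + 1,
         ": ", prob$expected[1])
  }
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    stop("missing columns in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(x[setdiff(required, na_ok)]))
  if (length(bad) > 0) {
    stop("parse error in ", basename(path), " at line ", bad[1] + 1,
         ": incomplete record")
  }
  x
}

#' Write a simulated session to disk
#'
#' Lays out a session directory: `eeg.edf` (16-bit EDF, one record per
#' second), `events.tsv`, `gaze.tsv`, `blocks.tsv`, `ground_truth.tsv`,
#' and `meta.json` (sampling metadata, channel table, paradigm
#' configuration, seed). Events round-trip exactly; EEG round-trips within
#' the EDF quantization step of each channel's physical range.
#'
#' @param session A `bci_session`.
#' @param path Directory to create/write into.
#' @param force Overwrite an existing session directory.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, force = FALSE) {
  if (dir.exists(path) && file.exists(file.path(path, "meta.json")) &&
      !force) {
    stop("session already exists at ", path, " (use force = TRUE)")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_edf(session$eeg, session$sfreq, session$channels$name,
            file.path(path, "eeg.edf"))
  readr::write_tsv(session$events, file.path(path, "events.tsv"))
  readr::write_tsv(session$gaze, file.path(path, "gaze.tsv"))
  readr::write_tsv(session$blocks, file.path(path, "blocks.tsv"))
  readr::write_tsv(session$ground_truth, file.path(path, "ground_truth.tsv"))

  cfg <- session$config
  meta <- list(
    format = "vsabci-session", version = 1L,
    sfreq = session$sfreq, n_samples = ncol(session$eeg),
    seed = session$seed,
    channels = session$channels,
    config = cfg[setdiff(names(cfg), "channels")]
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path Session directory.
#' @return A `bci_session`.
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "vsabci-session") {
    stop("not a vsabci session directory: ", path)
  }
  edf <- read_edf(file.path(path, "eeg.edf"))
  eeg <- edf$eeg[, seq_len(meta$n_samples), drop = FALSE]

  events <- read_tsv_checked(
    file.path(path, "events.tsv"),
    c("onset_ms", "block_id", "condition", "cued_target",
      "stimulus_target", "is_target", "rep_index", "event_id"))
  gaze <- read_tsv_checked(
    file.path(path, "gaze.tsv"),
    c("t_ms", "lx", "ly", "rx", "ry", "l_valid", "r_valid"))
  blocks <- read_tsv_checked(
    file.path(path, "blocks.tsv"),
    c("block_id", "condition", "cued_target", "t_start_ms", "t_end_ms"))
  gt <- read_tsv_checked(
    file.path(path, "ground_truth.tsv"),
    c("event_id", "true_shift_ms", "p3_scale", "visual_scale"),
    na_ok = "true_shift_ms")   # non-targets carry no attended response

  int_cols <- c("block_id", "cued_target", "stimulus_target", "rep_index",
                "event_id", "block_seed", "n_boot")
  as_int <- function(df) dplyr::mutate(df, dplyr::across(
    dplyr::any_of(int_cols), as.integer))
  events <- as_int(events); blocks <- as_int(blocks); gt <- as_int(gt)

  channels <- tibble::as_tibble(meta$channels)
  cfg_fields <- meta$config
  cfg <- do.call(paradigm_config, c(
    cfg_fields[intersect(names(cfg_fields), names(formals(paradigm_config)))],
    list(channels = channels)))

  structure(list(
    eeg = eeg, sfreq = meta$sfreq, channels = channels,
    events = events, gaze = gaze, blocks = blocks, ground_truth = gt,
    config = cfg, seed = meta$seed
  ), class = "bci_session")
}
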