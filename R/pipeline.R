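# Scenario-driven end-to-end runs: simulate -> decode -> report, with a
# YAML scenario schema, manifest hashing and reproducible seeding. The
# exec/vsabci script is a thin shell over these functions.

scenario_defaults <- function() {
  list(
    paradigm = list(),
    profiles = "default",
    noise = list(sd_uv = 5, ar = 0.97, spatial_decay = 0.5),
    decoders = list("tlda"),
    plan = list(within_condition = TRUE, cross_condition = FALSE,
                k_sweep = NULL),
    seed = 1L
  )
}

#' Load and validate a scenario
#'
#' A scenario is a YAML (or already-parsed list) description of one full
#' run: paradigm overrides, condition profiles, noise, decoders,
#' evaluation plan, and the master seed. Unknown top-level keys and
#' missing required keys raise validation errors naming the keys.
#'
#' @param x Path to a YAML file, or a named list.
#' @return A validated scenario list.
#' @export
load_scenario <- function(x) {
  sc <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(sc)) stop("scenario must be a mapping")
  defaults <- scenario_defaults()
  unknown <- setdiff(names(sc), c(names(defaults), "conditions"))
  if (length(unknown) > 0) {
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  }
  required <- c("conditions", "seed")
  miss <- setdiff(required, names(sc))
  if (length(miss) > 0) {
    stop("scenario missing required key(s): ", paste(miss, collapse = ", "))
  }
  out <- utils::modifyList(defaults, sc)
  known <- c("overt", "covert", "free")
  bad <- setdiff(out$conditions, known)
  if (length(bad) > 0) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  }
  out
}

scenario_session <- function(sc) {
  cfg <- do.call(paradigm_config,
                 c(sc$paradigm, list(conditions = sc$conditions)))
  profiles <- if (identical(sc$profiles, "default")) {
    default_condition_profiles()
  } else {
    purrr::imap(sc$profiles, function(p, nm)
      do.call(condition_profile, c(list(condition = nm), p)))
  }
  noise <- do.call(noise_spec, sc$noise)
  simulate_session(cfg, profiles = profiles[sc$conditions],
                   noise = noise, seed = sc$seed)
}

#' Simulate a scenario and write the session to disk
#'
#' Writes the session directory plus a `manifest.json` holding the
#' scenario, its content hash and the seed, so any artifact can be
#' regenerated from the manifest alone.
#'
#' @param scenario Scenario path or list (see [load_scenario()]).
#' @param out_dir Output directory.
#' @param force Overwrite an existing output directory.
#' @return The manifest list, invisibly.
#' @export
run_simulate <- function(scenario, out_dir, force = FALSE) {
  sc <- load_scenario(scenario)
  session <- scenario_session(sc)
  write_session(session, file.path(out_dir, "session"), force = force)
  manifest <- list(
    scenario = sc,
    scenario_hash = rlang::hash(sc),
    seed = sc$seed,
    n_blocks = nrow(session$blocks),
    n_events = nrow(session$events)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Decode a stored session and write reports
#'
#' Preprocesses (band-pass 0.5-16 Hz, mastoid re-reference, epoching,
#' truncation to 10 repetitions), runs the requested decoder under the
#' evaluation plan, and writes per-fold CSV plus a JSON summary (and a
#' cross-condition matrix / k-sweep table when the plan asks for them).
#'
#' @param session_dir Session directory from [run_simulate()].
#' @param decoder Decoder name or spec list (tlda, xdawn_ts, wcble).
#' @param plan List: `within_condition` (logical), `cross_condition`
#'   (logical), `k_sweep` (integer vector or NULL).
#' @param out_dir Report output directory.
#' @param seed Seed for bootstrap CIs.
#' @return A list of the computed report objects, invisibly.
#' @export
run_decode <- function(session_dir, decoder = "tlda",
                       plan = list(within_condition = TRUE,
                                   cross_condition = FALSE,
                                   k_sweep = NULL),
                       out_dir = session_dir, seed = 1L) {
  decoder <- decoder_spec(decoder)
  session <- read_session(session_dir)
  session <- bandpass(session)
  session <- rereference_mastoids(session)
  wide <- decoder$name == "wcble"
  epochs <- extract_epochs(session, tmin = -0.1, tmax = 0.9)
  epochs <- drop_excess_repetitions(epochs, 10)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conditions <- unique(epochs$info$condition)
  out <- list()

  if (isTRUE(plan$within_condition)) {
    reports <- purrr::map(conditions, function(cond)
      blockwise_cv(epochs, decoder, condition = cond, seed = seed))
    names(reports) <- conditions
    summary <- dplyr::bind_rows(purrr::map(reports, glance))
    readr::write_csv(dplyr::bind_rows(purrr::map(reports, tidy),
                                      .id = "condition"),
                     file.path(out_dir, "within_condition_folds.csv"))
    jsonlite::write_json(summary,
                         file.path(out_dir, "within_condition.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$within_condition <- summary
  }
  if (isTRUE(plan$cross_condition)) {
    mat <- cross_condition_eval(epochs, decoder, seed = seed)
    readr::write_csv(mat, file.path(out_dir, "cross_condition.csv"))
    jsonlite::write_json(mat, file.path(out_dir, "cross_condition.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$cross_condition <- mat
  }
  if (!is.null(plan$k_sweep)) {
    sweep <- purrr::map_dfr(conditions, function(cond)
      dplyr::mutate(accuracy_by_repetitions(
        epochs, decoder, condition = cond, k_values = plan$k_sweep,
        seed = seed), condition = cond))
    readr::write_csv(sweep, file.path(out_dir, "k_sweep.csv"))
    out$k_sweep <- sweep
  }
  jsonlite::write_json(
    list(decoder = decoder, plan = plan, seed = seed,
         session = basename(session_dir)),
    file.path(out_dir, "decode_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Merge decode reports into a human-readable summary
#'
#' Collects within-condition accuracies, cross-condition matrices and
#' repetitions-to-threshold tables (never-reached rendered as "-") from
#' one or more report directories into a single text summary.
#'
#' @param report_dirs Character vector of directories written by
#'   [run_decode()].
#' @param threshold Accuracy threshold for the repetitions table.
#' @return The summary lines, invisibly; also printed.
#' @export
run_report <- function(report_dirs, threshold = 0.8) {
  if (length(report_dirs) == 0) stop("no reports given")
  lines <- character(0)
  for (d in report_dirs) {
    lines <- c(lines, paste0("== ", d, " =="))
    wc <- file.path(d, "within_condition.json")
    if (file.exists(wc)) {
      tab <- jsonlite::read_json(wc, simplifyVector = TRUE)
      lines <- c(lines, "within-condition accuracy:",
                 sprintf("  %-8s %.3f [%.3f, %.3f] (n=%d)",
                         tab$condition, tab$accuracy, tab$ci_low,
                         tab$ci_high, tab$n_selections))
    }
    cc <- file.path(d, "cross_condition.csv")
    if (file.exists(cc)) {
      mat <- readr::read_csv(cc, show_col_types = FALSE)
      lines <- c(lines, "cross-condition accuracy (train -> test):",
                 sprintf("  %-8s -> %-8s %.3f", mat$train_condition,
                         mat$test_condition, mat$accuracy))
    }
    ks <- file.path(d, "k_sweep.csv")
    if (file.exists(ks)) {
      sweep <- readr::read_csv(ks, show_col_types = FALSE)
      reps <- dplyr::summarise(
        dplyr::group_by(sweep, .data$condition),
        reps = {
          r <- reps_to_threshold(dplyr::pick("k", "accuracy"), threshold)
          if (is.na(r)) "-" else as.character(r)
        })
      lines <- c(lines,
                 sprintf("repetitions to reach %.0f%% accuracy:",
                         100 * threshold),
                 sprintf("  %-8s %s", reps$condition, reps$reps))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
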