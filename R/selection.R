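# Target-selection machinery: grouping stimuli into selections, the
# argmax selection rule, repetition averaging, block-wise and
# cross-condition cross-validation, bootstrap CIs and
# repetitions-to-threshold.

#' Partition a block's epochs into single-trial selections
#'
#' A selection is one BCI decision: one epoch per target. Under the
#' round-structured stimulation order, consecutive groups of 6 stimuli
#' cover all 6 targets exactly once, so a default block truncated to 10
#' repetitions yields 10 selections. If a consecutive group contains a
#' duplicate target (non-round data), the function falls back to a greedy
#' scan that collects the next unseen targets, and says so via a message.
#'
#' @param info Epoch info tibble of a single block (must carry `event_id`,
#'   `stimulus_target`, `cued_target`, `onset_ms`).
#' @param n_targets Number of targets.
#' @return A tibble with one row per (selection, target):
#'   `selection_id`, `epoch_row` (row into `info`), `stimulus_target`.
#' @export
partition_single_trial_selections <- function(info, n_targets = 6L) {
  stopifnot(length(unique(info$block_id)) == 1)
  ord <- order(info$onset_ms)
  targets <- info$stimulus_target[ord]
  n_full <- floor(length(targets) / n_targets)
  chunked_ok <- n_full >= 1 && all(vapply(seq_len(n_full), function(g) {
    grp <- targets[((g - 1) * n_targets + 1):(g * n_targets)]
    length(unique(grp)) == n_targets
  }, logical(1)))

  if (chunked_ok) {
    rows <- ord[seq_len(n_full * n_targets)]
    sel <- rep(seq_len(n_full), each = n_targets)
  } else {
    message("non-round stimulus order: falling back to greedy grouping")
    rows <- integer(0); sel <- integer(0)
    seen <- integer(0); cur <- integer(0); sid <- 1L
    for (i in seq_along(ord)) {
      tg <- targets[i]
      if (tg %in% seen) next
      seen <- c(seen, tg); cur <- c(cur, ord[i])
      if (length(seen) == n_targets) {
        rows <- c(rows, cur); sel <- c(sel, rep(sid, n_targets))
        seen <- integer(0); cur <- integer(0); sid <- sid + 1L
      }
    }
  }
  if (length(rows) == 0) stop("no complete selection could be formed")
  tibble::tibble(
    selection_id = sel,
    epoch_row = rows,
    stimulus_target = info$stimulus_target[rows]
  )
}

#' Pick the attended target from one selection's scores
#'
#' Argmax of the per-target scores; exact ties resolve to the lowest
#' target index, making the rule deterministic.
#'
#' @param scores Numeric vector of length `n_targets`, named or ordered by
#'   target id `0..n-1`.
#' @return The predicted target id (0-based).
#' @export
select_target <- function(scores) {
  if (anyNA(scores)) stop("missing score in selection")
  as.integer(which.max(scores) - 1L)
}

#' Average the first k repetitions of each target in a block
#'
#' Samplewise average of each target's first `k` epochs, giving one
#' averaged epoch per target (hence one selection per block), the
#' signal-to-noise-enhancing strategy of multi-repetition BCI operation.
#'
#' @param epochs An `epoch_set` restricted to one block.
#' @param k Repetitions to average, `1 <= k <=` available repetitions.
#' @return An `epoch_set` with one epoch per target, ordered by target id.
#' @export
average_k_repetitions <- function(epochs, k) {
  info <- epochs$info
  stopifnot(length(unique(info$block_id)) == 1)
  targets <- sort(unique(info$stimulus_target))
  avail <- min(tapply(info$rep_index, info$stimulus_target, max))
  if (k < 1 || k > avail) {
    stop("k must be in 1..", avail, " (available repetitions)")
  }
  n_ch <- dim(epochs$data)[2]; n_s <- dim(epochs$data)[3]
  data <- array(0, c(length(targets), n_ch, n_s))
  rows <- integer(length(targets))
  for (i in seq_along(targets)) {
    idx <- which(info$stimulus_target == targets[i] & info$rep_index <= k)
    idx <- idx[order(info$onset_ms[idx])][seq_len(k)]
    data[i, , ] <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    rows[i] <- idx[1]
  }
  out <- epochs
  out$data <- data
  out$info <- dplyr::mutate(info[rows, ], rep_index = 1L)
  out
}

#' Percentile bootstrap CI for a selection accuracy
#'
#' Resamples the per-selection correctness flags with replacement
#' (10,000 replicates by default) and takes percentile bounds.
#' Deterministic given `seed`.
#'
#' @param correct Logical vector, one flag per selection.
#' @param n_boot Bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return An `accuracy_estimate` tibble row: `accuracy`, `ci_low`,
#'   `ci_high`, `n_selections`, `n_boot`.
#' @export
bootstrap_ci <- function(correct, n_boot = 10000, level = 0.95, seed = 1L) {
  if (length(correct) == 0) stop("no selections to bootstrap")
  correct <- as.logical(correct)
  m <- length(correct)
  p_hat <- mean(correct)
  set.seed(seed)
  # Resampling m binary flags with replacement and averaging is a
  # Binomial(m, p_hat) draw divided by m.
  boots <- stats::rbinom(n_boot, m, p_hat) / m
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 1)
  out <- tibble::tibble(
    accuracy = p_hat,
    ci_low = min(qs[1], p_hat),
    ci_high = max(qs[2], p_hat),
    n_selections = m,
    n_boot = as.integer(n_boot)
  )
  class(out) <- c("accuracy_estimate", class(out))
  out
}

# Fit the requested decoder on a training epoch_set and score a test
# epoch_set, returning per-epoch scores. `decoder` is a list(name, ...)
# or a bare name string.
decoder_spec <- function(decoder) {
  if (is.character(decoder)) decoder <- list(name = decoder)
  if (!decoder$name %in% c("tlda", "xdawn_ts", "wcble")) {
    stop("unknown decoder '", decoder$name,
         "'; valid options: tlda, xdawn_ts, wcble")
  }
  decoder
}

fit_decoder <- function(train_epochs, decoder) {
  decoder <- decoder_spec(decoder)
  window_ms <- decoder$window_ms %||% c(0, 800)
  switch(decoder$name,
    tlda = fit_tlda(
      crop_and_decimate(train_epochs, window_ms, decoder$decim %||% NULL),
      shrinkage = decoder$shrinkage %||% NULL),
    xdawn_ts = fit_xdawn_ts(
      crop_and_decimate(train_epochs, window_ms, decoder$decim %||% NULL),
      n_filters = decoder$n_filters %||% 4),
    wcble = fit_wcble(
      train_epochs,
      window_ms = window_ms,
      decim = decoder$decim %||% NULL,
      n_iter = decoder$n_iter %||% 3,
      search_window_ms = decoder$search_window_ms %||% c(-100, 100),
      shrinkage = decoder$shrinkage %||% NULL)
  )
}

score_decoder <- function(model, test_epochs, decoder) {
  decoder <- decoder_spec(decoder)
  if (decoder$name == "wcble") {
    wcble_score(model, test_epochs)$score
  } else {
    window_ms <- decoder$window_ms %||% c(0, 800)
    score(model, crop_and_decimate(test_epochs, window_ms,
                                   decoder$decim %||% NULL))
  }
}

# Evaluate one test block: returns tibble of selections with predicted and
# true targets. mode "single_trial" partitions the block; mode "average_k"
# averages the first k repetitions into one selection.
eval_block <- function(model, test_epochs, decoder,
                       mode = "single_trial", k = NULL) {
  info <- test_epochs$info
  cued <- unique(info$cued_target)
  stopifnot(length(cued) == 1)
  if (mode == "average_k") {
    avg <- average_k_repetitions(test_epochs, k)
    sc <- score_decoder(model, avg, decoder)
    ord <- order(avg$info$stimulus_target)
    pred <- select_target(sc[ord])
    return(tibble::tibble(selection_id = 1L, predicted = pred,
                          true_target = cued))
  }
  parts <- partition_single_trial_selections(info)
  sc <- score_decoder(model, test_epochs, decoder)
  dplyr::summarise(
    dplyr::group_by(parts, .data$selection_id),
    predicted = {
      ord <- order(.data$stimulus_target)
      select_target(sc[.data$epoch_row][ord])
    },
    true_target = cued,
    .groups = "drop"
  )
}

#' Block-wise cross-validated selection accuracy
#'
#' 6-fold cross-validation with folds equal to stimulation blocks of one
#' condition: train on 5 blocks, test on the held-out block, pool all test
#' selections, and attach a percentile-bootstrap CI. Epochs are truncated
#' to the first `keep_reps` repetitions per target before anything else.
#'
#' @param epochs An `epoch_set` (any mix of conditions; filtered to
#'   `condition`).
#' @param decoder Decoder spec: `"tlda"`, `"xdawn_ts"`, `"wcble"`, or a
#'   list with `name` and parameter overrides.
#' @param condition Condition to evaluate.
#' @param mode `"single_trial"` (several selections per block) or
#'   `"average_k"` (one selection per block from `k` averaged repetitions).
#' @param k Repetitions to average under `"average_k"`.
#' @param keep_reps Repetition truncation applied before decoding.
#' @param n_boot,seed Bootstrap parameters for the CI.
#' @return A `selection_report`: list with `accuracy` (an
#'   `accuracy_estimate` row), `selections` (per-selection detail with
#'   fold ids), `condition`, `decoder`, `mode`, `k`.
#' @export
blockwise_cv <- function(epochs, decoder = "tlda", condition = NULL,
                         mode = c("single_trial", "average_k"), k = NULL,
                         keep_reps = 10, n_boot = 10000, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "average_k" && is.null(k)) stop("mode 'average_k' needs k")
  if (!is.null(condition)) {
    epochs <- subset_epochs(epochs, epochs$info$condition == condition)
  } else {
    condition <- unique(epochs$info$condition)
    if (length(condition) > 1) stop("specify `condition`")
  }
  epochs <- drop_excess_repetitions(epochs, keep_reps)
  blocks <- sort(unique(epochs$info$block_id))
  if (length(blocks) < 2) stop("need at least 2 blocks for block-wise CV")

  folds <- purrr::map(seq_along(blocks), function(f) {
    test_b <- blocks[f]
    train <- subset_epochs(epochs, epochs$info$block_id != test_b)
    test <- subset_epochs(epochs, epochs$info$block_id == test_b)
    stopifnot(length(intersect(train$info$event_id,
                               test$info$event_id)) == 0)
    model <- fit_decoder(train, decoder)
    dplyr::mutate(eval_block(model, test, decoder, mode, k),
                  fold = f, block_id = test_b)
  })
  selections <- dplyr::bind_rows(folds)
  acc <- bootstrap_ci(selections$predicted == selections$true_target,
                      n_boot = n_boot, seed = seed)
  structure(list(
    accuracy = acc, selections = selections,
    condition = condition, decoder = decoder_spec(decoder)$name,
    mode = mode, k = k
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  a <- x$accuracy
  cat("<selection_report> ", x$decoder, " / ", x$condition, " / ", x$mode,
      if (!is.null(x$k)) paste0(" (k=", x$k, ")"), "\n", sep = "")
  cat(sprintf("  accuracy %.3f  [%.3f, %.3f]  (%d selections)\n",
              a$accuracy, a$ci_low, a$ci_high, a$n_selections))
  invisible(x)
}

#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) x$selections

#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$accuracy),
                condition = x$condition, decoder = x$decoder,
                mode = x$mode, k = x$k %||% NA_integer_)
}

#' Cross-condition calibration-transfer matrix
#'
#' For every ordered condition pair (train A, test B) with A != B: each of
#' B's blocks is tested once, trained on the 5 A-blocks left after removing
#' the A-block with the matching fold index (a rotation that keeps the
#' training size at 5 and uses all A data symmetrically). Diagonal entries
#' delegate to [blockwise_cv()] on the same data and decoder.
#'
#' @inheritParams blockwise_cv
#' @param pairs Optional restriction: a data frame with columns `train`
#'   and `test` naming the ordered condition pairs to evaluate (default:
#'   the full grid).
#' @return A `cross_condition_matrix` tibble: one row per (train, test)
#'   pair with accuracy, CI and selection count.
#' @export
cross_condition_eval <- function(epochs, decoder = "tlda",
                                 mode = "single_trial", k = NULL,
                                 keep_reps = 10, n_boot = 10000,
                                 seed = 1L, pairs = NULL) {
  conditions <- unique(epochs$info$condition)
  epochs <- drop_excess_repetitions(epochs, keep_reps)
  grid <- if (is.null(pairs)) {
    tidyr::expand_grid(train = conditions, test = conditions)
  } else {
    stopifnot(all(c(pairs$train, pairs$test) %in% conditions))
    tibble::as_tibble(pairs[, c("train", "test")])
  }
  rows <- purrr::pmap(grid, function(train, test) {
    if (train == test) {
      within <- blockwise_cv(epochs, decoder, condition = train,
                              mode = mode, k = k, keep_reps = keep_reps,
                              n_boot = n_boot, seed = seed)
      acc <- within$accuracy
    } else {
      tr_ep <- subset_epochs(epochs, epochs$info$condition == train)
      te_ep <- subset_epochs(epochs, epochs$info$condition == test)
      tr_blocks <- sort(unique(tr_ep$info$block_id))
      te_blocks <- sort(unique(te_ep$info$block_id))
      sels <- purrr::map(seq_along(te_blocks), function(f) {
        drop_b <- tr_blocks[((f - 1) %% length(tr_blocks)) + 1]
        train_set <- subset_epochs(tr_ep, tr_ep$info$block_id != drop_b)
        test_set <- subset_epochs(te_ep,
                                  te_ep$info$block_id == te_blocks[f])
        model <- fit_decoder(train_set, decoder)
        eval_block(model, test_set, decoder, mode, k)
      })
      sels <- dplyr::bind_rows(sels)
      acc <- bootstrap_ci(sels$predicted == sels$true_target,
                          n_boot = n_boot, seed = seed)
    }
    dplyr::mutate(tibble::as_tibble(acc), train_condition = train,
                  test_condition = test, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cross_condition_matrix", class(out))
  out
}

#' Repetitions needed to reach a target accuracy
#'
#' Given the accuracy-by-repetitions curve of a k-averaged evaluation,
#' returns the smallest k whose accuracy meets `threshold` (inclusive), or
#' `NA` when the curve never reaches it - rendered as "-" in reports, the
#' convention for participants who never reached effective-operation
#' accuracy.
#'
#' @param accuracy_by_k Numeric accuracy curve indexed by k = 1, 2, ...,
#'   or a tibble with columns `k` and `accuracy`.
#' @param threshold Accuracy threshold (default 0.8, the conventional
#'   effective-BCI-operation level).
#' @return Integer k, or `NA_integer_`.
#' @export
reps_to_threshold <- function(accuracy_by_k, threshold = 0.8) {
  if (is.data.frame(accuracy_by_k)) {
    curve <- accuracy_by_k$accuracy[order(accuracy_by_k$k)]
  } else {
    curve <- accuracy_by_k
  }
  hit <- which(curve >= threshold)
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1])
}

#' Accuracy as a function of averaged repetitions
#'
#' Runs [blockwise_cv()] in `"average_k"` mode for each k, producing the
#' curve consumed by [reps_to_threshold()].
#'
#' @inheritParams blockwise_cv
#' @param k_values Repetition counts to evaluate.
#' @return A tibble with one row per k: `k`, `accuracy`, `ci_low`,
#'   `ci_high`, `n_selections`.
#' @export
accuracy_by_repetitions <- function(epochs, decoder = "tlda",
                                    condition = NULL, k_values = 1:10,
                                    keep_reps = 10, n_boot = 10000,
                                    seed = 1L) {
  purrr::map_dfr(k_values, function(k) {
    res <- blockwise_cv(epochs, decoder, condition, mode = "average_k",
                        k = k, keep_reps = keep_reps, n_boot = n_boot,
                        seed = seed)
    dplyr::mutate(tibble::as_tibble(res$accuracy), k = k, .before = 1)
  })
}
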