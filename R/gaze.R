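# Eye-tracking post-processing: binocular fusion, stimulus-space mapping,
# per-block dwell summaries.

#' Fuse binocular gaze samples into one channel
#'
#' Per sample and coordinate: both eyes valid -> their mean; one valid ->
#' that eye's value adopted; none -> the sample stays missing (`NA`) and no
#' interpolation is ever performed, so gaps keep their length.
#'
#' @param gaze Tibble with `t_ms`, `lx`, `ly`, `rx`, `ry`, `l_valid`,
#'   `r_valid`.
#' @return A tibble `t_ms`, `x`, `y`, `source` (one of "both", "left",
#'   "right", "none").
#' @export
fuse_binocular <- function(gaze) {
  stopifnot(all(c("t_ms", "lx", "ly", "rx", "ry", "l_valid", "r_valid")
                %in% names(gaze)))
  l <- gaze$l_valid; r <- gaze$r_valid
  x <- dplyr::case_when(l & r ~ (gaze$lx + gaze$rx) / 2,
                        l ~ gaze$lx, r ~ gaze$rx,
                        .default = NA_real_)
  y <- dplyr::case_when(l & r ~ (gaze$ly + gaze$ry) / 2,
                        l ~ gaze$ly, r ~ gaze$ry,
                        .default = NA_real_)
  src <- dplyr::case_when(l & r ~ "both", l ~ "left", r ~ "right",
                          .default = "none")
  tibble::tibble(t_ms = gaze$t_ms, x = x, y = y, source = src)
}

#' Map a fused gaze trace into stimulus coordinates
#'
#' Applies an affine transform (2x2 linear part `A`, length-2 offset `b`):
#' `p' = A p + b`. Missing samples stay missing.
#'
#' @param fused A fused gaze tibble from [fuse_binocular()].
#' @param A 2x2 linear part; must be non-singular.
#' @param b Length-2 translation.
#' @return The transformed trace.
#' @export
to_stimulus_space <- function(fused, A = diag(2), b = c(0, 0)) {
  if (abs(det(A)) < 1e-12) stop("singular gaze calibration transform")
  p <- cbind(fused$x, fused$y) %*% t(A)
  fused$x <- p[, 1] + b[1]
  fused$y <- p[, 2] + b[2]
  fused
}

#' Estimate the screen-to-stimulus affine calibration by least squares
#'
#' Fits `target = A gaze + b` from at least 3 known fixation-target pairs.
#'
#' @param gaze_xy n x 2 matrix of recorded fixation positions.
#' @param target_xy n x 2 matrix of the true stimulus positions.
#' @return List with `A` (2x2) and `b` (length 2).
#' @export
estimate_gaze_transform <- function(gaze_xy, target_xy) {
  gaze_xy <- as.matrix(gaze_xy); target_xy <- as.matrix(target_xy)
  if (nrow(gaze_xy) < 3) stop("need at least 3 fixation-target pairs")
  X <- cbind(gaze_xy, 1)
  beta <- qr.solve(X, target_xy)   # 3 x 2
  list(A = t(beta[1:2, ]), b = as.numeric(beta[3, ]))
}

#' Per-block gaze dwell summary and strategy label
#'
#' Fraction of valid samples within `radius_deg` of each landmark: the
#' block's cued target, the screen center, and any other target. A block
#' is labeled "overt-like" when cued-target dwell exceeds
#' `overt_threshold`, "covert-like" when center dwell exceeds
#' `covert_threshold`, otherwise "mixed"; blocks with no valid sample are
#' "untracked" (eye-tracker failure).
#'
#' @param fused Fused gaze trace in stimulus coordinates.
#' @param blocks Block metadata tibble (`block_id`, `cued_target`,
#'   `condition`, `t_start_ms`, `t_end_ms`).
#' @param positions Target position tibble from [target_positions()].
#' @param radius_deg Landmark dwell radius (degrees).
#' @param overt_threshold,covert_threshold Label thresholds on the dwell
#'   fractions.
#' @return A tibble with one row per block: dwell fractions
#'   `dwell_cued`, `dwell_center`, `dwell_other_targets`,
#'   `dwell_elsewhere`, `valid_fraction` and `strategy_label`.
#' @export
dwell_summary <- function(fused, blocks, positions, radius_deg = 3,
                          overt_threshold = 0.5, covert_threshold = 0.5) {
  purrr::pmap_dfr(
    blocks[, c("block_id", "condition", "cued_target",
               "t_start_ms", "t_end_ms")],
    function(block_id, condition, cued_target, t_start_ms, t_end_ms) {
      seg <- dplyr::filter(fused, .data$t_ms >= t_start_ms,
                           .data$t_ms <= t_end_ms)
      valid <- dplyr::filter(seg, !is.na(.data$x), !is.na(.data$y))
      base <- tibble::tibble(
        block_id = block_id, condition = condition,
        cued_target = cued_target,
        n_samples = nrow(seg), valid_fraction = nrow(valid) /
          max(1, nrow(seg))
      )
      if (nrow(valid) == 0) {
        return(dplyr::mutate(base, dwell_cued = NA_real_,
                             dwell_center = NA_real_,
                             dwell_other_targets = NA_real_,
                             dwell_elsewhere = NA_real_,
                             strategy_label = "untracked"))
      }
      d_to <- function(px, py) sqrt((valid$x - px)^2 + (valid$y - py)^2)
      cued_pos <- positions[positions$target == cued_target, ]
      in_cued <- d_to(cued_pos$x, cued_pos$y) <= radius_deg
      in_center <- d_to(0, 0) <= radius_deg
      others <- positions[positions$target != cued_target, ]
      in_other <- Reduce(`|`, purrr::map2(others$x, others$y,
                                          function(px, py)
                                            d_to(px, py) <= radius_deg))
      assigned <- in_cued | in_center | in_other
      dwell_cued <- mean(in_cued)
      dwell_center <- mean(in_center & !in_cued)
      dwell_other <- mean(in_other & !in_cued & !in_center)
      label <- if (dwell_cued > overt_threshold) "overt-like"
      else if (dwell_center > covert_threshold) "covert-like"
      else "mixed"
      dplyr::mutate(base, dwell_cued = dwell_cued,
                    dwell_center = dwell_center,
                    dwell_other_targets = dwell_other,
                    dwell_elsewhere = mean(!assigned),
                    strategy_label = label)
    })
}
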