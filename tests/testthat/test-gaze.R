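test_that("binocular fusion means, adopts and preserves gaps", {
  g <- tibble::tibble(
    t_ms = c(0, 33, 66),
    lx = c(0.4, NA, 1), ly = c(0.6, NA, 1),
    rx = c(0.6, 0.2, 2), ry = c(0.6, 0.1, 2),
    l_valid = c(TRUE, FALSE, FALSE),
    r_valid = c(TRUE, TRUE, FALSE)
  )
  f <- fuse_binocular(g)
  expect_equal(f$x, c(0.5, 0.2, NA))
  expect_equal(f$y, c(0.6, 0.1, NA))
  expect_equal(f$source, c("both", "right", "none"))
  expect_equal(nrow(f), 3)   # gap preserved, never interpolated
})

test_that("stimulus-space mapping applies affine transforms faithfully", {
  f <- tibble::tibble(t_ms = 0:2, x = c(1, 2, NA), y = c(0, 1, NA),
                      source = c("both", "both", "none"))
  same <- to_stimulus_space(f)
  expect_equal(same$x, f$x)

  shifted <- to_stimulus_space(f, b = c(1, 0))
  expect_equal(shifted$x, f$x + 1)
  expect_equal(shifted$y, f$y)
  expect_true(is.na(shifted$x[3]))

  expect_error(to_stimulus_space(f, A = matrix(0, 2, 2)), "singular")
})

test_that("least-squares calibration recovers a known affine map", {
  set.seed(6)
  A_true <- matrix(c(1.1, 0.05, -0.03, 0.95), 2)
  b_true <- c(0.5, -1)
  gaze <- matrix(runif(20, -15, 15), ncol = 2)
  target <- t(A_true %*% t(gaze) + b_true) +
    matrix(rnorm(20, 0, 0.01), ncol = 2)
  est <- estimate_gaze_transform(gaze, target)
  expect_equal(est$A, A_true, tolerance = 0.01)
  expect_equal(est$b, b_true, tolerance = 0.05)

  mapped <- to_stimulus_space(
    tibble::tibble(t_ms = 1:10, x = gaze[, 1], y = gaze[, 2],
                   source = "both"), est$A, est$b)
  expect_lt(max(abs(cbind(mapped$x, mapped$y) - target)), 0.05)

  expect_error(estimate_gaze_transform(gaze[1:2, ], target[1:2, ]),
               "at least 3")
})

test_that("dwell summaries label fixation strategies and track failures", {
  cfg <- test_cfg()
  pos <- target_positions(cfg)
  blocks <- tibble::tibble(
    block_id = 1:3, condition = c("overt", "covert", "overt"),
    cued_target = c(2L, 2L, 4L),
    t_start_ms = c(0, 1000, 2000), t_end_ms = c(999, 1999, 2999))
  n <- 30
  trace <- dplyr::bind_rows(
    tibble::tibble(t_ms = seq(0, 999, length.out = n),
                   x = pos$x[3], y = pos$y[3], source = "both"),
    tibble::tibble(t_ms = seq(1000, 1999, length.out = n),
                   x = 0, y = 0, source = "both"),
    tibble::tibble(t_ms = seq(2000, 2999, length.out = n),
                   x = NA_real_, y = NA_real_, source = "none"))
  s <- dwell_summary(trace, blocks, pos)
  expect_equal(s$strategy_label, c("overt-like", "covert-like",
                                   "untracked"))
  expect_equal(s$dwell_cued[1], 1)
  expect_equal(s$dwell_center[2], 1)
  expect_equal(s$valid_fraction[3], 0)

  # dwell fractions partition the valid samples
  sums <- rowSums(s[1:2, c("dwell_cued", "dwell_center",
                           "dwell_other_targets", "dwell_elsewhere")])
  expect_equal(unname(sums), c(1, 1))
})

test_that("simulated gaze behavior is recovered by the dwell analysis", {
  ses <- cached("two_cond", simulate_session(
    test_cfg(conditions = c("overt", "covert")),
    noise = noise_spec(sd_uv = 3), seed = 71))
  fused <- fuse_binocular(ses$gaze)
  s <- dwell_summary(fused, ses$blocks, target_positions(ses$config))
  overt_rows <- s$condition == "overt"
  expect_true(all(s$strategy_label[overt_rows] == "overt-like"))
  expect_true(all(s$strategy_label[!overt_rows] == "covert-like"))
})
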