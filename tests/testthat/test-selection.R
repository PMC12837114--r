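test_that("round-structured blocks partition into clean selections", {
  ep <- separable_epochs()
  b1 <- ep$info[ep$info$block_id == ep$info$block_id[1], ]
  parts <- partition_single_trial_selections(b1)
  expect_equal(max(parts$selection_id), 10)
  per_sel <- tapply(parts$stimulus_target, parts$selection_id,
                    function(x) length(unique(x)))
  expect_true(all(per_sel == 6))

  one <- b1[match(0:5, b1$stimulus_target), ]
  expect_equal(max(partition_single_trial_selections(one)$selection_id), 1)

  set.seed(99)
  shuffled <- b1[sample(nrow(b1)), ]
  shuffled$onset_ms <- sort(runif(nrow(shuffled), 0, 1e5))
  expect_message(p2 <- partition_single_trial_selections(shuffled),
                 "greedy")
  expect_gte(max(p2$selection_id), 1)
  per_sel2 <- tapply(p2$stimulus_target, p2$selection_id,
                     function(x) length(unique(x)))
  expect_true(all(per_sel2 == 6))
})

test_that("argmax target selection is deterministic and chance-calibrated", {
  expect_equal(select_target(c(0.9, 0.1, 0.1, 0.1, 0.1, 0.1)), 0L)
  expect_equal(select_target(c(0, 0, 0.5, 0, 0.5, 0)), 2L)
  expect_error(select_target(c(1, NA, 0, 0, 0, 0)), "missing")

  set.seed(12)
  preds <- replicate(10000, select_target(runif(6)))
  truth <- sample(0:5, 10000, replace = TRUE)
  expect_lt(abs(mean(preds == truth) - 1 / 6), 0.02)
})

test_that("k-averaging returns first-k means and shrinks noise like 1/k", {
  ep <- separable_epochs()
  b1 <- vsabci:::subset_epochs(ep, ep$info$block_id == ep$info$block_id[1])
  a1 <- average_k_repetitions(b1, 1)
  expect_equal(dim(a1$data)[1], 6)
  first0 <- which(b1$info$stimulus_target == 0 & b1$info$rep_index == 1)
  expect_equal(a1$data[1, , ], b1$data[first0, , ])
  expect_error(average_k_repetitions(b1, 11), "k must be")

  # pure-noise epochs: variance of the k-mean scales as 1/k
  set.seed(14)
  n <- 500
  noise <- array(rnorm(n * 1 * 20), c(n, 1, 20))
  v1 <- var(as.vector(noise))
  k <- 5
  means <- sapply(seq_len(n / k), function(g)
    apply(noise[((g - 1) * k + 1):(g * k), 1, , drop = FALSE], 3, mean))
  expect_lt(abs(var(as.vector(means)) / (v1 / k) - 1), 0.15)
})

test_that("block-wise CV is perfect on separable data with clean folds", {
  ep <- separable_epochs()
  rep <- blockwise_cv(ep, "tlda", condition = "covert", n_boot = 500)
  expect_equal(rep$accuracy$accuracy, 1)
  expect_equal(c(rep$accuracy$ci_low, rep$accuracy$ci_high), c(1, 1))

  # per-fold test sets are disjoint and cover all 6 blocks
  expect_setequal(unique(rep$selections$block_id),
                  unique(ep$info$block_id))
  expect_equal(nrow(dplyr::distinct(rep$selections, fold, block_id)), 6)
  expect_equal(rep$accuracy$n_selections, nrow(rep$selections))
})

test_that("decoding without any attended response sits at chance level", {
  # amplitude-zero P3: nothing distinguishes targets, so CV accuracy must
  # fall inside the chance-level CI
  ses <- simulate_session(test_cfg(),
                          profiles = covert_profile(jitter = 0, scale = 0),
                          noise = noise_spec(sd_uv = 3), seed = 44)
  ep <- drop_excess_repetitions(
    extract_epochs(rereference_mastoids(bandpass(ses))), 10)
  rep <- blockwise_cv(ep, "tlda", condition = "covert", n_boot = 2000)
  expect_gte(1 / 6, rep$accuracy$ci_low - 0.05)
  expect_lte(1 / 6, rep$accuracy$ci_high + 0.05)
})

test_that("cross-condition diagonal delegates to within-condition CV", {
  ses <- cached("two_cond", simulate_session(
    test_cfg(conditions = c("overt", "covert")),
    noise = noise_spec(sd_uv = 3), seed = 71))
  ep <- drop_excess_repetitions(
    extract_epochs(rereference_mastoids(bandpass(ses))), 10)
  mat <- cross_condition_eval(ep, "tlda", n_boot = 500, seed = 3)
  within <- blockwise_cv(ep, "tlda", condition = "overt", n_boot = 500,
                         seed = 3)
  diag_row <- mat[mat$train_condition == "overt" &
                    mat$test_condition == "overt", ]
  expect_equal(diag_row$accuracy, within$accuracy$accuracy)
  expect_equal(diag_row$ci_low, within$accuracy$ci_low)
  expect_equal(nrow(mat), 4)

  sub <- cross_condition_eval(
    ep, "tlda", n_boot = 200,
    pairs = data.frame(train = "overt", test = "covert"))
  expect_equal(nrow(sub), 1)
})

test_that("bootstrap CIs honor percentile properties", {
  all_right <- bootstrap_ci(rep(TRUE, 40), n_boot = 1000, seed = 2)
  expect_equal(all_right$accuracy, 1)
  expect_equal(c(all_right$ci_low, all_right$ci_high), c(1, 1))

  set.seed(5)
  for (i in 1:20) {
    flags <- runif(50) < runif(1)
    est <- bootstrap_ci(flags, n_boot = 500, seed = i)
    expect_true(est$ci_low <= est$accuracy && est$accuracy <= est$ci_high)
  }
  expect_error(bootstrap_ci(logical(0)), "no selections")

  # deterministic given seed
  a <- bootstrap_ci(rep(c(TRUE, FALSE), 20), seed = 9)
  b <- bootstrap_ci(rep(c(TRUE, FALSE), 20), seed = 9)
  expect_identical(a, b)
})

test_that("repetitions-to-threshold uses an inclusive comparison", {
  expect_equal(reps_to_threshold(c(0.5, 0.7, 0.85, 0.9, 0.95)), 3L)
  expect_true(is.na(reps_to_threshold(c(0.5, 0.6, 0.7))))
  expect_equal(reps_to_threshold(rep(0.8, 10)), 1L)
  tab <- tibble::tibble(k = c(2, 1, 3), accuracy = c(0.7, 0.5, 0.9))
  expect_equal(reps_to_threshold(tab), 3L)
})
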