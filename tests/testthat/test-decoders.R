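test_that("crop-and-decimate arithmetic follows the half-open convention", {
  ep <- separable_epochs()           # [-0.1, 0.9) s @ 250 Hz
  fe <- crop_and_decimate(ep, c(0, 800), decim = 5)
  expect_equal(dim(fe$data)[3], 40)

  raw <- crop_and_decimate(ep, c(0, 800), decim = 1)
  expect_equal(dim(raw$data)[3], 200)
  # decim 1 leaves sample values untouched
  start <- round(0.1 * ep$sfreq) + 1
  expect_equal(raw$data[3, , ], ep$data[3, , start:(start + 199)])

  expect_error(crop_and_decimate(ep, c(0, 1500)), "outside")
})

test_that("tLDA equals unstructured shrinkage LDA at a single time lag", {
  set.seed(21)
  n <- 200; n_ch <- 6
  x <- array(rnorm(n * n_ch), c(n, n_ch, 1))
  y <- rep(c(TRUE, FALSE), n / 2)
  x[y, , 1] <- x[y, , 1] + matrix(c(1, 0.5, 0, -0.5, 0.2, 0.1), n / 2,
                                  n_ch, byrow = TRUE)
  fit <- fit_tlda(x, y)
  oracle <- oracle_shrinkage_lda(x[, , 1], y)
  expect_lt(max(abs(fit$w - oracle$w)) / max(abs(oracle$w)), 1e-6)
  expect_lt(abs(fit$b - oracle$b) / abs(oracle$b), 1e-6)
})

test_that("tLDA approaches the Bayes error on known Gaussians", {
  set.seed(22)
  p <- 6
  delta <- c(1.2, 0, 0.8, 0, -0.5, 0.3)
  A <- matrix(rnorm(p * p, 0, 0.3), p) ; Sigma <- crossprod(A) + diag(p)
  L <- chol(Sigma)
  draw <- function(n, mu) sweep(matrix(rnorm(n * p), n) %*% L, 2, -mu)
  n <- 1000
  xtr <- rbind(draw(n, delta / 2), draw(n, -delta / 2))
  ytr <- rep(c(TRUE, FALSE), each = n)
  xte <- rbind(draw(n, delta / 2), draw(n, -delta / 2))
  yte <- ytr

  fit <- fit_tlda(array(xtr, c(2 * n, p, 1)), ytr)
  pred <- score(fit, array(xte, c(2 * n, p, 1))) > 0
  err <- mean(pred != yte)
  bayes <- pnorm(-sqrt(sum(delta * solve(Sigma, delta))) / 2)
  expect_lt(abs(err - bayes), 0.03)
})

test_that("tLDA weights are invariant to duplicating every epoch", {
  set.seed(23)
  x <- array(rnorm(60 * 4 * 5), c(60, 4, 5))
  y <- rep(c(TRUE, FALSE), 30)
  x[y, , ] <- x[y, , ] + 0.5
  a <- fit_tlda(x, y, shrinkage = 0.2)
  b <- fit_tlda(x[rep(1:60, 2), , ], rep(y, 2), shrinkage = 0.2)
  expect_equal(a$w, b$w, tolerance = 1e-10)
  expect_equal(a$b, b$b, tolerance = 1e-10)
})

test_that("linear scores separate class means and honor the bias", {
  fe <- cached("sep_fe", crop_and_decimate(separable_epochs(), c(0, 800)))
  fit <- cached("sep_tlda", fit_tlda(fe))
  sc <- score(fit, fe)
  expect_gt(mean(sc[fe$info$is_target]), mean(sc[!fe$info$is_target]))

  zero <- array(0, c(1, dim(fe$data)[2], dim(fe$data)[3]))
  expect_equal(score(fit, zero), fit$b)

  bad <- array(0, c(1, 2, 3))
  expect_error(score(fit, bad), "mismatch")
})

test_that("xDAWN tangent-space model has the right geometry and separates", {
  fe <- cached("sep_fe", crop_and_decimate(separable_epochs(), c(0, 800)))
  fit <- fit_xdawn_ts(fe, n_filters = 4)

  d <- 3 * 4
  expect_equal(nrow(fit$ref_mean), d)
  ev <- eigen(fit$ref_mean, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)

  V <- vsabci:::xdawn_tangent_vectors(fit, fe$data[1:5, , , drop = FALSE])
  expect_equal(ncol(V), d * (d + 1) / 2)

  # noise-free separable session: perfect cross-validated selections
  rep <- blockwise_cv(separable_epochs(), "xdawn_ts", condition = "covert",
                      n_boot = 200)
  expect_equal(rep$accuracy$accuracy, 1)
})

test_that("WCBLE recovers known latency shifts from constructed epochs", {
  fx <- make_shifted_epochs(noise_sd = 0.5, seed = 7)
  m <- fit_wcble(fx$epochs, n_iter = 5)
  ti <- seq_len(fx$n_target)
  expect_gt(cor(m$train_latency_ms[ti], fx$shifts), 0.9)

  sc <- wcble_score(m, fx$epochs)
  expect_gt(cor(sc$latency_ms[ti], fx$shifts), 0.9)

  # an epoch shifted +80 ms reports a latency within 10 ms of +80
  probe <- make_shifted_epochs(n_target = 1, n_nontarget = 1,
                               shift_range = c(80, 80), noise_sd = 0.01,
                               seed = 9)
  sc80 <- wcble_score(m, probe$epochs)
  expect_lt(abs(sc80$latency_ms[1] - 80), 10 + 1e-9)
})

test_that("WCBLE stays at nominal alignment when there is no jitter", {
  ses <- simulate_session(test_cfg(), profiles = covert_profile(jitter = 0),
                          noise = noise_spec(sd_uv = 0.5), seed = 31)
  ep <- drop_excess_repetitions(
    extract_epochs(rereference_mastoids(bandpass(ses))), 10)
  m <- fit_wcble(ep)
  expect_lt(mean(abs(m$train_latency_ms[ep$info$is_target])), 10)
})

test_that("zero-width search reduces WCBLE to the base tLDA exactly", {
  ep <- separable_epochs()
  m <- fit_wcble(ep, search_window_ms = c(0, 0))
  base <- fit_tlda(crop_and_decimate(ep, c(0, 800)))
  expect_equal(m$base$w, base$w)
  sc <- wcble_score(m, ep)
  expect_equal(sc$score, score(base, crop_and_decimate(ep, c(0, 800))))
  expect_true(all(sc$latency_ms == 0))

  expect_error(fit_wcble(ep, search_window_ms = c(-400, 400)), "slack")
})

test_that("the max-over-latency score dominates the nominal score", {
  fx <- make_shifted_epochs(n_target = 20, n_nontarget = 80, seed = 11)
  m <- fit_wcble(fx$epochs, n_iter = 2)
  sc_w <- wcble_score(m, fx$epochs)$score
  sc_n <- score(m$base, crop_and_decimate(fx$epochs, c(0, 800)))
  expect_true(all(sc_w >= sc_n - 1e-12))

  zero_ep <- fx$epochs
  zero_ep$data[] <- 0
  expect_equal(unique(wcble_score(m, zero_ep)$score), m$base$b)
})

test_that("fitted decoders round-trip through the JSON container", {
  fe <- cached("sep_fe", crop_and_decimate(separable_epochs(), c(0, 800)))
  fit <- cached("sep_tlda", fit_tlda(fe))
  path <- withr::local_tempfile(fileext = ".json")
  write_decoder(fit, path)
  back <- read_decoder(path)
  expect_equal(back$w, fit$w)
  expect_equal(back$b, fit$b)
  expect_equal(score(back, fe), score(fit, fe))
})
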