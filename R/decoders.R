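# ERP decoders: block-Toeplitz LDA (tLDA), xDAWN-covariance tangent-space
# LDA, and WCBLE (classifier-based latency estimation with Woody
# iterations). Features are spatiotemporal: channels x decimated samples,
# flattened time-major (channel index fastest).

#' Crop and decimate epochs into decoder features
#'
#' Time-crops each epoch to `window_ms` (half-open) and reduces the sample
#' rate by averaging consecutive groups of `decim` samples (boxcar bins).
#' The data are already low-passed well below the decimated Nyquist by the
#' standard 0.5-16 Hz filter, so bin means are alias-free. The default
#' `decim` targets 50 Hz features.
#'
#' @param epochs An `epoch_set`.
#' @param window_ms Length-2 crop window, ms relative to stimulus onset.
#' @param decim Decimation factor (samples per bin); default
#'   `round(sfreq / 50)`.
#' @return A `feature_epochs` object: `data` (epochs x channels x bins),
#'   `info`, `bin_ms`, `window_ms`, `channel_names`.
#' @export
crop_and_decimate <- function(epochs, window_ms = c(0, 800), decim = NULL) {
  if (is.null(decim)) decim <- max(1L, round(epochs$sfreq / 50))
  span_ms <- c(epochs$tmin, epochs$tmax) * 1000
  if (window_ms[1] < span_ms[1] || window_ms[2] > span_ms[2]) {
    stop("window [", window_ms[1], ", ", window_ms[2],
         "] ms outside epoch span [", span_ms[1], ", ", span_ms[2], "] ms")
  }
  start <- round((window_ms[1] / 1000 - epochs$tmin) * epochs$sfreq) + 1L
  n_win <- round(diff(window_ms) / 1000 * epochs$sfreq)
  n_bins <- floor(n_win / decim)
  if (n_bins < 1) stop("window too short for decimation factor ", decim)
  structure(list(
    data = bin_epochs(epochs$data, start, decim, n_bins),
    info = epochs$info,
    bin_ms = decim / epochs$sfreq * 1000,
    window_ms = window_ms,
    decim = decim,
    channel_names = epochs$channel_names
  ), class = "feature_epochs")
}

# Boxcar-bin samples: data [n, C, S] -> [n, C, n_bins], bin b = mean of
# samples start + (b-1)*decim .. start + b*decim - 1.
bin_epochs <- function(data, start, decim, n_bins) {
  n <- dim(data)[1]; n_ch <- dim(data)[2]
  out <- array(0, c(n, n_ch, n_bins))
  for (b in seq_len(n_bins)) {
    c0 <- start + (b - 1L) * decim
    acc <- data[, , c0]
    if (decim > 1L) {
      for (k in seq_len(decim - 1L)) acc <- acc + data[, , c0 + k]
      acc <- acc / decim
    }
    out[, , b] <- acc
  }
  out
}

# Flatten [n, C, T] to n x (C*T), time-major (channel fastest).
flatten_features <- function(x) {
  if (inherits(x, "feature_epochs")) x <- x$data
  stopifnot(length(dim(x)) == 3)
  d <- dim(x)
  t(matrix(aperm(x, c(2, 3, 1)), d[2] * d[3], d[1]))
}

# Ledoit-Wolf-style analytic shrinkage toward nu * I.
# Xc: rows centered (per class). Returns S (MLE, denominator n), nu, gamma.
lw_stats <- function(Xc) {
  n <- nrow(Xc)
  S <- crossprod(Xc) / n
  nu <- mean(diag(S))
  sum_w2 <- crossprod(Xc^2)         # sum_k (x_ki x_kj)^2
  var_s <- (n / (n - 1)^3) * (sum_w2 - n * S^2)
  target <- diag(nu, ncol(S))
  denom <- sum((S - target)^2)
  gamma <- if (denom <= 0) 0 else min(1, max(0, sum(var_s) / denom))
  list(S = S, nu = nu, gamma = gamma)
}

# Average the C x C blocks of S along equal time-lag diagonals, enforcing
# the block-Toeplitz structure C(t, t') = B(t' - t).
toeplitz_structure <- function(S, n_ch, n_t) {
  B <- vector("list", n_t)
  for (lag in 0:(n_t - 1)) {
    acc <- matrix(0, n_ch, n_ch)
    for (t in 1:(n_t - lag)) {
      r <- ((t - 1) * n_ch + 1):(t * n_ch)
      c <- ((t + lag - 1) * n_ch + 1):((t + lag) * n_ch)
      acc <- acc + S[r, c, drop = FALSE]
    }
    B[[lag + 1]] <- acc / (n_t - lag)
  }
  B[[1]] <- (B[[1]] + t(B[[1]])) / 2
  out <- matrix(0, n_ch * n_t, n_ch * n_t)
  for (t1 in 1:n_t) {
    for (t2 in 1:n_t) {
      r <- ((t1 - 1) * n_ch + 1):(t1 * n_ch)
      c <- ((t2 - 1) * n_ch + 1):(t2 * n_ch)
      out[r, c] <- if (t2 >= t1) B[[t2 - t1 + 1]] else t(B[[t1 - t2 + 1]])
    }
  }
  out
}

# Core shrinkage-LDA fit on a feature matrix; optionally with the pooled
# covariance replaced by its block-Toeplitz average before shrinkage.
fit_lda_core <- function(X, y, shrinkage = NULL, block_toeplitz = FALSE,
                         n_ch = NULL, n_t = NULL) {
  if (length(unique(y)) < 2) stop("both classes must be present")
  mu1 <- colMeans(X[y, , drop = FALSE])
  mu0 <- colMeans(X[!y, , drop = FALSE])
  Xc <- X
  Xc[y, ] <- sweep(X[y, , drop = FALSE], 2, mu1)
  Xc[!y, ] <- sweep(X[!y, , drop = FALSE], 2, mu0)
  st <- lw_stats(Xc)
  gamma <- if (is.null(shrinkage)) st$gamma else shrinkage
  S <- st$S
  if (block_toeplitz) S <- toeplitz_structure(S, n_ch, n_t)
  Sigma <- (1 - gamma) * S + gamma * diag(st$nu, ncol(S))
  if (block_toeplitz) {
    # Lag-averaging a sample covariance need not stay positive definite;
    # clamp the spectrum at the shrinkage ridge level when it does not.
    ok <- tryCatch({ chol(Sigma); TRUE }, error = function(e) FALSE)
    if (!ok) {
      floor_val <- max(gamma, 1e-4) * st$nu
      Sigma <- sym_eig_fun(Sigma, function(v) pmax(v, floor_val))
    }
  }
  w <- solve(Sigma, mu1 - mu0)
  b <- -sum(w * (mu1 + mu0) / 2)
  list(w = as.numeric(w), b = b, mu_target = mu1, mu_nontarget = mu0,
       gamma = gamma, nu = st$nu)
}

#' Fit a block-Toeplitz LDA decoder
#'
#' Binary linear discriminant on flattened spatiotemporal features. The
#' pooled within-class covariance is averaged over equal time-lag
#' channel-blocks (its stationarity-in-time structure), then shrunk toward
#' a scaled identity with an analytically chosen intensity (Ledoit-Wolf
#' style; override via `shrinkage`). Weights solve
#' `Sigma w = mu_target - mu_nontarget`; the bias centers scores at the
#' class-mean midpoint. With a single retained time sample the structure
#' constraint is vacuous and the fit equals ordinary shrinkage LDA.
#'
#' @param features A `feature_epochs` object (labels taken from
#'   `info$is_target`), or a 3-D array `[epochs, channels, samples]`.
#' @param labels Logical target labels; required for array input.
#' @param shrinkage Shrinkage intensity in `[0, 1]`, or `NULL` for the
#'   analytic estimate.
#' @return A `tlda_model`.
#' @export
fit_tlda <- function(features, labels = NULL, shrinkage = NULL) {
  if (inherits(features, "feature_epochs")) {
    if (is.null(labels)) labels <- features$info$is_target
    dims <- dim(features$data)
    meta <- features[c("bin_ms", "window_ms", "decim", "channel_names")]
  } else {
    dims <- dim(features)
    meta <- list(bin_ms = NA, window_ms = NULL, decim = NA,
                 channel_names = NULL)
  }
  X <- flatten_features(features)
  fit <- fit_lda_core(X, as.logical(labels), shrinkage,
                      block_toeplitz = TRUE, n_ch = dims[2], n_t = dims[3])
  structure(c(fit, list(n_channels = dims[2], n_times = dims[3]), meta),
            class = "tlda_model")
}

#' @export
print.tlda_model <- function(x, ...) {
  cat("<tlda_model> ", x$n_channels, " channels x ", x$n_times,
      " samples, shrinkage ", signif(x$gamma, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.tlda_model
#' @method glance tlda_model
#' @export
glance.tlda_model <- function(x, ...) {
  tibble::tibble(n_channels = x$n_channels, n_times = x$n_times,
                 n_features = length(x$w), shrinkage = x$gamma,
                 nu = x$nu, bias = x$b)
}

#' Tidiers for tLDA models
#'
#' `tidy()` returns one row per weight with its channel and time bin;
#' `glance()` a one-row fit summary.
#'
#' @param x A `tlda_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tlda_model
#' @export
tidy.tlda_model <- function(x, ...) {
  ch <- x$channel_names %||% paste0("ch", seq_len(x$n_channels))
  t_ms <- if (!is.null(x$window_ms)) {
    x$window_ms[1] + (seq_len(x$n_times) - 0.5) * x$bin_ms
  } else seq_len(x$n_times)
  tibble::tibble(
    channel = rep(ch, times = x$n_times),
    t_ms = rep(t_ms, each = x$n_channels),
    weight = x$w
  )
}

#' Score epochs with a fitted linear decoder
#'
#' Returns `w . x + b` per epoch; higher means more target-like.
#'
#' @param model A fitted decoder model.
#' @param features Features laid out as at training time.
#' @param ... Method arguments.
#' @return Numeric score vector.
#' @export
score <- function(model, features, ...) UseMethod("score")

#' @export
score.tlda_model <- function(model, features, ...) {
  X <- if (is.matrix(features)) features else flatten_features(features)
  if (ncol(X) != length(model$w)) {
    stop("feature layout mismatch: got ", ncol(X), " features, model has ",
         length(model$w))
  }
  as.numeric(X %*% model$w + model$b)
}

# ---- xDAWN covariance + tangent space ------------------------------------

sym_eig_fun <- function(M, f) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

spd_floor <- function(M, rel = 1e-10) {
  tr <- sum(diag(M))
  floor_val <- max(rel * tr, .Machine$double.eps)
  sym_eig_fun(M, function(v) pmax(v, floor_val))
}

# Affine-invariant Riemannian mean of SPD matrices (fixed-point iteration).
riemann_mean <- function(mats, tol = 1e-8, max_iter = 50) {
  M <- Reduce(`+`, mats) / length(mats)
  for (i in seq_len(max_iter)) {
    Mi <- sym_eig_fun(M, function(v) 1 / sqrt(v))
    Ms <- sym_eig_fun(M, sqrt)
    logs <- lapply(mats, function(C) sym_eig_fun(Mi %*% C %*% Mi, log))
    J <- Reduce(`+`, logs) / length(mats)
    M <- Ms %*% sym_eig_fun(J, exp) %*% Ms
    M <- (M + t(M)) / 2
    if (sqrt(sum(J^2)) < tol) break
  }
  M
}

# Upper-triangular vectorization with sqrt(2) off-diagonal weighting.
tangent_vec <- function(S) {
  d <- nrow(S)
  up <- upper.tri(S)
  c(diag(S), sqrt(2) * S[up])
}

xdawn_filters <- function(evoked, noise_cov, n_filters) {
  Cs <- evoked %*% t(evoked) / ncol(evoked)
  eps <- 1e-12 * sum(diag(noise_cov))
  W <- eigen(solve(noise_cov + diag(eps, nrow(noise_cov)), Cs))$vectors
  W <- Re(W[, seq_len(n_filters), drop = FALSE])
  apply(W, 2, function(v) v / sqrt(sum(v^2)))
}

#' Fit an xDAWN-covariance tangent-space LDA decoder
#'
#' Per class, xDAWN spatial filters are the leading generalized
#' eigenvectors of the class-evoked covariance against the noise
#' covariance. Each epoch is augmented with the filtered class prototypes
#' (target and non-target evoked responses) and its own filtered signal,
#' giving a `3 * n_filters`-row matrix whose covariance is regularized to
#' SPD by eigenvalue flooring, projected to the tangent space at the
#' affine-invariant Riemannian mean of the training covariances, and
#' classified by shrinkage LDA on the tangent vectors.
#'
#' @param features A `feature_epochs` or 3-D array.
#' @param labels Logical target labels (defaults to `info$is_target`).
#' @param n_filters xDAWN filters per class.
#' @param reg Relative eigenvalue floor for covariance regularization.
#' @return An `xdawn_ts_model`.
#' @export
fit_xdawn_ts <- function(features, labels = NULL, n_filters = 4,
                         reg = 1e-10) {
  if (inherits(features, "feature_epochs") && is.null(labels)) {
    labels <- features$info$is_target
  }
  x <- if (inherits(features, "feature_epochs")) features$data else features
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n_t <- dim(x)[3]

  E1 <- apply(x[labels, , , drop = FALSE], c(2, 3), mean)
  E0 <- apply(x[!labels, , , drop = FALSE], c(2, 3), mean)
  Cn <- matrix(0, dim(x)[2], dim(x)[2])
  for (i in seq_len(dim(x)[1])) {
    Cn <- Cn + x[i, , ] %*% t(x[i, , ]) / n_t
  }
  Cn <- Cn / dim(x)[1]
  W1 <- xdawn_filters(E1, Cn, n_filters)
  W0 <- xdawn_filters(E0, Cn, n_filters)
  P1 <- t(W1) %*% E1
  P0 <- t(W0) %*% E0

  covs <- lapply(seq_len(dim(x)[1]), function(i) {
    Z <- rbind(P1, P0, t(W1) %*% x[i, , ])
    spd_floor(Z %*% t(Z) / (n_t - 1), reg)
  })
  M <- riemann_mean(covs)
  Mi <- sym_eig_fun(M, function(v) 1 / sqrt(v))
  V <- t(vapply(covs, function(C)
    tangent_vec(sym_eig_fun(Mi %*% C %*% Mi, log)),
    numeric(nrow(M) * (nrow(M) + 1) / 2)))
  lda <- fit_lda_core(V, labels)

  structure(list(
    n_filters = n_filters, filters_target = W1, filters_nontarget = W0,
    prototype_target = P1, prototype_nontarget = P0,
    ref_mean = M, ref_invsqrt = Mi, reg = reg, lda = lda,
    n_channels = dim(x)[2], n_times = n_t
  ), class = "xdawn_ts_model")
}

#' @export
print.xdawn_ts_model <- function(x, ...) {
  d <- 3 * x$n_filters
  cat("<xdawn_ts_model> ", x$n_filters, " filters/class, augmented dim ", d,
      ", tangent dim ", d * (d + 1) / 2, "\n", sep = "")
  invisible(x)
}

#' @method glance xdawn_ts_model
#' @export
glance.xdawn_ts_model <- function(x, ...) {
  d <- 3 * x$n_filters
  tibble::tibble(n_filters = x$n_filters, augmented_dim = d,
                 tangent_dim = d * (d + 1) / 2,
                 lda_shrinkage = x$lda$gamma)
}

# Map epochs through the fitted xDAWN+tangent pipeline.
xdawn_tangent_vectors <- function(model, x) {
  t(vapply(seq_len(dim(x)[1]), function(i) {
    Z <- rbind(model$prototype_target, model$prototype_nontarget,
               t(model$filters_target) %*% x[i, , ])
    C <- spd_floor(Z %*% t(Z) / (dim(x)[3] - 1), model$reg)
    tangent_vec(sym_eig_fun(model$ref_invsqrt %*% C %*% model$ref_invsqrt,
                            log))
  }, numeric(nrow(model$ref_mean) * (nrow(model$ref_mean) + 1) / 2)))
}

#' @export
score.xdawn_ts_model <- function(model, features, ...) {
  x <- if (inherits(features, "feature_epochs")) features$data else features
  if (dim(x)[2] != model$n_channels) {
    stop("feature layout mismatch: expected ", model$n_channels,
         " channels")
  }
  V <- xdawn_tangent_vectors(model, x)
  as.numeric(V %*% model$lda$w + model$lda$b)
}

# ---- WCBLE ----------------------------------------------------------------

# Bin a wide epoch_set once; shifts are expressed in whole bins so that a
# window shifted by s bins is a contiguous bin slice.
wcble_binning <- function(wide, window_ms, decim) {
  if (is.null(decim)) decim <- max(1L, round(wide$sfreq / 50))
  off_samples <- round((window_ms[1] / 1000 - wide$tmin) * wide$sfreq)
  if (off_samples %% decim != 0) {
    stop("window start must be an integer number of bins from epoch start")
  }
  n_bins_wide <- floor(dim(wide$data)[3] / decim)
  n_bins_win <- floor(round(diff(window_ms) / 1000 * wide$sfreq) / decim)
  list(decim = decim, off = off_samples %/% decim,
       n_wide = n_bins_wide, n_win = n_bins_win,
       bin_ms = decim / wide$sfreq * 1000)
}

wcble_slice <- function(binned, off, n_win, shifts) {
  n <- dim(binned)[1]
  out <- array(0, c(n, dim(binned)[2], n_win))
  for (i in seq_len(n)) {
    cols <- (off + shifts[i] + 1):(off + shifts[i] + n_win)
    out[i, , ] <- binned[i, , cols]
  }
  out
}

#' Fit a WCBLE decoder (Woody-iterated classifier-based latency estimation)
#'
#' Handles trial-to-trial latency jitter of the attended-target response.
#' Iteration 0 fits a [fit_tlda()] on the nominal `window_ms` crop of wide
#' epochs (-100 to 900 ms by default). Each Woody iteration then slides
#' the classifier over every target-labeled training epoch, takes the
#' latency of the maximum classification score inside `search_window_ms`
#' (earliest latency on ties), re-cuts the target epochs at their aligned
#' windows, and refits; non-target epochs stay at nominal alignment (they
#' carry no attended response to align). Iterations stop at `n_iter` or
#' when the mean absolute latency change drops below `tol_ms`.
#'
#' @param wide_epochs An `epoch_set` wider than the classifier window,
#'   e.g. cut at -0.1..0.9 s.
#' @param labels Logical target labels (defaults to `info$is_target`).
#' @param window_ms Classifier window (ms), default `c(0, 800)`.
#' @param decim Decimation factor; latency search runs on the binned grid.
#' @param n_iter Maximum Woody iterations.
#' @param search_window_ms Allowed latency range (ms); must fit inside the
#'   wide epoch minus the classifier window.
#' @param tol_ms Convergence tolerance on the mean absolute latency change.
#' @param shrinkage Passed to [fit_tlda()].
#' @return A `wcble_model`: the final `tlda_model` plus alignment state
#'   (per-iteration mean latency change, final training latencies).
#' @export
fit_wcble <- function(wide_epochs, labels = NULL, window_ms = c(0, 800),
                      decim = NULL, n_iter = 3,
                      search_window_ms = c(-100, 100), tol_ms = 5,
                      shrinkage = NULL) {
  if (is.null(labels)) labels <- wide_epochs$info$is_target
  labels <- as.logical(labels)
  stopifnot(n_iter >= 1)
  bn <- wcble_binning(wide_epochs, window_ms, decim)
  s_lo <- ceiling(search_window_ms[1] / bn$bin_ms)
  s_hi <- floor(search_window_ms[2] / bn$bin_ms)
  if (bn$off + s_lo < 0 || bn$off + s_hi + bn$n_win > bn$n_wide) {
    stop("search window exceeds the slack of the wide epoch")
  }
  s_range <- s_lo:s_hi

  binned <- bin_epochs(wide_epochs$data, 1L, bn$decim,
                       bn$n_wide)
  n <- dim(binned)[1]
  shifts <- integer(n)
  trace <- numeric(0)
  model <- fit_tlda_binned(binned, bn, shifts, labels, wide_epochs,
                           window_ms, shrinkage)
  ti <- which(labels)
  for (it in seq_len(n_iter)) {
    if (length(s_range) == 1) break
    sc <- vapply(s_range, function(s) {
      X <- flatten_features(wcble_slice(binned[ti, , , drop = FALSE],
                                        bn$off, bn$n_win,
                                        rep(s, length(ti))))
      as.numeric(X %*% model$w + model$b)
    }, numeric(length(ti)))
    if (length(ti) == 1) sc <- matrix(sc, nrow = 1)
    new_shifts <- shifts
    new_shifts[ti] <- s_range[apply(sc, 1, which.max)]
    delta_ms <- mean(abs(new_shifts[ti] - shifts[ti])) * bn$bin_ms
    trace <- c(trace, delta_ms)
    shifts <- new_shifts
    model <- fit_tlda_binned(binned, bn, shifts, labels, wide_epochs,
                             window_ms, shrinkage)
    if (delta_ms < tol_ms) break
  }
  structure(list(
    base = model, binning = bn, s_range = s_range,
    window_ms = window_ms, search_window_ms = search_window_ms,
    n_iterations = length(trace), convergence_trace_ms = trace,
    train_latency_ms = shifts * bn$bin_ms,
    channel_names = wide_epochs$channel_names
  ), class = "wcble_model")
}

fit_tlda_binned <- function(binned, bn, shifts, labels, wide, window_ms,
                            shrinkage) {
  x <- wcble_slice(binned, bn$off, bn$n_win, shifts)
  fe <- structure(list(data = x, info = wide$info, bin_ms = bn$bin_ms,
                       window_ms = window_ms, decim = bn$decim,
                       channel_names = wide$channel_names),
                  class = "feature_epochs")
  fit_tlda(fe, labels, shrinkage)
}

#' @export
print.wcble_model <- function(x, ...) {
  cat("<wcble_model> search ", x$search_window_ms[1], "..",
      x$search_window_ms[2], " ms (", length(x$s_range), " latencies), ",
      x$n_iterations, " Woody iteration(s)\n", sep = "")
  invisible(x)
}

#' @method glance wcble_model
#' @export
glance.wcble_model <- function(x, ...) {
  tibble::tibble(
    n_latencies = length(x$s_range),
    n_iterations = x$n_iterations,
    final_mean_latency_change_ms =
      if (length(x$convergence_trace_ms)) utils::tail(
        x$convergence_trace_ms, 1) else NA_real_,
    base_shrinkage = x$base$gamma
  )
}

#' Score wide epochs with a WCBLE model
#'
#' The decision score of an epoch is the maximum of the sliding
#' classification score over the allowed latencies (ties resolved to the
#' earliest latency); the argmax latency is reported for diagnostics.
#' Because the nominal latency is in the searched set, the WCBLE score is
#' never below the base classifier's score at nominal alignment.
#'
#' @param model A `wcble_model`.
#' @param wide_epochs An `epoch_set` with the training-time wide span.
#' @return A tibble `score`, `latency_ms`.
#' @export
wcble_score <- function(model, wide_epochs) {
  if (!identical(wide_epochs$channel_names, model$channel_names)) {
    stop("feature layout mismatch: channel sets differ")
  }
  bn <- model$binning
  binned <- bin_epochs(wide_epochs$data, 1L, bn$decim, bn$n_wide)
  n <- dim(binned)[1]
  sc <- vapply(model$s_range, function(s) {
    X <- flatten_features(wcble_slice(binned, bn$off, bn$n_win, rep(s, n)))
    as.numeric(X %*% model$base$w + model$base$b)
  }, numeric(n))
  if (n == 1) sc <- matrix(sc, nrow = 1)
  best <- apply(sc, 1, which.max)
  tibble::tibble(
    score = sc[cbind(seq_len(n), best)],
    latency_ms = model$s_range[best] * bn$bin_ms
  )
}

#' @export
score.wcble_model <- function(model, features, ...) {
  wcble_score(model, features)$score
}

# ---- serialization --------------------------------------------------------

#' Write/read a fitted decoder as a JSON container
#'
#' All numeric state is stored as JSON arrays at full double precision
#' with a version tag, so models round-trip exactly.
#'
#' @param model A `tlda_model`, `xdawn_ts_model` or `wcble_model`.
#' @param path Output file.
#' @return `path` invisibly; `read_decoder()` returns the model.
#' @export
write_decoder <- function(model, path) {
  payload <- list(format = "vsabci-decoder", version = 1L,
                  class = class(model)[1],
                  state = unclass_deep(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep)
  } else x
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = TRUE)
  if (is.null(p$format) || p$format != "vsabci-decoder") {
    stop("not a vsabci decoder file: ", path)
  }
  st <- restore_numeric(p$state)
  structure(st, class = p$class)
}

restore_numeric <- function(x) {
  if (is.list(x) && !is.data.frame(x)) lapply(x, restore_numeric) else x
}
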