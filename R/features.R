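#' Windowing parameters L, K, N
#'
#' One analysis window covers `L * K * N` consecutive samples of every
#' channel: `L` raw samples are averaged into one segment mean, `K` segment
#' means form the series over which each pairwise Pearson correlation is
#' computed, and `N` consecutive correlation matrices form the sequence seen
#' by the LSTM (one per time step). The defaults `L = 2, K = 8, N = 10` are
#' the setting selected by the hyperparameter sweep; at 128 Hz they cover
#' 1.25 s of signal, at 200 Hz 0.8 s.
#'
#' @param L samples per segment (`>= 1`; `>= 2` recommended for noise
#'   reduction).
#' @param K segments per correlation matrix (`>= 2`, since a correlation
#'   needs at least two points).
#' @param N correlation matrices (LSTM time steps) per window (`>= 1`).
#' @return an object of class `windowing_params`.
#' @export
windowing_params <- function(L = 2L, K = 8L, N = 10L) {
  if (!is_count(L, 1L)) abort("`L` must be an integer >= 1")
  if (!is_count(K, 2L)) abort("`K` must be an integer >= 2 (correlation needs >= 2 points)")
  if (!is_count(N, 1L)) abort("`N` must be an integer >= 1")
  structure(list(L = as.integer(L), K = as.integer(K), N = as.integer(N)),
            class = "windowing_params")
}

#' @rdname windowing_params
#' @param params a `windowing_params`.
#' @export
window_samples <- function(params) params$L * params$K * params$N

#' @rdname windowing_params
#' @param rate sampling rate in Hz.
#' @export
window_seconds <- function(params, rate) window_samples(params) / rate

#' @export
print.windowing_params <- function(x, ...) {
  cat(sprintf("<windowing_params> L=%d K=%d N=%d (window %d samples)\n",
              x$L, x$K, x$N, window_samples(x)))
  invisible(x)
}

#' Extract one raw analysis window as a C x L x K x N tensor
#'
#' Cuts `L * K * N` consecutive samples per channel starting at 0-based
#' `start_sample` into non-overlapping segments, ordered time-major: segment
#' `(k, n)` (both 0-based) covers samples
#' `start + ((n*K) + k)*L ... start + ((n*K) + k + 1)*L - 1`.
#'
#' @param rec a [raw_recording()].
#' @param start_sample 0-based index of the first sample in the window.
#' @param params a [windowing_params()].
#' @return a numeric array of dim `(C, L, K, N)` with class `window_tensor`;
#'   attributes carry `params` and the source recording's identifiers.
#' @export
extract_window <- function(rec, start_sample, params) {
  stopifnot(inherits(rec, "raw_recording"), inherits(params, "windowing_params"))
  if (!is_count(start_sample, 0L)) abort("`start_sample` must be a non-negative integer")
  w <- window_samples(params)
  M <- n_samples(rec)
  if (start_sample + w > M)
    abort("window [%d, %d) exceeds recording of %d samples",
          start_sample, start_sample + w, M)
  slab <- rec$data[, (start_sample + 1L):(start_sample + w), drop = FALSE]
  dimnames(slab) <- NULL
  # column-major reshape of C x (L*K*N) gives exactly the time-major layout
  E <- array(slab, dim = c(nrow(slab), params$L, params$K, params$N))
  structure(E, class = "window_tensor", params = params,
            source = list(subject_id = rec$subject_id, trial_id = rec$trial_id,
                          start_sample = as.integer(start_sample)))
}

#' Segment-mean single-channel features
#'
#' Reduces a raw window `E` (C x L x K x N) to `S` (C x K x N), where
#' `S[c, k, n]` is the arithmetic mean of the `L` raw samples in segment
#' `(k, n)` of channel `c`. This is the data-size reduction step that
#' precedes the correlation features.
#'
#' @param E a [extract_window()] tensor.
#' @return numeric array of dim `(C, K, N)` with class
#'   `single_channel_features`.
#' @export
single_channel_features <- function(E) {
  stopifnot(inherits(E, "window_tensor"))
  params <- attr(E, "params")
  S <- colMeans(aperm(unclass(E), c(2L, 1L, 3L, 4L)), dims = 1L)
  structure(S, class = "single_channel_features", params = params,
            source = attr(E, "source"))
}

# Pearson correlation matrix of the columns of a K x C matrix with the
# package's degenerate-channel convention: a zero-variance column gets 0
# off-diagonals and 1 on the diagonal. Entries are clipped to [-1, 1] to
# absorb floating-point overshoot only.
.cor_matrix <- function(X, warn_degenerate = TRUE) {
  Xc <- sweep(X, 2L, colMeans(X))
  ss <- colSums(Xc * Xc)
  zero <- ss <= 0
  denom <- sqrt(ss)
  denom[zero] <- 1 # avoid 0/0; rows are overwritten below
  R <- crossprod(Xc) / tcrossprod(denom)
  if (any(zero)) {
    if (warn_degenerate)
      warning(sprintf("%d channel(s) with zero-variance segment means; their correlations set to 0",
                      sum(zero)), call. = FALSE)
    R[zero, ] <- 0
    R[, zero] <- 0
  }
  R <- (R + t(R)) / 2
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

#' Channel-wise feature: the C x C Pearson correlation matrix at one step
#'
#' `F[x, y]` is the sample Pearson correlation of the two K-vectors of
#' segment means `S[x, , n]` and `S[y, , n]` — the spatial-connectivity
#' representation at LSTM time step `n`. The matrix is symmetric with unit
#' diagonal and entries in `[-1, 1]`. If a channel's K segment means are
#' constant the correlation is undefined (0/0); by convention its
#' off-diagonal entries are 0 (with a warning) and the diagonal stays 1, so
#' a flat-lined channel cannot poison the window.
#'
#' @param S a [single_channel_features()] array.
#' @param n 1-based time-step index in `[1, N]`.
#' @return C x C numeric matrix of class `channel_wise_feature` with
#'   attribute `time_index = n`.
#' @export
channel_wise_feature <- function(S, n) {
  stopifnot(inherits(S, "single_channel_features"))
  d <- dim(S)
  if (d[2L] < 2L) abort("K = %d: correlation needs at least 2 segments", d[2L])
  if (!is_count(n, 1L) || n > d[3L]) abort("time index n = %s out of [1, %d]", format(n), d[3L])
  X <- t(unclass(S)[, , n]) # K x C
  R <- .cor_matrix(X)
  structure(R, class = c("channel_wise_feature", "matrix"),
            time_index = as.integer(n))
}

#' Flatten / restore the strict upper triangle of a channel-wise feature
#'
#' Because the correlation matrix is symmetric with a fixed unit diagonal,
#' only its `C*(C-1)/2` strictly-upper-triangle entries are informative
#' (496 for C = 32, 1891 for C = 62). The flattening order is row-major:
#' `(1,2), (1,3), ..., (1,C), (2,3), ...` — fixed so features are portable
#' across runs. `unflatten_upper_triangle()` inverts it, restoring a
#' symmetric matrix with unit diagonal (used for tests and heatmaps).
#'
#' @param F a symmetric C x C matrix (e.g. a [channel_wise_feature()]).
#' @return numeric vector of length `C*(C-1)/2`.
#' @export
flatten_upper_triangle <- function(F) {
  if (!is.matrix(F) || nrow(F) != ncol(F)) abort("`F` must be a square matrix")
  t(F)[lower.tri(F)]
}

#' @rdname flatten_upper_triangle
#' @param v flattened vector of length `C*(C-1)/2`.
#' @param C channel count.
#' @export
unflatten_upper_triangle <- function(v, C) {
  if (!is_count(C, 2L)) abort("`C` must be an integer >= 2")
  expected <- C * (C - 1L) / 2L
  if (length(v) != expected)
    abort("vector length %d does not match C = %d (expected %d)",
          length(v), C, expected)
  A <- matrix(0, C, C)
  A[lower.tri(A)] <- v # fills t(F)'s lower triangle = F's row-major upper
  t(A) + A + diag(C)
}

#' Feature sequence: N flattened channel-wise features from one window
#'
#' The full feature pipeline for one window: segment means, one correlation
#' matrix per time step, each flattened to its strict upper triangle. The
#' result is the LSTM input for one example.
#'
#' @param E a [extract_window()] tensor.
#' @return an `N x C(C-1)/2` numeric matrix of class `feature_sequence`
#'   (rows = time steps); attributes carry `C` and the windowing params.
#' @export
feature_sequence <- function(E) {
  stopifnot(inherits(E, "window_tensor"))
  params <- attr(E, "params")
  S <- single_channel_features(E)
  C <- dim(S)[1L]
  out <- matrix(NA_real_, params$N, C * (C - 1L) / 2L)
  for (n in seq_len(params$N))
    out[n, ] <- flatten_upper_triangle(channel_wise_feature(S, n))
  structure(out, class = c("feature_sequence", "matrix"),
            C = C, params = params, source = attr(E, "source"))
}

#' Sliding-window training examples from one trial
#'
#' Data augmentation: windows of `L*K*N` samples are taken at stride `L*K`
#' (one correlation matrix's worth of samples), so adjacent windows overlap
#' by `(N-1)/N` of their length and share exactly `N - 1` of their `N`
#' channel-wise features. Trailing samples that do not fill a window are
#' dropped; windows never span trial boundaries. Every example inherits the
#' trial's label.
#'
#' The number of examples is `floor((M - L*K*N) / (L*K)) + 1`.
#'
#' Implementation note: each distinct `L*K`-sample block's correlation matrix
#' is computed once and windows are rolling slices over those blocks; this is
#' numerically identical to running [feature_sequence()] on every
#' [extract_window()] (asserted in the test suite) but ~N times cheaper.
#'
#' @param rec a [raw_recording()] (already pre-stimulus trimmed).
#' @param params a [windowing_params()].
#' @param label the trial's [emotion_label()].
#' @return list of `labeled_example` objects, each with fields `sequence`
#'   (a [feature_sequence()]), `label`, `subject_id`, `trial_id`,
#'   `start_sample`.
#' @export
make_training_examples <- function(rec, params, label) {
  stopifnot(inherits(rec, "raw_recording"), inherits(params, "windowing_params"),
            inherits(label, "emotion_label"))
  L <- params$L; K <- params$K; N <- params$N
  stride <- L * K
  M <- n_samples(rec)
  if (M < stride * N)
    abort("recording of %d samples is shorter than one window (%d samples)",
          M, stride * N)
  n_blocks <- M %/% stride
  C <- n_channels(rec)
  # per-block flattened correlation features, computed once
  slab <- rec$data[, seq_len(n_blocks * stride), drop = FALSE]
  dimnames(slab) <- NULL
  Eall <- array(slab, dim = c(C, L, K, n_blocks))
  Sall <- colMeans(aperm(Eall, c(2L, 1L, 3L, 4L)), dims = 1L) # C x K x n_blocks
  D <- C * (C - 1L) / 2L
  feats <- matrix(NA_real_, n_blocks, D)
  for (j in seq_len(n_blocks))
    feats[j, ] <- flatten_upper_triangle(.cor_matrix(t(Sall[, , j])))
  n_windows <- n_blocks - N + 1L
  lapply(seq_len(n_windows), function(i) {
    seqmat <- feats[i:(i + N - 1L), , drop = FALSE]
    structure(
      list(sequence = structure(seqmat,
                                class = c("feature_sequence", "matrix"),
                                C = C, params = params,
                                source = list(subject_id = rec$subject_id,
                                              trial_id = rec$trial_id,
                                              start_sample = (i - 1L) * stride)),
           label = label,
           subject_id = rec$subject_id, trial_id = rec$trial_id,
           start_sample = (i - 1L) * stride),
      class = "labeled_example")
  })
}

#' @export
print.labeled_example <- function(x, ...) {
  cat(sprintf("<labeled_example> %s/%s @%d, %s=%s, sequence %d x %d\n",
              x$subject_id, x$trial_id, x$start_sample, x$label$scheme,
              class_name(x$label), nrow(x$sequence), ncol(x$sequence)))
  invisible(x)
}
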