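test_that("extract_window lays segments out time-major and checks bounds", {
  rec <- make_test_recording(C = 3, M = 200, seed = 4)
  p <- windowing_params(2, 8, 10)
  E <- extract_window(rec, 0, p)
  expect_equal(dim(E), c(3L, 2L, 8L, 10L))
  # E[c, l, k, n] == data[c, start + ((n-1)*K + (k-1))*L + l] (1-based)
  for (probe in list(c(1, 1, 1, 1), c(2, 2, 3, 1), c(3, 1, 8, 10), c(1, 2, 5, 7))) {
    c_ <- probe[1]; l <- probe[2]; k <- probe[3]; n <- probe[4]
    expect_identical(E[c_, l, k, n],
                     unname(rec$data[c_, ((n - 1) * 8 + (k - 1)) * 2 + l]))
  }
  # window consumes exactly [start, start + L*K*N)
  E2 <- extract_window(rec, 40, p)
  expect_identical(E2[2, 1, 1, 1], unname(rec$data[2, 41]))
  expect_identical(E2[2, 2, 8, 10], unname(rec$data[2, 200]))
  expect_error(extract_window(rec, 41, p), "exceeds")
  expect_error(extract_window(make_test_recording(M = 160), 1, p), "exceeds")
})

test_that("single_channel_features matches an elementwise sum/L oracle", {
  rec <- make_test_recording(C = 4, M = 160, seed = 9)
  E <- extract_window(rec, 0, windowing_params(4, 5, 8))
  S <- single_channel_features(E)
  expect_equal(dim(S), c(4L, 5L, 8L))
  # brute-force summation oracle over every segment
  for (c_ in 1:4) for (k in 1:5) for (n in 1:8) {
    acc <- 0
    for (l in 1:4) acc <- acc + E[c_, l, k, n]
    expect_equal(as.numeric(S[c_, k, n]), acc / 4, tolerance = 1e-12)
  }
  # constant segment -> the constant
  rec2 <- raw_recording(matrix(7, 2, 32), 128)
  S2 <- single_channel_features(extract_window(rec2, 0, windowing_params(2, 4, 4)))
  expect_true(all(S2 == 7 | is.na(S2) == FALSE))
  expect_equal(unique(as.vector(unclass(S2))), 7)
})

test_that("channel_wise_feature is a clipped sample Pearson matrix", {
  rec <- make_test_recording(C = 5, M = 160, seed = 2)
  S <- single_channel_features(extract_window(rec, 0, windowing_params(2, 8, 10)))
  F <- channel_wise_feature(S, 3)
  expect_equal(dim(F), c(5L, 5L))
  expect_identical(unclass(F), t(unclass(F)))
  expect_true(all(F >= -1 & F <= 1))
  expect_equal(unname(diag(F)), rep(1, 5))
  # against stats::cor as a second route
  expect_equal(unclass(F), unname(cor(t(unclass(S)[, , 3]))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(channel_wise_feature(S, 11), "out of")

  # perfectly correlated / anticorrelated channels
  base <- chanwise:::with_seed(5, rnorm(16))
  data <- rbind(base, 3 * base + 2, -base)
  rec2 <- raw_recording(data, 128)
  S2 <- single_channel_features(extract_window(rec2, 0, windowing_params(2, 8, 1)))
  F2 <- channel_wise_feature(S2, 1)
  expect_equal(F2[1, 2], 1, tolerance = 1e-12)
  expect_equal(F2[1, 3], -1, tolerance = 1e-12)
  expect_equal(F2[2, 3], -1, tolerance = 1e-12)
})

test_that("zero-variance channels get 0 off-diagonals, 1 diagonal, a warning", {
  data <- rbind(chanwise:::with_seed(6, rnorm(16)), rep(5, 16),
                chanwise:::with_seed(7, rnorm(16)))
  S <- single_channel_features(extract_window(raw_recording(data, 128), 0,
                                              windowing_params(2, 8, 1)))
  expect_warning(F <- channel_wise_feature(S, 1), "zero-variance")
  expect_equal(F[2, 1], 0)
  expect_equal(F[2, 3], 0)
  expect_equal(F[2, 2], 1)
  expect_true(abs(F[1, 3]) > 0) # healthy pair untouched
})

test_that("Pearson is invariant to positive affine rescaling; negation flips sign", {
  rec <- make_test_recording(C = 4, M = 64, seed = 11)
  p <- windowing_params(2, 8, 2)
  F0 <- channel_wise_feature(single_channel_features(extract_window(rec, 0, p)), 1)
  scaled <- rec$data * c(2.5, 0.3, 7, 1.1) + c(-1, 4, 0, 2)
  F1 <- channel_wise_feature(single_channel_features(
    extract_window(raw_recording(scaled, 128), 0, p)), 1)
  expect_equal(unclass(F0), unclass(F1), tolerance = 1e-12)
  flipped <- rec$data * c(-1, 1, 1, 1)
  F2 <- channel_wise_feature(single_channel_features(
    extract_window(raw_recording(flipped, 128), 0, p)), 1)
  expect_equal(F2[1, -1], -F0[1, -1], tolerance = 1e-12)
  expect_equal(F2[-1, -1], F0[-1, -1], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("flatten order is row-major strict upper triangle and round-trips", {
  F <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3)
  expect_equal(flatten_upper_triangle(F), c(.1, .2, .3))
  expect_equal(unflatten_upper_triangle(c(.1, .2, .3), 3), F)
  expect_error(unflatten_upper_triangle(c(.1, .2, .3, .4), 3), "does not match")
  expect_error(flatten_upper_triangle(matrix(0, 2, 3)), "square")
  # C=2: single pair
  F2 <- matrix(c(1, .7, .7, 1), 2, 2)
  expect_equal(flatten_upper_triangle(F2), 0.7)
  # random round-trip at several sizes
  for (C in c(2, 5, 9)) {
    v <- chanwise:::with_seed(C, runif(C * (C - 1) / 2, -1, 1))
    expect_identical(flatten_upper_triangle(unflatten_upper_triangle(v, C)), v)
  }
})

test_that("feature_sequence yields N vectors and commutes with channel permutation", {
  rec <- make_test_recording(C = 5, M = 400, seed = 13)
  p <- windowing_params(2, 8, 4)
  fs <- feature_sequence(extract_window(rec, 0, p))
  expect_equal(dim(fs), c(4L, 10L))
  # N = 1 degenerate sequence
  fs1 <- feature_sequence(extract_window(rec, 0, windowing_params(2, 8, 1)))
  expect_equal(nrow(fs1), 1L)

  # permuting channels permutes flattened entries by the induced index map
  perm <- c(3, 1, 5, 2, 4)
  rec_p <- raw_recording(rec$data[perm, ], rec$rate)
  fs_p <- feature_sequence(extract_window(rec_p, 0, p))
  C <- 5
  # index map via unflatten/flatten on both orderings
  for (n in 1:4) {
    Forig <- unflatten_upper_triangle(fs[n, ], C)
    expect_equal(fs_p[n, ], flatten_upper_triangle(Forig[perm, perm]),
                 tolerance = 1e-14)
  }
})

test_that("make_training_examples strides by L*K and matches the direct route", {
  rec <- make_test_recording(C = 4, M = 500, seed = 17)
  p <- windowing_params(2, 8, 10)
  lab <- emotion_label("valence2", 1)
  ex <- make_training_examples(rec, p, lab)
  # explicit enumeration oracle over start samples
  starts <- integer(0)
  s <- 0L
  while (s + window_samples(p) <= n_samples(rec)) {
    starts <- c(starts, s)
    s <- s + p$L * p$K
  }
  expect_equal(length(ex), length(starts))
  expect_equal(vapply(ex, function(e) e$start_sample, integer(1)), starts)
  expect_true(all(vapply(ex, function(e) e$label$value, integer(1)) == 1L))

  # block-sliced features identical to extract_window + feature_sequence
  for (i in c(1, 7, length(ex))) {
    direct <- feature_sequence(extract_window(rec, ex[[i]]$start_sample, p))
    expect_equal(unclass(ex[[i]]$sequence), unclass(direct),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # boundary cases
  rec_exact <- make_test_recording(C = 3, M = window_samples(p))
  expect_length(make_training_examples(rec_exact, p, lab), 1L)
  rec_short <- make_test_recording(C = 3, M = window_samples(p) - 1L)
  expect_error(make_training_examples(rec_short, p, lab), "shorter than one window")
})
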