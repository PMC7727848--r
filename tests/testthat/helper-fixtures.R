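# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

# textbook Pearson correlation: explicit mean/cov/sd loops, independent of
# the implementation under test
pearson_oracle <- function(x, y) {
  K <- length(x)
  mx <- sum(x) / K
  my <- sum(y) / K
  cv <- 0; vx <- 0; vy <- 0
  for (i in seq_len(K)) {
    cv <- cv + (x[i] - mx) * (y[i] - my)
    vx <- vx + (x[i] - mx)^2
    vy <- vy + (y[i] - my)^2
  }
  cv / sqrt(vx * vy)
}

make_test_recording <- function(C = 4, M = 320, rate = 128, seed = 1,
                                subject_id = "sx", trial_id = "tx") {
  raw_recording(chanwise:::with_seed(seed, matrix(rnorm(C * M), C, M)),
                rate = rate, subject_id = subject_id, trial_id = trial_id)
}

# fabricated labeled examples (no signal) for split/stub tests
make_fake_examples <- function(n, n_subjects = 5, scheme = "valence2",
                               values = NULL, seed = 1) {
  nc <- length(chanwise:::.label_schemes[[scheme]])
  chanwise:::with_seed(seed, {
    if (is.null(values)) values <- sample(0:(nc - 1), n, replace = TRUE)
    lapply(seq_len(n), function(i) {
      structure(list(
        sequence = structure(matrix(rnorm(3 * 6), 3, 6),
                             class = c("feature_sequence", "matrix"),
                             C = 4L, params = windowing_params(2, 2, 3)),
        label = emotion_label(scheme, values[i]),
        subject_id = sprintf("s%02d", (i - 1L) %% n_subjects + 1L),
        trial_id = sprintf("t%d", i), start_sample = 0L),
        class = "labeled_example")
    })
  })
}

# small, quickly separable synthetic dataset for model tests
small_synth_examples <- function(seed = 1, trial_seconds = 6) {
  cfg <- synth_config(n_subjects = 2, n_trials_per_emotion = 1,
                      trial_seconds = trial_seconds, seed = seed)
  dataset_examples(generate_dataset(cfg))
}

# nearest-class-centroid engine over time-averaged features: a cheap,
# deterministic stand-in classifier for evaluation-module tests
centroid_engine <- function(D, nc) {
  feat <- function(ex) t(vapply(ex, function(e) colMeans(e$sequence), numeric(D)))
  list(
    fit = function(tr, fold) {
      X <- feat(tr)
      y <- vapply(tr, function(e) e$label$value, integer(1))
      t(vapply(0:(nc - 1L), function(cl) colMeans(X[y == cl, , drop = FALSE]),
               numeric(D)))
    },
    predict = function(centroids, te) {
      X <- feat(te)
      d2 <- outer(rowSums(X^2), rowSums(centroids^2), "+") - 2 * tcrossprod(X, centroids)
      max.col(-d2, ties.method = "first") - 1L
    })
}

# mean silhouette width on a 2-D embedding (Euclidean), hand-rolled
silhouette_mean <- function(X, labels) {
  labels <- as.integer(factor(labels))
  D <- as.matrix(dist(X))
  s <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
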