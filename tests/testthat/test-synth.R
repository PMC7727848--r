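test_that("subject profiles are valid correlation matrices, seeded and distinct", {
  p1 <- make_subject_profile(32, seed = 1)
  p2 <- make_subject_profile(32, seed = 1)
  p3 <- make_subject_profile(32, seed = 2)
  expect_identical(p1$base_correlation, p2$base_correlation)
  expect_gt(norm(p1$base_correlation - p3$base_correlation, "F"), 0.5)
  B <- p1$base_correlation
  expect_equal(unname(diag(B)), rep(1, 32))
  expect_identical(B, t(B))
  expect_true(all(abs(B[row(B) != col(B)]) < 1))
  expect_gt(min(eigen(B, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(make_subject_profile(1, seed = 1), ">= 2")
})

test_that("project_correlation repairs indefinite symmetric matrices", {
  # over-perturbed matrix with a negative eigenvalue
  M <- diag(4)
  M[1, 2] <- M[2, 1] <- 0.95
  M[1, 3] <- M[3, 1] <- 0.95
  M[2, 3] <- M[3, 2] <- -0.95
  expect_lt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  R <- project_correlation(M)
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_true(all(abs(R[row(R) != col(R)]) < 1))
  # already-valid matrices pass through nearly unchanged
  B <- make_subject_profile(6, seed = 3)$base_correlation
  expect_equal(project_correlation(B), B, tolerance = 1e-8)
})

test_that("emotion effects are sparse symmetric zero-diagonal perturbations", {
  eff <- emotion_effects("valence2", C = 8, magnitude = 0.6, sparsity = 0.1,
                         seed = 4)
  expect_length(eff, 2)
  n_pairs <- 8 * 7 / 2
  for (e in eff) {
    expect_identical(e$delta, t(e$delta))
    expect_equal(unname(diag(e$delta)), rep(0, 8))
  }
  gap <- flatten_upper_triangle(eff[[2]]$delta - eff[[1]]$delta)
  expect_equal(sum(abs(gap) > 0), round(0.1 * n_pairs))
  expect_equal(unique(abs(gap[abs(gap) > 0])), 0.6, tolerance = 1e-12)
  # three-class scheme: one effect per class
  eff3 <- emotion_effects("seed3", C = 8, seed = 4)
  expect_length(eff3, 3)
})

test_that("generate_recording is trial-seeded and respects the target structure", {
  cfg <- synth_config(C = 6, trial_seconds = 5, seed = 1)
  prof <- make_subject_profile(6, seed = 7, subject_id = "s1")
  r1 <- generate_recording(prof, NULL, cfg, trial_seed = 11)
  r2 <- generate_recording(prof, NULL, cfg, trial_seed = 11)
  r3 <- generate_recording(prof, NULL, cfg, trial_seed = 12)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))
  expect_equal(dim(r1$data), c(6L, 5L * 128L))

  # non-positive-definite base -> Cholesky precondition error
  badM <- diag(3); badM[1, 2] <- badM[2, 1] <- 1.5
  bad <- structure(list(subject_id = "b", base_correlation = badM,
                        channel_names = c("a", "b", "c")),
                   class = "subject_profile")
  expect_error(generate_recording(bad, NULL, cfg, 1), "not positive-definite")
})

test_that("channel-wise features recover the generator's target correlation", {
  # identity target: empirical off-diagonals stay within sampling noise
  cfg <- synth_config(C = 5, trial_seconds = 10, seed = 2)
  idp <- structure(list(subject_id = "s", base_correlation = diag(5),
                        channel_names = sprintf("c%d", 1:5)),
                   class = "subject_profile")
  rec <- generate_recording(idp, NULL, cfg, trial_seed = 3)
  ex <- make_training_examples(rec, windowing_params(),
                               emotion_label("valence2", 0))
  Fbar <- Reduce(`+`, lapply(ex, function(e)
    unflatten_upper_triangle(colMeans(e$sequence), 5))) / length(ex)
  # sd of one K=8 sample correlation is ~1/sqrt(K-1); the mean runs over
  # n_blocks ~ M/(L*K) effectively independent blocks -> 4-sigma bound
  n_blocks <- n_samples(rec) %/% 16
  expect_lt(max(abs(Fbar - diag(5))), 4 / (sqrt(7) * sqrt(n_blocks)))
  # single-window entries bounded by ~3/sqrt(K)
  expect_lt(max(abs(ex[[1]]$sequence)), 3 / sqrt(8))

  # strong targeted pair: r(ch1, ch2) = 0.9 recovered within +-0.1
  tgt <- diag(3); tgt[1, 2] <- tgt[2, 1] <- 0.9
  prof <- structure(list(subject_id = "s", base_correlation = tgt,
                         channel_names = c("a", "b", "c")),
                    class = "subject_profile")
  cfg2 <- synth_config(C = 3, trial_seconds = 30, seed = 2)
  rec2 <- generate_recording(prof, NULL, cfg2, trial_seed = 5)
  ex2 <- make_training_examples(rec2, windowing_params(),
                                emotion_label("valence2", 0))
  expect_gte(length(ex2), 200)
  r12 <- mean(vapply(ex2, function(e) mean(e$sequence[, 1]), numeric(1)))
  expect_lt(abs(r12 - 0.9), 0.1)
})

test_that("generate_dataset emits seeded, balanced, labeled trials", {
  cfg <- synth_config(n_subjects = 4, n_trials_per_emotion = 2,
                      trial_seconds = 2, scheme = "seed3", seed = 6)
  ds <- generate_dataset(cfg)
  expect_length(ds, 4 * 3 * 2)
  labs <- vapply(ds, function(d) d$label$value, integer(1))
  expect_equal(unname(table(labs)), rep(8L, 3), ignore_attr = TRUE)
  subjects <- vapply(ds, function(d) d$recording$subject_id, character(1))
  expect_length(unique(subjects), 4)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds[[5]]$recording$data, ds2[[5]]$recording$data)
})

test_that("subject identity dominates channel-wise features (nearest profile)", {
  cfg <- synth_config(n_subjects = 4, n_trials_per_emotion = 2,
                      trial_seconds = 4, seed = 8)
  ds <- generate_dataset(cfg)
  profiles <- attr(ds, "profiles")
  hits <- vapply(ds, function(d) {
    ex <- make_training_examples(d$recording, windowing_params(), d$label)
    Fbar <- unflatten_upper_triangle(
      colMeans(do.call(rbind, lapply(ex, function(e) colMeans(e$sequence)))),
      cfg$C)
    dists <- vapply(profiles, function(p)
      norm(Fbar - p$base_correlation, "F"), numeric(1))
    profiles[[which.min(dists)]]$subject_id == d$recording$subject_id
  }, logical(1))
  expect_gt(mean(hits), 0.9) # chance would be 0.25
})
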