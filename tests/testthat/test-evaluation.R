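test_that("random_mixed folds partition examples into near-equal folds", {
  ex <- make_fake_examples(100)
  folds <- suppressWarnings(kfold_split(ex, k = 10, seed = 3))
  expect_equal(sort(unique(folds$fold_of_example)), 1:10)
  expect_equal(unname(table(folds$fold_of_example)), rep(10L, 10),
               ignore_attr = TRUE)
  # seeded reproducibility
  folds2 <- suppressWarnings(kfold_split(ex, k = 10, seed = 3))
  expect_identical(folds$fold_of_example, folds2$fold_of_example)
  folds3 <- suppressWarnings(kfold_split(ex, k = 10, seed = 4))
  expect_false(identical(folds$fold_of_example, folds3$fold_of_example))
  expect_error(suppressWarnings(kfold_split(ex[1:5], k = 10)), "fewer examples")
  expect_warning(kfold_split(ex, k = 10, seed = 1), "random_mixed")
})

test_that("subject_wise folds keep each subject in exactly one fold", {
  ex <- make_fake_examples(90, n_subjects = 15)
  folds <- kfold_split(ex, k = 5, mode = "subject_wise", seed = 2)
  subj <- vapply(ex, function(e) e$subject_id, character(1))
  per_subject_folds <- tapply(folds$fold_of_example, subj,
                              function(f) length(unique(f)))
  expect_true(all(per_subject_folds == 1))
  # 15 subjects into 5 folds -> 3 subjects per fold
  subj_fold <- tapply(folds$fold_of_example, subj, unique)
  expect_equal(unname(table(subj_fold)), rep(3L, 5), ignore_attr = TRUE)
  expect_error(kfold_split(make_fake_examples(40, n_subjects = 3), k = 5,
                           mode = "subject_wise"), "at least 5 subjects")
})

test_that("cross_validate aggregates stub classifiers exactly", {
  ex <- make_fake_examples(100, values = rep(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L), 10))
  folds <- suppressWarnings(kfold_split(ex, k = 10, seed = 1))
  # perfect-classifier stub
  oracle <- list(fit = function(tr, fold) NULL,
                 predict = function(state, te)
                   vapply(te, function(e) e$label$value, integer(1)))
  cv <- cross_validate(ex, folds = folds, engine = oracle)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$per_fold_accuracy, rep(1, 10))
  expect_true(all(cv$confusion[row(cv$confusion) != col(cv$confusion)] == 0))

  # majority-class stub on a 70/30 set
  majority <- list(fit = function(tr, fold) NULL,
                   predict = function(state, te) rep(0L, length(te)))
  cv2 <- cross_validate(ex, folds = folds, engine = majority)
  expect_equal(cv2$mean_accuracy, 0.7, tolerance = 1e-12)

  # confusion totals reconcile with example counts
  expect_equal(sum(cv2$confusion), 100)
  truth <- vapply(ex, function(e) e$label$value, integer(1))
  expect_equal(unname(rowSums(cv2$confusion)), unname(as.vector(table(truth))))
  expect_equal(cv$mean_accuracy, mean(cv$per_fold_accuracy))
})

test_that("cross_validate with the LSTM engine learns a separable dataset", {
  ex <- small_synth_examples(seed = 9)
  cf <- model_config(ncol(ex[[1]]$sequence), hidden_dim = 16, num_classes = 2)
  tc <- train_config(max_epochs = 20, seed = 4, batch_size = 64)
  folds <- suppressWarnings(kfold_split(ex, k = 3, seed = 4))
  cv <- suppressWarnings(cross_validate(ex, cf, tc, folds))
  expect_gt(cv$mean_accuracy, 0.9)
  expect_equal(sum(cv$confusion), length(ex))
})

test_that("sweep_hyperparameters builds one row per setting and skips oversize windows", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_emotion = 1,
                      trial_seconds = 3, seed = 21)
  ds <- generate_dataset(cfg)
  tab <- sweep_hyperparameters(ds, N_values = c(3, 5, 10), k = 3, seed = 2,
                               engine_fn = centroid_engine)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$N, c(3, 5, 10))
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))

  # 3 s at 128 Hz = 384 samples; L = 30 makes the window 30*8*10 = 2400 > M
  tab2 <- sweep_hyperparameters(ds, L_values = c(2, 30), k = 3, seed = 2,
                                engine_fn = centroid_engine)
  expect_equal(tab2$status, c("ok", "skipped"))
  expect_true(is.na(tab2$mean_accuracy[2]))
  expect_error(sweep_hyperparameters(ds), "no values")
})

test_that("accuracy grows with the number of time steps on slow-dynamics data", {
  cfg <- synth_config(n_subjects = 3, n_trials_per_emotion = 1,
                      trial_seconds = 6, seed = 31)
  ds <- generate_dataset(cfg)
  tab <- sweep_hyperparameters(ds, N_values = c(2, 10), k = 3, seed = 5,
                               engine_fn = centroid_engine)
  expect_gte(tab$mean_accuracy[tab$N == 10], tab$mean_accuracy[tab$N == 2])
})

test_that("subject-mixed splitting inflates accuracy relative to subject-wise", {
  # strong subject structure, weak emotion effect: windows of the same trial
  # land on both sides of a mixed split and leak
  cfg <- synth_config(n_subjects = 4, n_trials_per_emotion = 1,
                      trial_seconds = 5, magnitude = 0.3, seed = 41)
  ds <- generate_dataset(cfg)
  ex <- dataset_examples(ds)
  D <- ncol(ex[[1]]$sequence)
  mixed <- suppressWarnings(kfold_split(ex, k = 4, mode = "random_mixed", seed = 6))
  sw <- kfold_split(ex, k = 4, mode = "subject_wise", seed = 6)
  acc_mixed <- cross_validate(ex, folds = mixed, engine = centroid_engine(D, 2))$mean_accuracy
  acc_sw <- cross_validate(ex, folds = sw, engine = centroid_engine(D, 2))$mean_accuracy
  expect_gt(acc_mixed, acc_sw)
})
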