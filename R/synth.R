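#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping at a small floor followed by diagonal renormalization
#' (`cov2cor`). Used to repair base-plus-perturbation sums that drift out of
#' the positive-definite cone.
#'
#' @param M symmetric matrix with approximately unit diagonal.
#' @param eig_floor smallest admissible eigenvalue (default 1e-3).
#' @return symmetric positive-definite correlation matrix with unit
#'   diagonal and off-diagonals in `(-1, 1)`.
#' @export
project_correlation <- function(M, eig_floor = 1e-3) {
  A <- (M + t(M)) / 2
  e <- eigen(A, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  R <- e$vectors %*% (vals * t(e$vectors))
  R <- stats::cov2cor(R)
  R <- (R + t(R)) / 2
  off <- row(R) != col(R)
  R[off] <- pmin(pmax(R[off], -0.999), 0.999)
  diag(R) <- 1
  R
}

#' Draw a subject-specific base connectivity pattern
#'
#' A random factor model (`W W' + diag(u)`, normalized to unit diagonal)
#' gives a valid correlation matrix with substantial, structured
#' off-diagonals — emulating the observation that each individual's
#' channel-wise features carry a stable personal pattern across stimuli.
#' Deterministic under `seed`.
#'
#' @param C channel count (`>= 2`).
#' @param seed integer seed.
#' @param n_factors number of latent factors (default `max(2, C/4)`).
#' @param channel_names optional montage labels.
#' @param subject_id identifier stored on the profile.
#' @return an object of class `subject_profile` with fields `subject_id`,
#'   `base_correlation` (C x C SPD, unit diagonal) and `channel_names`.
#' @export
make_subject_profile <- function(C, seed, n_factors = max(2L, ceiling(C / 4)),
                                 channel_names = NULL,
                                 subject_id = NA_character_) {
  if (!is_count(C, 2L)) abort("`C` must be an integer >= 2")
  B <- with_seed(seed, {
    W <- matrix(stats::rnorm(C * n_factors), C, n_factors)
    u <- stats::runif(C, 0.3, 1)
    stats::cov2cor(tcrossprod(W) + diag(u))
  })
  B <- (B + t(B)) / 2 # cov2cor is symmetric only up to rounding
  diag(B) <- 1
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(C))
  structure(list(subject_id = as.character(subject_id), base_correlation = B,
                 channel_names = channel_names),
            class = "subject_profile")
}

#' Emotion-specific connectivity perturbations
#'
#' Each emotion class perturbs a sparse random subset of channel pairs
#' (default 10% of the `C(C-1)/2` pairs) of the subject's base correlation.
#' For two-class schemes the classes share one support and sit at
#' `-magnitude/2` and `+magnitude/2` times a random sign pattern, so the
#' between-class correlation gap on a perturbed pair is exactly `magnitude`
#' (before projection). Schemes with more classes get an independent
#' support per class at amplitude `magnitude/2`.
#'
#' @param scheme label scheme (see [emotion_label()]).
#' @param C channel count.
#' @param magnitude between-class correlation gap scale (default 0.6).
#' @param sparsity fraction of channel pairs perturbed (default 0.1).
#' @param seed integer seed.
#' @return list of `emotion_effect` objects (one per class), each with
#'   `label`, `delta` (C x C symmetric, zero diagonal) and `magnitude`.
#' @export
emotion_effects <- function(scheme, C, magnitude = 0.6, sparsity = 0.1,
                            seed = 1L) {
  scheme <- match.arg(scheme, names(.label_schemes))
  nc <- length(.label_schemes[[scheme]])
  n_pairs <- C * (C - 1L) / 2L
  n_sel <- max(1L, round(sparsity * n_pairs))
  with_seed(seed, {
    make_delta <- function(support, amp) {
      v <- numeric(n_pairs)
      v[support] <- amp * sample(c(-1, 1), length(support), replace = TRUE)
      unflatten_upper_triangle(v, C) - diag(C)
    }
    if (nc == 2L) {
      support <- sample.int(n_pairs, n_sel)
      signs <- sample(c(-1, 1), n_sel, replace = TRUE)
      v <- numeric(n_pairs); v[support] <- signs
      base_dir <- unflatten_upper_triangle(v, C) - diag(C)
      deltas <- list(-magnitude / 2 * base_dir, magnitude / 2 * base_dir)
    } else {
      deltas <- lapply(seq_len(nc), function(cl)
        make_delta(sample.int(n_pairs, n_sel), magnitude / 2))
    }
    lapply(seq_len(nc), function(cl)
      structure(list(label = emotion_label(scheme, cl - 1L),
                     delta = deltas[[cl]], magnitude = magnitude),
                class = "emotion_effect"))
  })
}

#' Synthetic-dataset configuration
#'
#' Defaults describe a desk-scale stand-in for an affective-EEG experiment:
#' 4 subjects, two emotion classes, 2 trials per subject and class, 17 s
#' trials at 128 Hz over 8 channels (about 2,000 sliding windows at the
#' default windowing), AR(1) temporal smoothing 0.5, sensor noise sd 0.2
#' and a between-class correlation gap of 0.6 on 10% of channel pairs.
#'
#' @param n_subjects,n_trials_per_emotion counts (`>= 1`).
#' @param trial_seconds trial duration in seconds.
#' @param rate sampling rate in Hz.
#' @param C channel count.
#' @param scheme label scheme (number of emotions).
#' @param magnitude,sparsity emotion-effect size (see [emotion_effects()]).
#' @param noise_sd sd of additive white sensor noise (signal sd is ~1.15).
#' @param ar_coef AR(1) coefficient of the temporal smoothing, in `[0, 1)`.
#' @param seed master seed; subject profiles, effects and trials derive
#'   their own sub-seeds from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 4L, n_trials_per_emotion = 2L,
                         trial_seconds = 17, rate = 128, C = 8L,
                         scheme = "valence2", magnitude = 0.6, sparsity = 0.1,
                         noise_sd = 0.2, ar_coef = 0.5, seed = 1L) {
  if (!is_count(n_subjects, 1L)) abort("`n_subjects` must be >= 1")
  if (!is_count(n_trials_per_emotion, 1L)) abort("`n_trials_per_emotion` must be >= 1")
  if (!is_scalar_num(trial_seconds) || trial_seconds <= 0) abort("`trial_seconds` must be > 0")
  if (!is_scalar_num(rate) || rate <= 0) abort("`rate` must be > 0")
  if (!is_count(C, 2L)) abort("`C` must be >= 2")
  scheme <- match.arg(scheme, names(.label_schemes))
  if (!is_scalar_num(ar_coef) || ar_coef < 0 || ar_coef >= 1)
    abort("`ar_coef` must be in [0, 1)")
  if (!is_scalar_num(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_emotion = as.integer(n_trials_per_emotion),
                 trial_seconds = trial_seconds, rate = rate, C = as.integer(C),
                 scheme = scheme, magnitude = magnitude, sparsity = sparsity,
                 noise_sd = noise_sd, ar_coef = ar_coef,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate one synthetic trial
#'
#' The target correlation matrix is the subject's base pattern plus the
#' emotion's perturbation, projected back to a valid correlation matrix.
#' Independent AR(1)-smoothed unit-variance noise per latent channel is
#' mixed through the Cholesky factor of the target, so raw samples — and
#' hence segment-mean vectors — inherit the target inter-channel
#' correlation; white sensor noise is added on top. Deterministic under
#' `trial_seed`.
#'
#' @param profile a [make_subject_profile()].
#' @param effect one element of [emotion_effects()], or `NULL` for the bare
#'   base pattern.
#' @param cfg a [synth_config()].
#' @param trial_seed integer seed for this trial.
#' @param trial_id identifier stored on the recording.
#' @return a [raw_recording()] with attribute `target_correlation`.
#' @export
generate_recording <- function(profile, effect, cfg, trial_seed,
                               trial_id = NA_character_) {
  stopifnot(inherits(profile, "subject_profile"), inherits(cfg, "synth_config"))
  target <- if (is.null(effect)) profile$base_correlation
            else project_correlation(profile$base_correlation + effect$delta)
  Lchol <- tryCatch(chol(target), error = function(e)
    abort("combined correlation matrix is not positive-definite"))
  C <- ncol(target)
  M <- round(cfg$trial_seconds * cfg$rate)
  burn <- 200L
  data <- with_seed(trial_seed, {
    E <- matrix(stats::rnorm((M + burn) * C), M + burn, C)
    if (cfg$ar_coef > 0) {
      X <- stats::filter(E, cfg$ar_coef, method = "recursive")
      X <- as.matrix(X) * sqrt(1 - cfg$ar_coef^2) # back to unit variance
    } else X <- E
    X <- X[(burn + 1L):(burn + M), , drop = FALSE]
    Y <- X %*% Lchol # rows now have cov = target
    if (cfg$noise_sd > 0) Y <- Y + cfg$noise_sd * stats::rnorm(length(Y))
    t(Y)
  })
  rec <- raw_recording(data, cfg$rate, profile$channel_names,
                       profile$subject_id, trial_id)
  attr(rec, "target_correlation") <- target
  rec
}

#' Generate a labeled synthetic dataset
#'
#' For each subject a base connectivity profile is drawn; for each emotion
#' class and trial, a recording with the class's perturbed correlation
#' structure. All randomness derives from `cfg$seed`. Class counts are
#' balanced by construction.
#'
#' @param cfg a [synth_config()].
#' @return a list of `list(recording, label)` pairs with attributes
#'   `profiles`, `effects` and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  profiles <- lapply(seq_len(cfg$n_subjects), function(s)
    make_subject_profile(cfg$C, seed = derive_seed(cfg$seed, 101L, s),
                         subject_id = sprintf("s%02d", s)))
  effects <- emotion_effects(cfg$scheme, cfg$C, cfg$magnitude, cfg$sparsity,
                             seed = derive_seed(cfg$seed, 202L))
  out <- list()
  for (s in seq_len(cfg$n_subjects)) {
    for (e in seq_along(effects)) {
      for (tr in seq_len(cfg$n_trials_per_emotion)) {
        rec <- generate_recording(
          profiles[[s]], effects[[e]], cfg,
          trial_seed = derive_seed(cfg$seed, 303L, s, e, tr),
          trial_id = sprintf("t%02d_e%d", tr, e - 1L))
        out[[length(out) + 1L]] <- list(recording = rec,
                                        label = effects[[e]]$label)
      }
    }
  }
  structure(out, profiles = profiles, effects = effects, config = cfg)
}

#' Windowed labeled examples from a synthetic (or loaded) dataset
#'
#' Convenience wrapper: applies [make_training_examples()] to every trial
#' and concatenates.
#'
#' @param dataset list of `list(recording, label)`.
#' @param params a [windowing_params()].
#' @return list of `labeled_example`.
#' @export
dataset_examples <- function(dataset, params = windowing_params()) {
  unlist(lapply(dataset, function(d)
    make_training_examples(d$recording, params, d$label)), recursive = FALSE)
}
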