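#' Assign examples to cross-validation folds
#'
#' Two modes. `random_mixed` shuffles examples under the seed and deals them
#' round-robin, so the same subject (and windows of the same stimulus) can
#' land in both training and test folds — this reproduces the published
#' evaluation protocol, but leaks subject identity. `subject_wise` deals
#' whole subjects to folds, the methodologically sound alternative for
#' claiming cross-subject generalization. `random_mixed` therefore emits a
#' one-time warning.
#'
#' @param examples list of `labeled_example`.
#' @param k number of folds (default 10).
#' @param mode `"random_mixed"` or `"subject_wise"`.
#' @param seed integer seed.
#' @return an object of class `fold_assignment`: `fold_of_example` (1-based
#'   fold ids), `k`, `mode`, `seed`.
#' @export
kfold_split <- function(examples, k = 10L,
                        mode = c("random_mixed", "subject_wise"), seed = 1L) {
  mode <- match.arg(mode)
  if (!is_count(k, 2L)) abort("`k` must be an integer >= 2")
  n <- length(examples)
  if (n < k) abort("fewer examples (%d) than folds (%d)", n, k)
  fold <- integer(n)
  if (mode == "random_mixed") {
    warning("random_mixed split: the same subject/stimulus can appear in both training and test folds; use subject_wise for honest cross-subject estimates",
            call. = FALSE)
    perm <- with_seed(seed, sample.int(n))
    fold[perm] <- rep_len(seq_len(k), n)
  } else {
    subj <- vapply(examples, function(e) e$subject_id, character(1))
    us <- unique(subj)
    if (length(us) < k)
      abort("subject_wise split needs at least %d subjects, got %d", k, length(us))
    us <- with_seed(seed, sample(us))
    fold_of_subj <- stats::setNames(rep_len(seq_len(k), length(us)), us)
    fold <- unname(fold_of_subj[subj])
  }
  structure(list(fold_of_example = fold, k = as.integer(k), mode = mode,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

.default_train_config <- function() train_config()

# default engine: the package's LSTM. An engine is a list(fit, predict):
# fit(train_examples, fold) -> state; predict(state, test_examples) ->
# 0-based class indices. Injectable so tests can use oracle stubs and
# sweeps can use cheap classifiers.
.lstm_engine <- function(model_config, train_config) {
  list(
    fit = function(train_examples, fold) {
      cfg <- train_config
      cfg$seed <- derive_seed(train_config$seed, fold)
      train_model(build_model(model_config), train_examples, cfg)
    },
    predict = function(state, test_examples) {
      predict(state, test_examples, type = "class")
    })
}

#' k-fold cross-validation
#'
#' Trains a fresh model per fold on the out-of-fold examples and evaluates
#' on the fold. Accuracy is micro-accuracy per fold, macro-averaged over
#' folds; the confusion matrix (rows = true class, columns = predicted) is
#' pooled over folds, so its total equals the number of examples.
#'
#' @param examples list of `labeled_example`.
#' @param model_config a [model_config()] (ignored when `engine` is given).
#' @param train_config a [train_config()]; each fold trains under a seed
#'   derived from `train_config$seed` and the fold id.
#' @param folds a [kfold_split()] assignment over `examples`.
#' @param engine optional `list(fit, predict)` overriding the LSTM (e.g. a
#'   stub classifier); see source for the contract.
#' @return an object of class `cv_result` with `per_fold_accuracy`,
#'   `mean_accuracy`, `confusion`, `folds`.
#' @export
cross_validate <- function(examples, model_config = NULL, train_config = NULL,
                           folds, engine = NULL) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (length(folds$fold_of_example) != length(examples))
    abort("fold assignment covers %d examples, got %d",
          length(folds$fold_of_example), length(examples))
  if (is.null(engine)) {
    stopifnot(inherits(model_config, "model_config"),
              inherits(train_config, "train_config"))
    engine <- .lstm_engine(model_config, train_config)
  }
  cls <- examples[[1L]]$label$class_names
  nc <- length(cls)
  confusion <- matrix(0L, nc, nc, dimnames = list(true = cls, predicted = cls))
  acc <- numeric(folds$k)
  for (f in seq_len(folds$k)) {
    te <- which(folds$fold_of_example == f)
    tr <- which(folds$fold_of_example != f)
    state <- engine$fit(examples[tr], f)
    pred <- engine$predict(state, examples[te])
    truth <- vapply(examples[te], function(e) e$label$value, integer(1))
    acc[f] <- mean(pred == truth)
    for (j in seq_along(te))
      confusion[truth[j] + 1L, pred[j] + 1L] <- confusion[truth[j] + 1L, pred[j] + 1L] + 1L
  }
  structure(list(per_fold_accuracy = acc, mean_accuracy = mean(acc),
                 confusion = confusion, folds = folds,
                 model_config = model_config, train_config = train_config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold (%s): mean accuracy %.4f\n",
              x$folds$k, x$folds$mode, x$mean_accuracy))
  cat("  per fold:", paste(sprintf("%.3f", x$per_fold_accuracy), collapse = " "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Sweep one windowing hyperparameter at a time
#'
#' Re-extracts features and re-runs cross-validation for each value of `L`,
#' `K` or `N`, holding the other two at `fixed` — the protocol behind the
#' choice of `L = 2, K = 8, N = 10`. Settings whose window exceeds the
#' shortest trial are reported as `skipped`, not errors.
#'
#' @param dataset list of `list(recording, label)` pairs (e.g. from
#'   [generate_dataset()]), already pre-stimulus trimmed.
#' @param L_values,K_values,N_values numeric vectors of values to try
#'   (`NULL` = do not vary).
#' @param fixed a [windowing_params()] supplying the non-varied values.
#' @param k,mode,seed cross-validation settings (see [kfold_split()]).
#' @param model_config_fn function `(input_dim, num_classes) ->`
#'   [model_config()]; default builds one with `hidden_dim = 32` for speed.
#' @param train_config a [train_config()]; defaults to `train_config()`.
#' @param engine_fn optional function `(input_dim, num_classes) -> engine`
#'   (see [cross_validate()]) replacing the LSTM, e.g. for cheap sweeps.
#' @return a data.frame with columns `param`, `L`, `K`, `N`,
#'   `mean_accuracy`, `n_examples`, `status`.
#' @export
sweep_hyperparameters <- function(dataset, L_values = NULL, K_values = NULL,
                                  N_values = NULL, fixed = windowing_params(),
                                  k = 5L, mode = "random_mixed", seed = 1L,
                                  model_config_fn = NULL,
                                  train_config = NULL,
                                  engine_fn = NULL) {
  if (is.null(train_config)) train_config <- .default_train_config()
  stopifnot(inherits(fixed, "windowing_params"))
  if (is.null(L_values) && is.null(K_values) && is.null(N_values))
    abort("no values to sweep")
  settings <- list()
  add <- function(param, values) {
    for (v in values) {
      p <- fixed
      p[[param]] <- as.integer(v)
      settings[[length(settings) + 1L]] <<- list(param = param, p = do.call(
        windowing_params, unclass(p)[c("L", "K", "N")]))
    }
  }
  add("L", L_values); add("K", K_values); add("N", N_values)
  min_M <- min(vapply(dataset, function(d) n_samples(d$recording), integer(1)))
  rows <- lapply(settings, function(s) {
    p <- s$p
    base <- data.frame(param = s$param, L = p$L, K = p$K, N = p$N,
                       mean_accuracy = NA_real_, n_examples = 0L,
                       status = "ok", stringsAsFactors = FALSE)
    if (window_samples(p) > min_M) {
      base$status <- "skipped"
      return(base)
    }
    examples <- unlist(lapply(dataset, function(d)
      make_training_examples(d$recording, p, d$label)), recursive = FALSE)
    folds <- suppressWarnings(kfold_split(examples, k = k, mode = mode, seed = seed))
    D <- ncol(examples[[1L]]$sequence)
    nc <- n_classes(examples[[1L]]$label)
    engine <- if (!is.null(engine_fn)) engine_fn(D, nc) else NULL
    mc <- if (is.null(engine)) {
      if (!is.null(model_config_fn)) model_config_fn(D, nc)
      else model_config(D, hidden_dim = 32L, num_classes = nc)
    } else NULL
    cv <- suppressWarnings(cross_validate(examples, mc, train_config, folds,
                                          engine = engine))
    base$mean_accuracy <- cv$mean_accuracy
    base$n_examples <- length(examples)
    base
  })
  do.call(rbind, rows)
}
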