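#' Model architecture configuration
#'
#' The classifier is a two-layer stacked LSTM over the sequence of flattened
#' channel-wise features, followed by dropout and a single fully connected
#' softmax layer applied to the last time step of the second LSTM layer.
#' Because channel-wise features already live in `[-1, 1]`, there is no
#' input normalization and no batch-normalization layer anywhere.
#'
#' @param input_dim feature dimension per time step, `C*(C-1)/2`
#'   (496 for 32 channels, 1891 for 62).
#' @param hidden_dim LSTM hidden-state size (default 256).
#' @param num_classes number of emotion classes (2, 3 or 4).
#' @param dropout_p dropout probability on the fully connected layer's input
#'   (default 0.5); dropout is disabled at inference.
#' @param num_lstm_layers fixed at 2 (stacked).
#' @return an object of class `model_config`.
#' @export
model_config <- function(input_dim, hidden_dim = 256L, num_classes,
                         dropout_p = 0.5, num_lstm_layers = 2L) {
  if (!is_count(input_dim, 1L)) abort("`input_dim` must be a positive integer")
  if (!is_count(hidden_dim, 1L)) abort("`hidden_dim` must be a positive integer")
  if (!is_count(num_classes, 2L)) abort("`num_classes` must be an integer >= 2")
  if (!is_scalar_num(dropout_p) || dropout_p < 0 || dropout_p >= 1)
    abort("`dropout_p` must be in [0, 1)")
  if (!identical(as.integer(num_lstm_layers), 2L))
    abort("the architecture is a two-layer stacked LSTM; `num_lstm_layers` must be 2")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 num_classes = as.integer(num_classes),
                 dropout_p = dropout_p, num_lstm_layers = 2L),
            class = "model_config")
}

#' Training configuration
#'
#' Cross-entropy loss minimized by RMSProp at the stated learning rate, with
#' seeded mini-batch shuffling. The RMSProp smoothing constant `rho` and
#' `epsilon` are the usual framework defaults (0.9 and 1e-7) and are recorded
#' in the returned object for reproducibility. When `validation_fraction > 0`
#' a seeded tail split of the training examples is held out, the epoch with
#' the best validation loss is checkpointed, and (optionally) training stops
#' early after `early_stop_patience` epochs without improvement; otherwise
#' the fixed epoch budget runs to completion and final weights are returned.
#'
#' @param learning_rate RMSProp learning rate (default 0.001).
#' @param batch_size mini-batch size (default 240).
#' @param max_epochs epoch budget (default 30).
#' @param optimizer only `"rmsprop"`.
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @param early_stop_patience optional integer; requires
#'   `validation_fraction > 0`.
#' @param validation_fraction fraction of examples held out for
#'   checkpointing (default 0 = use every example, fixed budget).
#' @param rho,epsilon RMSProp smoothing constant and stabilizer.
#' @param verbose print a line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 240L,
                         max_epochs = 30L, optimizer = "rmsprop",
                         seed = 1L, early_stop_patience = NULL,
                         validation_fraction = 0, rho = 0.9, epsilon = 1e-7,
                         verbose = FALSE) {
  optimizer <- match.arg(optimizer, "rmsprop")
  if (!is_scalar_num(learning_rate) || learning_rate <= 0)
    abort("`learning_rate` must be > 0")
  if (!is_count(batch_size, 1L)) abort("`batch_size` must be a positive integer")
  if (!is_count(max_epochs, 1L)) abort("`max_epochs` must be a positive integer")
  if (!is_scalar_num(validation_fraction) || validation_fraction < 0 ||
      validation_fraction >= 1)
    abort("`validation_fraction` must be in [0, 1)")
  if (!is.null(early_stop_patience)) {
    if (!is_count(early_stop_patience, 1L)) abort("`early_stop_patience` must be >= 1")
    if (validation_fraction <= 0)
      abort("`early_stop_patience` requires `validation_fraction` > 0")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), optimizer = optimizer,
                 seed = as.integer(seed),
                 early_stop_patience = early_stop_patience,
                 validation_fraction = validation_fraction,
                 rho = rho, epsilon = epsilon, verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build an (untrained) emotion model
#'
#' Architecture: `LSTM(input_dim -> hidden)` -> `LSTM(hidden -> hidden)` ->
#' last time step -> dropout -> fully connected `(hidden -> num_classes)` ->
#' softmax. Parameters are initialized uniform in `(-1/sqrt(H), 1/sqrt(H))`
#' under `init_seed`; [train_model()] re-initializes from its own seed so a
#' training run is self-contained and reproducible.
#'
#' @param config a [model_config()].
#' @param init_seed seed for the initial random parameters.
#' @return an object of class `emotion_model`.
#' @export
build_model <- function(config, init_seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  params <- with_seed(init_seed,
    .lstm_init_params(config$input_dim, config$hidden_dim, config$num_classes))
  structure(list(config = config, params = params, trained = FALSE,
                 training_log = NULL, seed = NA_integer_),
            class = "emotion_model")
}

#' @export
print.emotion_model <- function(x, ...) {
  cf <- x$config
  cat(sprintf("<emotion_model> LSTM(%d->%d) -> LSTM(%d->%d) -> dropout(%.2f) -> FC(%d->%d) -> softmax\n",
              cf$input_dim, cf$hidden_dim, cf$hidden_dim, cf$hidden_dim,
              cf$dropout_p, cf$hidden_dim, cf$num_classes))
  cat(if (x$trained) sprintf("  trained (seed %d, %d epochs logged)\n",
                             x$seed, nrow(x$training_log))
      else "  untrained\n")
  invisible(x)
}

# validate a list of labeled examples against a model config; returns the
# 1-based class index vector
.check_examples <- function(examples, config) {
  if (length(examples) == 0L) abort("empty example list")
  schemes <- vapply(examples, function(e) e$label$scheme, character(1))
  if (length(unique(schemes)) != 1L)
    abort("examples mix label schemes: %s", paste(unique(schemes), collapse = ", "))
  nc <- n_classes(examples[[1L]]$label)
  if (nc != config$num_classes)
    abort("label scheme has %d classes but model expects %d", nc, config$num_classes)
  dims <- vapply(examples, function(e) ncol(e$sequence), integer(1))
  if (any(dims != config$input_dim))
    abort("feature dimension %d does not match model input_dim %d",
          dims[which(dims != config$input_dim)[1L]], config$input_dim)
  vapply(examples, function(e) e$label$value, integer(1)) + 1L
}

#' Train the emotion model
#'
#' Minimizes mean cross-entropy with RMSProp over seeded shuffled
#' mini-batches. The whole run — weight initialization, batch order and
#' dropout masks — is driven by `cfg$seed`, so two runs with the same seed
#' produce bitwise-identical models on the same machine.
#'
#' @param model an [build_model()] object (its parameters are re-initialized
#'   from `cfg$seed`).
#' @param examples list of `labeled_example` (see
#'   [make_training_examples()]); all must share the feature dimension and
#'   label scheme of `model$config`.
#' @param cfg a [train_config()].
#' @return the trained `emotion_model`, with `training_log` (a data.frame of
#'   per-epoch loss/accuracy, plus validation columns when used) and `seed`.
#' @export
train_model <- function(model, examples, cfg) {
  stopifnot(inherits(model, "emotion_model"), inherits(cfg, "train_config"))
  config <- model$config
  y_all <- .check_examples(examples, config)
  seqs <- lapply(examples, function(e) unclass(e$sequence))

  with_seed(cfg$seed, {
    params <- .lstm_init_params(config$input_dim, config$hidden_dim,
                                config$num_classes)
    n <- length(seqs)
    # optional seeded validation split for checkpointing / early stopping
    if (cfg$validation_fraction > 0) {
      n_val <- max(1L, floor(n * cfg$validation_fraction))
      val_idx <- sample.int(n, n_val)
      tr_idx <- setdiff(seq_len(n), val_idx)
      if (length(tr_idx) == 0L) abort("validation split leaves no training examples")
      xs_val <- .stack_sequences(seqs[val_idx]); y_val <- y_all[val_idx]
    } else {
      tr_idx <- seq_len(n)
      xs_val <- NULL; y_val <- NULL
    }
    xs_tr <- .stack_sequences(seqs[tr_idx]); y_tr <- y_all[tr_idx]
    n_tr <- length(tr_idx)

    state <- .rmsprop_init_state(params)
    log_rows <- vector("list", cfg$max_epochs)
    best <- list(loss = Inf, params = params, epoch = 0L)
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = cfg$batch_size)
      ep_loss <- 0; ep_correct <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n_tr)]
        xb <- .subset_steps(xs_tr, idx); yb <- y_tr[idx]
        fw <- .lstm_forward(params, xb, dropout_p = config$dropout_p, train = TRUE)
        loss <- .ce_loss(fw, yb)
        gr <- .lstm_backward(params, fw, yb)
        upd <- .rmsprop_step(params, gr, state, cfg$learning_rate, cfg$rho, cfg$epsilon)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
        ep_correct <- ep_correct + sum(max.col(fw$probs) == yb)
      }
      row <- data.frame(epoch = epoch, loss = ep_loss / n_tr,
                        accuracy = ep_correct / n_tr)
      if (!is.null(xs_val)) {
        fv <- .lstm_forward(params, xs_val, train = FALSE)
        row$val_loss <- .ce_loss(fv, y_val)
        row$val_accuracy <- mean(max.col(fv$probs) == y_val)
        if (row$val_loss < best$loss) {
          best <- list(loss = row$val_loss, params = params, epoch = epoch)
          stall <- 0L
        } else stall <- stall + 1L
      }
      log_rows[[epoch]] <- row
      if (cfg$verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", epoch, row$loss,
                        row$accuracy,
                        if (!is.null(xs_val))
                          sprintf("  val_loss %.4f  val_acc %.3f", row$val_loss,
                                  row$val_accuracy) else ""))
      if (!is.null(cfg$early_stop_patience) && stall >= cfg$early_stop_patience) break
    }
    model$params <- if (!is.null(xs_val)) best$params else params
    model$trained <- TRUE
    model$seed <- cfg$seed
    model$train_config <- cfg
    model$training_log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
    model
  })
}

# coerce predict/extract input to a list of plain N x D matrices
.as_sequence_list <- function(newdata, config) {
  if (inherits(newdata, "feature_sequence") ||
      (is.matrix(newdata) && !is.list(newdata))) newdata <- list(newdata)
  if (inherits(newdata, "labeled_example")) newdata <- list(newdata)
  seqs <- lapply(newdata, function(s) {
    if (inherits(s, "labeled_example")) s <- s$sequence
    m <- unclass(s)
    if (!is.matrix(m)) abort("each sequence must be an N x input_dim matrix")
    if (ncol(m) != config$input_dim)
      abort("sequence has %d features per step, model expects %d",
            ncol(m), config$input_dim)
    m
  })
  Ns <- vapply(seqs, nrow, integer(1))
  if (length(unique(Ns)) != 1L) abort("sequences have differing numbers of time steps")
  seqs
}

#' Predict class probabilities
#'
#' Runs the trained network with dropout disabled; output is a valid
#' probability distribution per sequence (softmax). Deterministic: repeated
#' calls on the same input return identical values.
#'
#' @param object a trained [emotion_model].
#' @param newdata one [feature_sequence()] / `labeled_example`, or a list of
#'   them (all with the same number of time steps).
#' @param type `"prob"` for class probabilities, `"class"` for 0-based
#'   predicted class indices.
#' @param ... unused.
#' @return a matrix (rows = sequences, columns = classes) for `"prob"`,
#'   or an integer vector for `"class"`. A single input yields a single row.
#' @export
predict.emotion_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  seqs <- .as_sequence_list(newdata, object$config)
  fw <- .lstm_forward(object$params, .stack_sequences(seqs), train = FALSE)
  if (type == "class") return(max.col(fw$probs) - 1L)
  fw$probs
}

#' Extract learned emotional features
#'
#' Returns the last-time-step hidden state of the second LSTM layer (before
#' dropout and the fully connected layer) — a `hidden_dim`-length vector per
#' sequence (256 under the default configuration). These are the features
#' visualized with PCA and reusable for transfer tasks.
#'
#' @param model a trained [emotion_model].
#' @param newdata as in [predict.emotion_model()].
#' @return numeric matrix, one row per sequence, `hidden_dim` columns.
#' @export
extract_emotional_features <- function(model, newdata) {
  stopifnot(inherits(model, "emotion_model"))
  seqs <- .as_sequence_list(newdata, model$config)
  fw <- .lstm_forward(model$params, .stack_sequences(seqs), train = FALSE)
  fw$hN
}
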