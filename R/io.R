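# Dataset and feature serialization: plain-text matrices + JSON sidecars,
# so every artifact is diffable and the synthetic path exercises the same
# reader used for real data.

#' Write / read a labeled dataset directory
#'
#' Each trial becomes `<stem>.csv` (channels x samples) plus `<stem>.json`
#' (rate, channel names, ids, label); `manifest.json` lists all trials.
#'
#' @param dataset list of `list(recording, label)` (see
#'   [generate_dataset()]).
#' @param dir target directory (created if missing).
#' @return (invisibly) the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- lapply(seq_along(dataset), function(i) {
    d <- dataset[[i]]
    stem <- sprintf("%s_%s", d$recording$subject_id, d$recording$trial_id)
    save_recording(d$recording, dir, stem = stem, format = "csv",
                   label = d$label)
    list(stem = stem, subject_id = d$recording$subject_id,
         trial_id = d$recording$trial_id,
         label = list(scheme = d$label$scheme, value = d$label$value))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n_trials = length(entries), trials = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_dataset
#' @param dir directory containing `manifest.json`.
#' @export
read_dataset <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) abort("no manifest.json in %s", dir)
  m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  lapply(m$trials, function(e) {
    rec <- load_recording(file.path(dir, paste0(e$stem, ".csv")))
    list(recording = rec,
         label = emotion_label(e$label$scheme, e$label$value))
  })
}

#' Write / read windowed feature examples
#'
#' Examples are stored long-format in one `features.csv` (columns:
#' `example`, `subject_id`, `trial_id`, `start_sample`, `label_value`,
#' `step`, `f1..fD`) with `schema.json` recording `C`, the windowing
#' parameters, the label scheme and the flattening order.
#'
#' @param examples list of `labeled_example`.
#' @param dir target directory.
#' @return (invisibly) the features.csv path.
#' @export
write_feature_examples <- function(examples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (length(examples) == 0L) abort("no examples to write")
  params <- attr(examples[[1L]]$sequence, "params")
  C <- attr(examples[[1L]]$sequence, "C")
  lab <- examples[[1L]]$label
  tabs <- lapply(seq_along(examples), function(i) {
    e <- examples[[i]]
    m <- unclass(e$sequence)
    data.table::data.table(
      example = i, subject_id = e$subject_id, trial_id = e$trial_id,
      start_sample = e$start_sample, label_value = e$label$value,
      step = seq_len(nrow(m)), m)
  })
  dt <- data.table::rbindlist(tabs)
  D <- ncol(examples[[1L]]$sequence)
  data.table::setnames(dt, 7:(6L + D), sprintf("f%d", seq_len(D)))
  path <- file.path(dir, "features.csv")
  data.table::fwrite(dt, path)
  jsonlite::write_json(
    list(C = C, L = params$L, K = params$K, N = params$N,
         feature_dim = D, label_scheme = lab$scheme,
         class_names = lab$class_names,
         flatten_order = "row_major_strict_upper_triangle"),
    file.path(dir, "schema.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_examples
#' @export
read_feature_examples <- function(dir) {
  schema <- jsonlite::read_json(file.path(dir, "schema.json"),
                                simplifyVector = TRUE)
  dt <- data.table::fread(file.path(dir, "features.csv"))
  params <- windowing_params(schema$L, schema$K, schema$N)
  fcols <- sprintf("f%d", seq_len(schema$feature_dim))
  df <- as.data.frame(dt)
  split_dt <- split(df, df$example)
  split_dt <- split_dt[order(as.integer(names(split_dt)))]
  lapply(unname(split_dt), function(g) {
    g <- g[order(g$step), , drop = FALSE]
    m <- as.matrix(g[, fcols, drop = FALSE])
    dimnames(m) <- NULL
    structure(
      list(sequence = structure(m, class = c("feature_sequence", "matrix"),
                                C = schema$C, params = params,
                                source = list(subject_id = g$subject_id[1L],
                                              trial_id = g$trial_id[1L],
                                              start_sample = g$start_sample[1L])),
           label = emotion_label(schema$label_scheme, g$label_value[1L]),
           subject_id = g$subject_id[1L], trial_id = g$trial_id[1L],
           start_sample = g$start_sample[1L]),
      class = "labeled_example")
  })
}
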