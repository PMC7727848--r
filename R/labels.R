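.label_schemes <- list(
  valence2  = c("low", "high"),
  arousal2  = c("low", "high"),
  quadrant4 = c("HVHA", "HVLA", "LVHA", "LVLA"),
  seed3     = c("positive", "neutral", "negative"))

#' Emotion labels
#'
#' A label is a class index under one of four schemes: binary valence,
#' binary arousal, the four valence/arousal quadrants (HVHA, HVLA, LVHA,
#' LVLA), or the three categorical film-clip classes (positive, neutral,
#' negative). Class indices are 0-based so they are stable identifiers in
#' serialized files; `n_classes()` and `class_name()` give the usual views.
#'
#' @param scheme one of `"valence2"`, `"arousal2"`, `"quadrant4"`, `"seed3"`.
#' @param value 0-based class index, `0 <= value < n_classes`.
#' @return an object of class `emotion_label`.
#' @examples
#' emotion_label("seed3", 0)        # positive
#' emotion_label("quadrant4", 3)    # LVLA
#' @export
emotion_label <- function(scheme, value) {
  scheme <- match.arg(scheme, names(.label_schemes))
  class_names <- .label_schemes[[scheme]]
  if (!is_count(value, min = 0L) || value >= length(class_names))
    abort("label value %s out of range [0, %d) for scheme '%s'",
          format(value), length(class_names), scheme)
  structure(list(scheme = scheme, value = as.integer(value),
                 class_names = class_names),
            class = "emotion_label")
}

#' @rdname emotion_label
#' @param label an `emotion_label`.
#' @export
n_classes <- function(label) length(label$class_names)

#' @rdname emotion_label
#' @export
class_name <- function(label) label$class_names[label$value + 1L]

#' @export
print.emotion_label <- function(x, ...) {
  cat(sprintf("<emotion_label> %s: %s (%d)\n", x$scheme, class_name(x), x$value))
  invisible(x)
}

#' Binarize a 9-point self-assessment rating
#'
#' Ratings above 5 map to "high", below 5 to "low". A rating of exactly 5 is
#' ambiguous (the neutral midpoint of the scale); by default it maps to "low"
#' so every trial stays usable, and `ties = "drop"` returns `NULL` so callers
#' can discard midpoint trials instead.
#'
#' @param rating numeric rating on the 1-9 scale.
#' @param dimension `"valence"` or `"arousal"`.
#' @param ties `"low"` (default) or `"drop"`.
#' @return an [emotion_label()] with scheme `valence2`/`arousal2`, or `NULL`
#'   when a midpoint rating is dropped.
#' @export
binarize_rating <- function(rating, dimension = c("valence", "arousal"),
                            ties = c("low", "drop")) {
  dimension <- match.arg(dimension)
  ties <- match.arg(ties)
  if (!is_scalar_num(rating) || rating < 1 || rating > 9)
    abort("rating %s outside the 1-9 scale", format(rating))
  scheme <- if (dimension == "valence") "valence2" else "arousal2"
  if (rating > 5) return(emotion_label(scheme, 1L))
  if (rating < 5) return(emotion_label(scheme, 0L))
  if (ties == "drop") return(NULL)
  emotion_label(scheme, 0L)
}

#' Combine binary valence and arousal labels into a quadrant label
#'
#' Class order: HVHA, HVLA, LVHA, LVLA (high/low valence crossed with
#' high/low arousal).
#'
#' @param valence an [emotion_label()] with scheme `valence2`.
#' @param arousal an [emotion_label()] with scheme `arousal2`.
#' @return an [emotion_label()] with scheme `quadrant4`.
#' @export
quadrant_label <- function(valence, arousal) {
  if (!inherits(valence, "emotion_label") || valence$scheme != "valence2")
    abort("`valence` must be an emotion_label with scheme 'valence2'")
  if (!inherits(arousal, "emotion_label") || arousal$scheme != "arousal2")
    abort("`arousal` must be an emotion_label with scheme 'arousal2'")
  hv <- valence$value == 1L; ha <- arousal$value == 1L
  idx <- if (hv && ha) 0L else if (hv && !ha) 1L else if (!hv && ha) 2L else 3L
  emotion_label("quadrant4", idx)
}

#' Categorical three-class label from its name
#'
#' @param name one of `"positive"`, `"neutral"`, `"negative"`.
#' @return an [emotion_label()] with scheme `seed3`.
#' @export
categorical_label <- function(name) {
  name <- match.arg(name, .label_schemes$seed3)
  emotion_label("seed3", match(name, .label_schemes$seed3) - 1L)
}
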