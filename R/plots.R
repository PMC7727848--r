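#' Heatmap of a channel-wise feature matrix
#'
#' Diverging colormap with bounds fixed at `[-1, 1]` (not data-adaptive, so
#' heatmaps are comparable across subjects and emotions): strong positive
#' correlations render green, strong negative red, near-zero white.
#' Channels are ordered and labeled by montage name; channel 1 is the top
#' row. Draws on the current graphics device.
#'
#' @param F a [channel_wise_feature()] or any symmetric C x C matrix.
#' @param channel_names C montage labels (default `rownames(F)` or
#'   `ch01...`).
#' @param main plot title.
#' @param axis_cex label size.
#' @return (invisibly) `F`.
#' @export
plot_channel_wise <- function(F, channel_names = NULL, main = "",
                              axis_cex = 0.5) {
  if (!is.matrix(F) || nrow(F) != ncol(F)) abort("`F` must be a square matrix")
  C <- nrow(F)
  if (is.null(channel_names)) channel_names <- rownames(F) %||% sprintf("ch%02d", seq_len(C))
  if (length(channel_names) != C)
    abort("%d channel names for a %d x %d matrix", length(channel_names), C, C)
  pal <- grDevices::colorRampPalette(c("#b2182b", "#ffffff", "#1a9850"))(200)
  breaks <- seq(-1, 1, length.out = 201)
  z <- t(unclass(F)[C:1, , drop = FALSE]) # row 1 at the top
  z[z > 1] <- 1; z[z < -1] <- -1
  graphics::image(x = seq_len(C), y = seq_len(C), z = z, col = pal,
                  breaks = breaks, axes = FALSE, xlab = "", ylab = "",
                  main = main, useRaster = FALSE)
  graphics::axis(1, at = seq_len(C), labels = channel_names, las = 2,
                 cex.axis = axis_cex, tick = FALSE)
  graphics::axis(2, at = seq_len(C), labels = rev(channel_names), las = 2,
                 cex.axis = axis_cex, tick = FALSE)
  graphics::box()
  invisible(F)
}

#' 2-D PCA embedding of learned emotional features
#'
#' Fits a 2-component PCA on the hidden-state vectors from
#' [extract_emotional_features()] and scatters them colored by label —
#' well-trained models show class-coherent clusters. PCA here is
#' visualization-only; classification never depends on it.
#'
#' @param features numeric matrix, one row per example (e.g. n x 256).
#' @param labels vector (factor, character or integer) of class labels, one
#'   per row.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @return (invisibly) a list with `scores` (n x 2) and `explained`
#'   (variance fractions of the two components, decreasing).
#' @export
plot_embedding <- function(features, labels, main = "Emotional features (PCA)",
                           ...) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) abort("need at least 2 feature vectors")
  if (length(labels) != nrow(features))
    abort("%d labels for %d feature vectors", length(labels), nrow(features))
  total_var <- sum(apply(features, 2L, stats::var))
  if (total_var == 0) {
    warning("all feature vectors identical; embedding is degenerate", call. = FALSE)
    scores <- matrix(0, nrow(features), 2L)
    explained <- c(0, 0)
  } else {
    pca <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = 2L)
    scores <- pca$x[, 1:2, drop = FALSE]
    if (ncol(scores) < 2L) scores <- cbind(scores, 0)
    explained <- (pca$sdev[1:2]^2) / sum(pca$sdev^2)
    explained[is.na(explained)] <- 0
  }
  lab <- factor(labels)
  cols <- grDevices::hcl.colors(max(3L, nlevels(lab)), "Dark 3")[as.integer(lab)]
  graphics::plot(scores[, 1L], scores[, 2L], col = cols, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * explained[2L]),
                 main = main, ...)
  graphics::legend("topright", legend = levels(lab), col =
                     grDevices::hcl.colors(max(3L, nlevels(lab)), "Dark 3")[seq_len(nlevels(lab))],
                   pch = 19, cex = 0.8, bty = "n")
  invisible(list(scores = scores, explained = explained))
}
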