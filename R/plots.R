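#' Plot PCA scores
#'
#' Scatter of the first two PC scores, coloured by habitat with
#' municipality glyphs when those columns are present.
#'
#' @param object A `toe_pca`.
#' @param axes Two axis numbers.
#' @param ... Unused.
#' @method autoplot toe_pca
#' @export
autoplot.toe_pca <- function(object, axes = c(1L, 2L), ...) {
  df <- object$scores_tbl
  ax <- paste0("PC", axes)
  lab <- sprintf("%s (%.1f%%)", ax, object$eig$percent[axes])
  p <- ggplot(df, aes(x = .data[[ax[1L]]], y = .data[[ax[2L]]]))
  if ("habitat" %in% names(df)) {
    p <- p + aes(colour = .data$habitat)
  }
  if ("municipality" %in% names(df)) {
    p <- p + aes(shape = .data$municipality)
  }
  p + geom_point() + labs(x = lab[1L], y = lab[2L]) + theme_minimal()
}

#' Plot the CV axis as a score histogram by group
#'
#' @param object A `toe_cva`.
#' @param ... Unused.
#' @method autoplot toe_cva
#' @export
autoplot.toe_cva <- function(object, ...) {
  ggplot(object$scores_tbl,
         aes(x = .data$CV1, fill = .data$group)) +
    geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    labs(x = "CV 1 score", y = "specimens") +
    theme_minimal()
}

#' Plot an aligned sample as an all-specimen overlay
#'
#' @param object A `toe_aligned`.
#' @param ... Unused.
#' @method autoplot toe_aligned
#' @export
autoplot.toe_aligned <- function(object, ...) {
  ids <- dimnames(object$coords)[[1L]]
  df <- purrr::map_dfr(seq_along(ids), function(i) {
    tibble(specimen_id = ids[i],
           x = object$coords[i, , 1L], y = object$coords[i, , 2L])
  })
  cons <- tibble(x = object$consensus[, 1L], y = object$consensus[, 2L])
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.15, size = 0.4) +
    geom_point(data = cons, colour = "red", size = 0.8) +
    coord_equal() +
    labs(x = "x (Procrustes units)", y = "y (Procrustes units)") +
    theme_minimal()
}

#' Overlay group mean shapes
#'
#' @param shapes A named list of mean-shape matrices from
#'   [group_mean_shapes()].
#' @return A ggplot.
#' @export
plot_mean_shapes <- function(shapes) {
  df <- purrr::imap_dfr(shapes, function(m, nm) {
    tibble(group = nm, x = m[, 1L], y = m[, 2L])
  })
  unit <- if (identical(attr(shapes, "space"), "pre_alignment_mm")) "mm"
          else "Procrustes units"
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$group)) +
    geom_point(size = 0.8) +
    coord_equal() +
    labs(x = paste0("x (", unit, ")"), y = paste0("y (", unit, ")")) +
    theme_minimal()
}
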