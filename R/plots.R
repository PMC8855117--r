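#' Dendrogram of a morphotype clustering
#'
#' @param object A `morphotype_result`.
#' @param ... Unused.
#' @return A ggplot object showing the Ward dendrogram with the chosen
#'   cut height.
#' @method autoplot morphotype_result
#' @export
autoplot.morphotype_result <- function(object, ...) {
  hc <- object$linkage
  segs <- dendrogram_segments(hc)
  n <- length(hc$order)
  cut_h <- mean(hc$height[c(n - object$k, n - object$k + 1L)])
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::geom_hline(yintercept = cut_h, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Ward merge height (Euclidean)",
                  title = sprintf("Ward clustering, k = %d", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

# rectangular dendrogram segments from an hclust object
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(n - 1L)
  node_h <- hc$height
  segs <- list()
  getx <- function(id) if (id < 0) xpos[-id] else node_x[id]
  geth <- function(id) if (id < 0) 0 else node_h[id]
  for (i in seq_len(n - 1L)) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- getx(a); xb <- getx(b)
    node_x[i] <- (xa + xb) / 2
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(xa, xb, xa), y = c(geth(a), geth(b), node_h[i]),
      xend = c(xa, xb, xb), yend = c(node_h[i], node_h[i], node_h[i]))
  }
  dplyr::bind_rows(segs)
}

#' Density plot with detected peaks
#'
#' @param object A `kde_peaks` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kde_peaks
#' @export
autoplot.kde_peaks <- function(object, ...) {
  dd <- tibble::tibble(x = object$density$x, y = object$density$y)
  pk <- tibble::tibble(x = object$peak_locations, y = object$peak_heights)
  ggplot2::ggplot(dd, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk, colour = "firebrick", size = 2) +
    ggplot2::labs(x = "value", y = "density",
                  title = sprintf("%d density peak(s)", object$n_peaks)) +
    ggplot2::theme_minimal()
}

#' Canonical discriminant score plot
#'
#' @param object A `discriminant_summary`.
#' @param ... Unused.
#' @return A ggplot object of the first two canonical functions (or a
#'   strip plot when only one function exists).
#' @method autoplot discriminant_summary
#' @export
autoplot.discriminant_summary <- function(object, ...) {
  sc <- object$scores
  if ("function_2" %in% names(sc)) {
    ggplot2::ggplot(sc, ggplot2::aes(.data$function_1, .data$function_2,
                                     colour = .data$group)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(
        x = sprintf("Function 1 (%.1f%%)", object$pct_variance[1]),
        y = sprintf("Function 2 (%.1f%%)", object$pct_variance[2]),
        colour = "morphotype") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(sc, ggplot2::aes(.data$group, .data$function_1,
                                     colour = .data$group)) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.8) +
      ggplot2::labs(x = "morphotype", y = "Function 1") +
      ggplot2::theme_minimal()
  }
}

#' Allele size against migratory distance
#'
#' @param object A `distance_association` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_association
#' @export
autoplot.distance_association <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$distance_km, .data$mean_allele)) +
    ggplot2::geom_jitter(width = 80, alpha = 0.7,
                         ggplot2::aes(colour = .data$species)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30") +
    ggplot2::labs(x = "migratory distance (km)",
                  y = "mean allele size (bp)",
                  title = sprintf("Spearman rho = %.3f (p = %.3g)",
                                  object$rho, object$p_rho)) +
    ggplot2::theme_minimal()
}

#' Plot a cell morphology in the section plane
#'
#' @param object A `cell_morphology`.
#' @param ... Unused.
#' @return A ggplot object of the XY projection of the arbor.
#' @method autoplot cell_morphology
#' @export
autoplot.cell_morphology <- function(object, ...) {
  nodes <- tibble::as_tibble(object)
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$node_id)
  child <- nodes[nodes$parent_id != -1L, ]
  pi_ <- idx[as.character(child$parent_id)]
  segs <- tibble::tibble(x = nodes$x[pi_], y = nodes$y[pi_],
                         xend = child$x, yend = child$y,
                         radius = child$radius)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend,
                                       linewidth = .data$radius)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", title = cell_id(object)) +
    ggplot2::theme_minimal()
}
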