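#' Ward minimum-variance clustering of cells into morphotypes
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`stats::hclust`, method `"ward.D2"`: Lance-Williams updates on squared
#' Euclidean distances) on the supplied (typically MMI-screened and
#' variance-shrunk log-transformed) features.  The number of morphotypes is
#' chosen over `k_range` at the largest *relative* jump between successive
#' merge heights — the cut below which groups are separated by the largest
#' distance relative to their internal structure; an explicit `k` overrides
#' the automatic choice.  Morphotype labels are renumbered so that type 1
#' has the highest mean `complexity` (when that column is present),
#' matching the field convention that Type I is the most complex
#' morphotype.
#'
#' @param features A tibble with a `cell_id` column and numeric feature
#'   columns (already transformed).
#' @param k_range Candidate cluster counts, default `2:6`.
#' @param k Optional fixed cluster count.
#' @param feature_cols Optional subset of feature columns to use.
#' @return A list of class `morphotype_result`: `selected_features`,
#'   `linkage` (the `hclust` object), `heights`, `k`, `k_range`,
#'   `gap_ratio` (per candidate k), `labels` (tibble `cell_id`,
#'   `morphotype`), `representatives` (filled by [representative_cell()]
#'   when run through the pipeline).
#' @export
ward_cluster <- function(features, k_range = 2:6, k = NULL,
                         feature_cols = NULL) {
  cols <- resolve_feature_cols(features, feature_cols)
  X <- as.matrix(features[cols])
  n <- nrow(X)
  if (n < max(k_range) + 1L) {
    stop("need at least max(k_range) + 1 = ", max(k_range) + 1L,
         " cells for clustering", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  h <- hc$height
  gap <- rep(NA_real_, length(k_range))
  eps <- 1e-12 * max(h, 1)
  for (i in seq_along(k_range)) {
    kk <- k_range[i]
    if (kk < 2L || kk > n - 1L) next
    top <- h[n - kk + 1L]
    below <- if (kk == n) 0 else h[n - kk]
    gap[i] <- if (below > eps) top / below
      else if (top > eps) Inf else NA_real_
  }
  if (is.null(k)) {
    if (all(is.na(gap))) {
      stop("cannot choose k: all merge heights are zero", call. = FALSE)
    }
    k <- k_range[which.max(gap)]
  }
  labels <- stats::cutree(hc, k = k)
  labels <- relabel_morphotypes(labels, features, k)
  structure(list(
    selected_features = cols,
    linkage = hc,
    heights = h,
    k = as.integer(k),
    k_range = k_range,
    gap_ratio = stats::setNames(gap, k_range),
    labels = tibble::tibble(cell_id = as.character(features$cell_id),
                            morphotype = labels),
    representatives = NULL),
    class = "morphotype_result")
}

# type 1 = highest mean complexity when available, else largest cluster
relabel_morphotypes <- function(labels, features, k) {
  if ("complexity" %in% names(features)) {
    key <- tapply(features$complexity, factor(labels, levels = 1:k), mean)
    ord <- order(-key)
  } else {
    ord <- order(-tabulate(labels, nbins = k))
  }
  match(labels, ord)
}

#' @export
print.morphotype_result <- function(x, ...) {
  cat("<morphotype_result> k =", x$k, "on",
      nrow(x$labels), "cells;", length(x$selected_features),
      "features:", paste(x$selected_features, collapse = ", "), "\n")
  print(table(morphotype = x$labels$morphotype))
  invisible(x)
}

#' Representative ("average") cell of each morphotype
#'
#' For each cluster, returns the member cell with the smallest sum of
#' Euclidean distances to all other members in the feature space — the
#' "average cell" used to illustrate a morphotype.  Ties are broken by
#' lowest `cell_id`.
#'
#' @param features A tibble with `cell_id` and numeric feature columns
#'   (the same space used for clustering).
#' @param labels Either a `morphotype_result` or a vector of cluster ids
#'   aligned with `features` rows.
#' @param feature_cols Optional subset of feature columns.
#' @return A tibble with columns `morphotype`, `cell_id`, `sum_distance`.
#' @export
representative_cell <- function(features, labels, feature_cols = NULL) {
  if (inherits(labels, "morphotype_result")) labels <- labels$labels$morphotype
  stopifnot(length(labels) == nrow(features))
  cols <- resolve_feature_cols(features, feature_cols)
  X <- as.matrix(features[cols])
  ids <- as.character(features$cell_id)
  purrr::map_dfr(sort(unique(labels)), function(g) {
    sel <- which(labels == g)
    D <- as.matrix(stats::dist(X[sel, , drop = FALSE]))
    sums <- colSums(D)
    ord <- order(sums, ids[sel])
    tibble::tibble(morphotype = g, cell_id = ids[sel][ord[1]],
                   sum_distance = unname(sums[ord[1]]))
  })
}

#' Count peaks of a kernel density estimate
#'
#' Gaussian-kernel density on a 512-point grid; peaks are interior local
#' maxima whose topographic prominence exceeds `prominence` times the
#' maximum density.  Used to confirm visually separable morphotype modes
#' in complexity values.  The default bandwidth is Sheather-Jones
#' (`"SJ"`): Silverman's rule-of-thumb is calibrated to a unimodal
#' Gaussian reference and systematically over-smooths well-separated
#' mixtures, merging genuine modes; when the SJ selector fails on sparse
#' samples the Silverman rule is used as fallback.
#'
#' @param values Numeric sample, `n >= 10`, non-constant.
#' @param bandwidth Bandwidth rule or numeric bandwidth passed to
#'   `stats::density` (default `"SJ"`).
#' @param prominence Fraction of the maximum density a peak must rise
#'   above its key saddle, default 0.05.
#' @return A list of class `kde_peaks`: `n_peaks`, `peak_locations`,
#'   `peak_heights`, `density` (the `density` object).
#' @export
kernel_density_peaks <- function(values, bandwidth = "SJ",
                                 prominence = 0.05) {
  x <- values[is.finite(values)]
  if (length(x) < 10L) stop("need at least 10 values", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample: density peaks undefined",
                              call. = FALSE)
  dens <- tryCatch(stats::density(x, bw = bandwidth, n = 512),
                   error = function(e) stats::density(x, bw = "nrd0",
                                                     n = 512))
  d <- dens$y
  n <- length(d)
  loc <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  if (length(loc) == 0L) loc <- which.max(d)
  prom <- vapply(loc, function(i) peak_prominence(d, i), numeric(1))
  keep <- prom > prominence * max(d)
  structure(list(n_peaks = sum(keep),
                 peak_locations = dens$x[loc[keep]],
                 peak_heights = d[loc[keep]],
                 density = dens),
            class = "kde_peaks")
}

# topographic prominence of d[i]: height above the higher of the two key
# saddles towards the nearest strictly higher ground on each side
peak_prominence <- function(d, i) {
  h <- d[i]
  saddle <- -Inf
  left <- which(d[seq_len(i - 1L)] > h)
  if (length(left) > 0) {
    saddle <- max(saddle, min(d[max(left):i]))
  }
  right <- which(d[(i + 1L):length(d)] > h)
  if (length(right) > 0) {
    saddle <- max(saddle, min(d[i:(i + min(right))]))
  }
  if (!is.finite(saddle)) return(h)  # global maximum
  h - saddle
}

#' @export
print.kde_peaks <- function(x, ...) {
  cat("<kde_peaks>", x$n_peaks, "peak(s) at",
      paste(signif(x$peak_locations, 5), collapse = ", "), "\n")
  invisible(x)
}
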