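#' Path-based morphometrics
#'
#' * `total_branch_length`: sum of Euclidean inter-node distances over all
#'   edges of the arbor (micrometres).
#' * `tortuosity`: mean over segments of path length / straight-line chord
#'   between the segment's endpoints (dimensionless, >= 1); zero-chord
#'   segments are excluded with a warning.
#' * `segments_per_mm`: number of segments per millimetre of total length.
#' * `base_diameter`: mean over primary branches of twice the radius at the
#'   first branch node after the soma (micrometres).
#'
#' @param cell A [cell_morphology()].
#' @param decomp Optional precomputed [decompose()] result.
#' @return A one-row tibble with columns `total_branch_length`,
#'   `tortuosity`, `n_segments`, `segments_per_mm`, `base_diameter`.
#' @export
path_metrics <- function(cell, decomp = decompose(cell)) {
  nodes <- tibble::as_tibble(cell)
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  map <- integer(max(nodes$node_id))
  map[nodes$node_id] <- seq_len(nrow(nodes))
  rows_of <- function(ids) map[ids]

  seg_len <- purrr::map_dbl(decomp$nodes, function(ids) {
    p <- coords[rows_of(ids), , drop = FALSE]
    sum(sqrt(rowSums(diff(p)^2)))
  })
  chords <- purrr::map_dbl(decomp$nodes, function(ids) {
    p <- coords[rows_of(ids), , drop = FALSE]
    sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  })
  total <- sum(seg_len)
  ok <- chords > 0
  if (!all(ok)) {
    warning("zero-chord segment(s) excluded from tortuosity", call. = FALSE)
  }
  tort <- if (any(ok)) mean(seg_len[ok] / chords[ok]) else NA_real_

  prim <- which(is.na(decomp$parent_segment))
  base_d <- mean(purrr::map_dbl(prim, function(i) {
    2 * nodes$radius[rows_of(decomp$nodes[[i]][2])]
  }))
  tibble::tibble(
    total_branch_length = total,
    tortuosity = tort,
    n_segments = nrow(decomp),
    segments_per_mm = nrow(decomp) * 1000 / total,
    base_diameter = base_d)
}

#' Frustum-model surface and volume
#'
#' Each inter-node edge is modelled as a conical frustum whose end radii
#' are the node radii; `tree_surface_area` is the summed lateral area,
#' `total_branch_volume` the summed volume, and `branch_surface_area` the
#' tree surface divided by the number of primary branches (mean surface
#' per primary tree).  Edges leaving the soma use the distal node's radius
#' at both ends, so the soma body does not inflate branch metrics.
#'
#' @inheritParams path_metrics
#' @return A one-row tibble with `tree_surface_area`,
#'   `branch_surface_area`, `total_branch_volume`.
#' @export
frustum_metrics <- function(cell, decomp = decompose(cell)) {
  nodes <- tibble::as_tibble(cell)
  root <- nodes$node_id[nodes$parent_id == -1L]
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$node_id)
  child <- nodes[nodes$parent_id != -1L, , drop = FALSE]
  pi_ <- idx[as.character(child$parent_id)]
  h <- sqrt((child$x - nodes$x[pi_])^2 + (child$y - nodes$y[pi_])^2 +
              (child$z - nodes$z[pi_])^2)
  r2 <- child$radius
  r1 <- ifelse(child$parent_id == root, r2, nodes$radius[pi_])
  lat <- pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2)
  vol <- pi * h * (r1^2 + r1 * r2 + r2^2) / 3
  np <- attr(decomp, "primary_count", exact = TRUE)
  tibble::tibble(tree_surface_area = sum(lat),
                 branch_surface_area = sum(lat) / np,
                 total_branch_volume = sum(vol))
}

#' Mean planar bifurcation angle
#'
#' At every branch point (a non-soma node with two or more daughters) the
#' angle between the direction vectors from the branch point to the first
#' node of each daughter is measured; multifurcations contribute the mean
#' over all daughter pairs.  The cell-level value is the mean over branch
#' points, in degrees.  Cells without bifurcations return `NA` (the angle
#' is undefined, not zero).
#'
#' @inheritParams path_metrics
#' @return Mean planar angle in degrees, or `NA_real_`.
#' @export
planar_angle <- function(cell) {
  nodes <- tibble::as_tibble(cell)
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  root_row <- which(nodes$parent_id == -1L)
  parent_row <- match(nodes$parent_id, nodes$node_id)
  kid_rows <- split(seq_len(nrow(nodes))[-root_row],
                    factor(parent_row[-root_row],
                           levels = seq_len(nrow(nodes))))
  bp <- setdiff(which(lengths(kid_rows) >= 2L), root_row)
  if (length(bp) == 0L) return(NA_real_)
  angs <- vapply(bp, function(b) {
    V <- coords[kid_rows[[b]], , drop = FALSE] -
      matrix(coords[b, ], length(kid_rows[[b]]), 3, byrow = TRUE)
    V <- V / sqrt(rowSums(V^2))
    pairs <- utils::combn(nrow(V), 2)
    mean(apply(pairs, 2, function(pr) {
      ct <- sum(V[pr[1], ] * V[pr[2], ])
      acos(min(1, max(-1, ct))) * 180 / pi
    }))
  }, numeric(1))
  mean(angs)
}

#' Vertex analysis
#'
#' Classifies every branch point by the terminality of its daughter
#' segments: `va` counts branch points whose daughters are (at least) two
#' terminal segments, `vb` those with exactly one terminal daughter, and
#' `vc` those with none.  For strictly binary trees
#' `va + vb + vc` equals the number of branch points.
#'
#' @param decomp A [decompose()] result.
#' @return A one-row tibble with integer columns `vertex_va`, `vertex_vb`,
#'   `vertex_vc`.
#' @export
vertex_analysis <- function(decomp) {
  va <- vb <- vc <- 0L
  parents <- decomp$parent_segment
  for (sid in decomp$segment_id) {
    d <- which(!is.na(parents) & parents == sid)
    if (length(d) < 2L) next
    t <- sum(decomp$is_terminal[d])
    if (t >= 2L) va <- va + 1L
    else if (t == 1L) vb <- vb + 1L
    else vc <- vc + 1L
  }
  tibble::tibble(vertex_va = va, vertex_vb = vb, vertex_vc = vc)
}

#' Box-counting fractal dimension
#'
#' The arbor is resampled to points spaced at most `min(scales)/4` apart
#' along every edge, then for each box size `s` the number `N(s)` of
#' occupied cells of an axis-aligned cubic grid is counted.  `k_dim` is
#' the least-squares slope of `log N(s)` against `log(1/s)`, clamped to
#' `[0, 3]`.  By default 8 dyadic scales from `extent/2` down to
#' `extent/256` are used, where extent is the largest coordinate range.
#'
#' @param cell A [cell_morphology()] (or a bare matrix of 3-D points, which
#'   is used as-is without resampling).
#' @param scales Optional numeric vector of box sizes (micrometres); at
#'   least 4 values spanning at least one decade.
#' @return Fractal dimension in `[0, 3]`; a single point gives 0.
#' @export
fractal_dimension <- function(cell, scales = NULL) {
  if (inherits(cell, "cell_morphology")) {
    pts <- as.matrix(tibble::as_tibble(cell)[, c("x", "y", "z")])
    resample <- TRUE
  } else {
    pts <- as.matrix(cell)[, 1:3, drop = FALSE]
    resample <- FALSE
  }
  extent <- max(apply(pts, 2, function(v) diff(range(v))))
  if (extent == 0 || nrow(pts) == 1L) return(0)
  if (is.null(scales)) scales <- extent / 2^(1:8)
  if (length(scales) < 4L) {
    stop("need at least 4 box-counting scales", call. = FALSE)
  }
  if (max(scales) / min(scales) < 10) {
    stop("box-counting scales must span at least one decade", call. = FALSE)
  }
  if (resample) {
    pts <- resample_arbor(cell, spacing = min(scales) / 4)
  }
  origin <- apply(pts, 2, min)
  shifted <- sweep(pts, 2, origin)
  counts <- purrr::map_int(scales, function(s) {
    idx <- floor(shifted / s)
    base <- max(idx) + 2
    length(unique((idx[, 1] * base + idx[, 2]) * base + idx[, 3]))
  })
  fit <- stats::lm(log(counts) ~ log(1 / scales))
  min(3, max(0, unname(stats::coef(fit)[2])))
}

# points along every edge at <= `spacing` separation (includes all nodes)
resample_arbor <- function(cell, spacing) {
  nodes <- tibble::as_tibble(cell)
  child <- nodes[nodes$parent_id != -1L, , drop = FALSE]
  if (nrow(child) == 0L) return(as.matrix(nodes[, c("x", "y", "z")]))
  pi_ <- match(child$parent_id, nodes$node_id)
  a <- as.matrix(nodes[pi_, c("x", "y", "z")])
  b <- as.matrix(child[, c("x", "y", "z")])
  len <- sqrt(rowSums((b - a)^2))
  k <- pmax(1L, ceiling(len / spacing))
  # vectorized linear interpolation over all edges at once
  edge <- rep.int(seq_along(k), k + 1L)
  t <- unlist(lapply(k, function(ki) seq(0, 1, length.out = ki + 1L)),
              use.names = FALSE)
  a[edge, , drop = FALSE] + t * (b[edge, , drop = FALSE] -
                                   a[edge, , drop = FALSE])
}

#' Canonical morphometric feature names
#'
#' The 19 named per-cell variables produced by [compute_features()], in
#' canonical order.
#'
#' @return A character vector of length 19.
#' @export
feature_names <- function() {
  c("total_branch_length", "branch_surface_area", "tortuosity",
    "total_branch_volume", "base_diameter", "n_segments",
    "segments_per_mm", "n_branch_points", "tree_surface_area",
    "planar_angle", "complexity", "hull_perimeter_2d", "hull_area_2d",
    "hull_surface_area_3d", "hull_volume_3d", "vertex_va", "vertex_vb",
    "vertex_vc", "k_dim")
}

#' Compute the full morphometric feature vector of one cell
#'
#' Aggregates every per-cell variable (see [feature_names()]) into a
#' one-row tibble prefixed with `cell_id`, `species`, `individual`.
#' `planar_angle` and `tortuosity` may be `NA` on degenerate arbors; all
#' other fields are finite and non-negative.
#'
#' @param cell A [cell_morphology()].
#' @return A one-row tibble.
#' @export
compute_features <- function(cell) {
  rep <- validate_tree(cell)
  if (!rep$ok) {
    stop("invalid cell '", cell_id(cell), "': ",
         paste(rep$issues$message, collapse = "; "), call. = FALSE)
  }
  decomp <- decompose(cell)
  pm <- path_metrics(cell, decomp)
  fm <- frustum_metrics(cell, decomp)
  hull <- suppressWarnings(
    convex_hull_metrics(tibble::as_tibble(cell)[, c("x", "y", "z")]))
  tibble::tibble(
    cell_id = cell_id(cell),
    species = attr(cell, "species", exact = TRUE),
    individual = attr(cell, "individual", exact = TRUE),
    total_branch_length = pm$total_branch_length,
    branch_surface_area = fm$branch_surface_area,
    tortuosity = pm$tortuosity,
    total_branch_volume = fm$total_branch_volume,
    base_diameter = pm$base_diameter,
    n_segments = as.integer(pm$n_segments),
    segments_per_mm = pm$segments_per_mm,
    n_branch_points = attr(decomp, "n_branch_points", exact = TRUE),
    tree_surface_area = fm$tree_surface_area,
    planar_angle = planar_angle(cell),
    complexity = complexity(decomp, pm$total_branch_length),
    hull_perimeter_2d = hull$hull_perimeter_2d,
    hull_area_2d = hull$hull_area_2d,
    hull_surface_area_3d = hull$hull_surface_area_3d,
    hull_volume_3d = hull$hull_volume_3d) |>
    dplyr::bind_cols(vertex_analysis(decomp)) |>
    dplyr::mutate(k_dim = fractal_dimension(cell))
}

#' Compute the feature matrix for many cells
#'
#' @param cells A list of [cell_morphology()] objects.
#' @return A tibble with one row per cell (see [compute_features()]).
#' @export
compute_feature_matrix <- function(cells) {
  purrr::map_dfr(cells, compute_features)
}
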