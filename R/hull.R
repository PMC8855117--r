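#' Convex hull metrics of a 3-D point cloud
#'
#' The 2-D metrics (perimeter, area) are taken from the convex hull of the
#' XY projection (the section plane); the 3-D metrics (surface area,
#' volume) from the full 3-D hull, computed by an incremental
#' (beneath-beyond) algorithm.  Degenerate inputs (collinear projection,
#' coplanar cloud) yield zeros for the affected dimension together with a
#' `degenerate_2d` / `degenerate_3d` flag and a warning.
#'
#' @param points A numeric matrix or data frame with 3 columns (x, y, z in
#'   micrometres).
#' @return A one-row tibble with columns `hull_perimeter_2d`,
#'   `hull_area_2d`, `hull_surface_area_3d`, `hull_volume_3d`,
#'   `degenerate_2d`, `degenerate_3d`.
#' @export
convex_hull_metrics <- function(points) {
  pts <- as.matrix(points)[, 1:3, drop = FALSE]
  storage.mode(pts) <- "double"
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]

  # ---- 2-D: hull of XY projection
  xy <- unique(pts[, 1:2, drop = FALSE])
  per2 <- area2 <- 0
  deg2 <- TRUE
  if (nrow(xy) >= 3) {
    h <- grDevices::chull(xy[, 1], xy[, 2])
    hx <- xy[h, 1]; hy <- xy[h, 2]
    a <- abs(polygon_area(hx, hy))
    if (a > 0) {
      deg2 <- FALSE
      area2 <- a
      per2 <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    }
  }

  # ---- 3-D hull
  surf3 <- vol3 <- 0
  faces <- hull3d_faces(pts)
  deg3 <- is.null(faces)
  if (!deg3) {
    a <- pts[faces[, 1], , drop = FALSE]
    b <- pts[faces[, 2], , drop = FALSE]
    cc <- pts[faces[, 3], , drop = FALSE]
    cr <- vec_cross(b - a, cc - a)
    surf3 <- sum(sqrt(rowSums(cr^2))) / 2
    ctr <- colMeans(pts)
    a0 <- sweep(a, 2, ctr); b0 <- sweep(b, 2, ctr); c0 <- sweep(cc, 2, ctr)
    vol3 <- abs(sum(rowSums(a0 * vec_cross(b0, c0)))) / 6
  }
  if (deg2 || deg3) {
    warning("degenerate point set: some hull metrics reported as 0",
            call. = FALSE)
  }
  tibble::tibble(hull_perimeter_2d = per2, hull_area_2d = area2,
                 hull_surface_area_3d = surf3, hull_volume_3d = vol3,
                 degenerate_2d = deg2, degenerate_3d = deg3)
}

# row-wise cross product of two n x 3 matrices
vec_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Incremental 3-D convex hull.  Returns an m x 3 matrix of point indices
# per triangular facet, outward oriented, or NULL for degenerate input.
hull3d_faces <- function(pts, tol = NULL) {
  n <- nrow(pts)
  if (n < 4) return(NULL)
  diam <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  if (diam == 0) return(NULL)
  if (is.null(tol)) tol <- 1e-10 * diam

  # initial simplex: extreme in x, farthest point, farthest from line,
  # farthest from plane
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] <= tol^2) return(NULL)
  u <- pts[i2, ] - pts[i1, ]
  w <- sweep(pts, 2, pts[i1, ])
  cr <- vec_cross(w, matrix(u, n, 3, byrow = TRUE))
  d2 <- rowSums(cr^2)
  i3 <- which.max(d2)
  if (sqrt(d2[i3]) / sqrt(sum(u^2)) <= tol) return(NULL)
  nrm <- vec_cross(matrix(pts[i2, ] - pts[i1, ], 1),
                   matrix(pts[i3, ] - pts[i1, ], 1))[1, ]
  nrm <- nrm / sqrt(sum(nrm^2))
  d3 <- abs(as.vector(w %*% nrm))
  i4 <- which.max(d3)
  if (d3[i4] <= tol) return(NULL)

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    a <- pts[f[1], ]; nv <- vec_cross(matrix(pts[f[2], ] - a, 1),
                                     matrix(pts[f[3], ] - a, 1))[1, ]
    if (sum(nv * (interior - a)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  normals <- function(fs) {
    a <- pts[fs[, 1], , drop = FALSE]
    nv <- vec_cross(pts[fs[, 2], , drop = FALSE] - a,
                    pts[fs[, 3], , drop = FALSE] - a)
    len <- sqrt(rowSums(nv^2))
    cbind(nv / len, rowSums((nv / len) * a))
  }
  nrm <- normals(faces)  # columns: nx ny nz offset

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  # far points first: fewer retained interior candidates later
  rest <- rest[order(-rowSums(sweep(pts[rest, , drop = FALSE], 2,
                                    interior)^2))]
  for (p in rest) {
    sd <- nrm[, 1:3, drop = FALSE] %*% pts[p, ] - nrm[, 4]
    vis <- sd > tol
    if (!any(vis)) next
    visf <- faces[vis, , drop = FALSE]
    # horizon: edges of visible faces not shared by two visible faces
    e <- rbind(visf[, c(1, 2)], visf[, c(2, 3)], visf[, c(3, 1)])
    lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
    key <- lo * (n + 1) + hi
    horizon <- e[key %in% key[!(duplicated(key) |
                                  duplicated(key, fromLast = TRUE))], ,
                 drop = FALSE]
    newf <- cbind(horizon[, 1], horizon[, 2], p)
    newf <- t(apply(newf, 1, orient))
    faces <- rbind(faces[!vis, , drop = FALSE], newf)
    nrm <- rbind(nrm[!vis, , drop = FALSE], normals(newf))
  }
  faces
}
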