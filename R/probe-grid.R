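#' Place a stereological probe grid over a section contour
#'
#' Systematic-random sampling: square probes (default 50 um side) are
#' centred on the lattice `origin_offset + spacing * (i, j)` (default 900 um
#' interval) and kept when the centre falls inside the section contour, so
#' the expected probe count is proportional to the contour area.  When
#' `origin_offset` is `NULL` a uniform random offset in `[0, spacing)^2` is
#' drawn (seeded via `seed`), giving an unbiased systematic-random design.
#'
#' Lattice inclusion is half-open: a centre lying on the "low" boundary of
#' an axis-aligned contour edge counts as inside, one on the "high"
#' boundary does not, so abutting rectangles never share a probe.
#'
#' @param contour A data frame or matrix with columns/two columns `x`, `y`
#'   (micrometres) tracing a simple closed polygon.
#' @param probe_side Probe square side in micrometres (default 50).
#' @param spacing Lattice interval in micrometres (default 900); must be at
#'   least `probe_side`.
#' @param origin_offset Numeric length-2 offset of the lattice origin, or
#'   `NULL` for a seeded random offset.
#' @param seed Integer seed used only when `origin_offset` is `NULL`.
#' @return A list of class `probe_grid`: `probes` (tibble `probe_id`, `cx`,
#'   `cy`), `probe_side`, `spacing`, `origin_offset`, `seed`, `contour`.
#' @export
place_probe_grid <- function(contour, probe_side = 50, spacing = 900,
                             origin_offset = NULL, seed = NULL) {
  contour <- as.data.frame(contour)
  if (ncol(contour) < 2) stop("contour needs x and y columns", call. = FALSE)
  names(contour)[1:2] <- c("x", "y")
  if (probe_side > spacing) {
    stop("probe_side must not exceed spacing", call. = FALSE)
  }
  area <- abs(polygon_area(contour$x, contour$y))
  if (area <= .Machine$double.eps) {
    stop("degenerate contour: area is zero", call. = FALSE)
  }
  if (is.null(origin_offset)) {
    if (!is.null(seed)) set.seed(seed)
    origin_offset <- stats::runif(2, 0, spacing)
  }
  stopifnot(length(origin_offset) == 2)

  xr <- range(contour$x); yr <- range(contour$y)
  is <- seq(floor((xr[1] - origin_offset[1]) / spacing) - 1L,
            ceiling((xr[2] - origin_offset[1]) / spacing) + 1L)
  js <- seq(floor((yr[1] - origin_offset[2]) / spacing) - 1L,
            ceiling((yr[2] - origin_offset[2]) / spacing) + 1L)
  lattice <- expand.grid(cx = origin_offset[1] + spacing * is,
                         cy = origin_offset[2] + spacing * js)
  # nudging by +eps makes boundary inclusion half-open on axis-aligned edges
  eps <- 1e-9 * spacing
  inside <- pracma::inpolygon(lattice$cx + eps, lattice$cy + eps,
                              contour$x, contour$y, boundary = TRUE)
  probes <- tibble::as_tibble(lattice[inside, , drop = FALSE])
  probes <- probes[order(probes$cy, probes$cx), ]
  probes <- tibble::tibble(probe_id = seq_len(nrow(probes)),
                           cx = probes$cx, cy = probes$cy)
  structure(list(probes = probes, probe_side = probe_side, spacing = spacing,
                 origin_offset = as.numeric(origin_offset), seed = seed,
                 contour = tibble::as_tibble(contour[c("x", "y")])),
            class = "probe_grid")
}

#' @export
print.probe_grid <- function(x, ...) {
  cat("<probe_grid> ", nrow(x$probes), " probes (", x$probe_side, " um side, ",
      x$spacing, " um spacing)\n", sep = "")
  invisible(x)
}

# shoelace area, signed
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Select cells via the probe grid
#'
#' Implements the stereological selection rule: every soma whose position
#' falls inside a probe box (half-open, `[c - side/2, c + side/2)` on both
#' axes) is selected; when a probe box contains no soma, the single nearest
#' soma outside the box (Euclidean distance to the box boundary) is selected
#' instead.  A soma is selected at most once overall; equidistant fallback
#' candidates are broken by lowest `cell_id`.
#'
#' @param somata A data frame with columns `cell_id`, `x`, `y` (soma
#'   positions in the grid's frame).
#' @param grid A [place_probe_grid()] result.
#' @return A tibble with columns `probe_id`, `cell_id`, `fallback`
#'   (`TRUE` when the cell was picked by the empty-probe nearest rule).
#' @export
select_cells <- function(somata, grid) {
  stopifnot(inherits(grid, "probe_grid"))
  somata <- tibble::as_tibble(somata)
  out <- tibble::tibble(probe_id = integer(), cell_id = character(),
                        fallback = logical())
  if (nrow(somata) == 0L) {
    warning("no somata supplied: empty selection", call. = FALSE)
    return(out)
  }
  somata$cell_id <- as.character(somata$cell_id)
  half <- grid$probe_side / 2
  taken <- character(0)
  rows <- list()
  for (i in seq_len(nrow(grid$probes))) {
    cx <- grid$probes$cx[i]; cy <- grid$probes$cy[i]
    inside <- somata$x >= cx - half & somata$x < cx + half &
      somata$y >= cy - half & somata$y < cy + half
    ids <- setdiff(somata$cell_id[inside], taken)
    if (length(ids) > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        probe_id = grid$probes$probe_id[i], cell_id = sort(ids),
        fallback = FALSE)
      taken <- c(taken, ids)
    } else {
      cand <- somata[!somata$cell_id %in% taken, , drop = FALSE]
      if (nrow(cand) == 0L) next
      dx <- pmax(cx - half - cand$x, cand$x - (cx + half), 0)
      dy <- pmax(cy - half - cand$y, cand$y - (cy + half), 0)
      d <- sqrt(dx^2 + dy^2)
      ord <- order(d, cand$cell_id)
      pick <- cand$cell_id[ord[1]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        probe_id = grid$probes$probe_id[i], cell_id = pick, fallback = TRUE)
      taken <- c(taken, pick)
    }
  }
  if (length(rows) > 0) out <- dplyr::bind_rows(rows)
  out
}
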