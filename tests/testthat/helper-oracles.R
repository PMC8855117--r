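# Independent brute-force oracles used to check the package's morphometry
# and clustering code.  These are deliberately naive (recursion, O(n^3),
# O(n^4)) and share no code with the implementation.

# --- simple deterministic test cells --------------------------------------

# straight cable along +x: n_nodes nodes, total length `length_um`
make_cable <- function(length_um = 100, n_nodes = 11, radius = 1,
                       cell_id = "cable") {
  xs <- seq(0, length_um, length.out = n_nodes)
  cell_morphology(data.frame(
    node_id = seq_len(n_nodes), parent_id = c(-1, seq_len(n_nodes - 1)),
    x = xs, y = 0, z = 0, radius = radius), cell_id)
}

# one primary (10 um) bifurcating into two 5 um terminals
make_y_tree <- function() {
  cell_morphology(data.frame(
    node_id = 1:4, parent_id = c(-1, 1, 2, 2),
    x = c(0, 10, 15, 15), y = c(0, 0, 5, -5), z = 0, radius = 1), "ytree")
}

# random binary tree grown independently of the package generator
random_tree <- function(seed, n_segments = 12, step = 4) {
  set.seed(seed)
  nodes <- data.frame(node_id = 1L, parent_id = -1L, x = 0, y = 0, z = 0,
                      radius = 2)
  tips <- 1L
  nid <- 1L
  while (nid < n_segments * 3) {
    tip <- tips[sample.int(length(tips), 1)]
    k <- sample(1:2, 1)  # extend or bifurcate
    for (j in seq_len(k)) {
      nid <- nid + 1L
      base <- nodes[nodes$node_id == tip, ]
      nodes <- rbind(nodes, data.frame(
        node_id = nid, parent_id = tip,
        x = base$x + stats::rnorm(1, 0, step),
        y = base$y + stats::rnorm(1, 0, step),
        z = base$z + stats::rnorm(1, 0, step),
        radius = stats::runif(1, 0.5, 2)))
      tips <- c(tips, nid)
    }
    tips <- setdiff(tips, tip)
  }
  cell_morphology(nodes, paste0("rt", seed))
}

# --- recursive traversal oracle for segment decomposition ------------------

oracle_segments <- function(cell) {
  nodes <- as.data.frame(cell)
  kids <- function(id) nodes$node_id[nodes$parent_id == id]
  root <- nodes$node_id[nodes$parent_id == -1]
  segs <- list()
  walk <- function(start, anchor, order) {
    path <- c(anchor, start)
    cur <- start
    while (length(kids(cur)) == 1) {
      cur <- kids(cur)
      path <- c(path, cur)
    }
    ch <- kids(cur)
    segs[[length(segs) + 1]] <<- list(nodes = path, order = order,
                                      terminal = length(ch) == 0)
    for (c2 in ch) walk(c2, cur, order + 1)
  }
  for (c1 in kids(root)) walk(c1, root, 1)
  segs
}

# --- per-edge summation oracles --------------------------------------------

oracle_total_length <- function(cell) {
  nodes <- as.data.frame(cell)
  tot <- 0
  for (i in seq_len(nrow(nodes))) {
    if (nodes$parent_id[i] == -1) next
    p <- nodes[nodes$node_id == nodes$parent_id[i], ]
    tot <- tot + sqrt((nodes$x[i] - p$x)^2 + (nodes$y[i] - p$y)^2 +
                        (nodes$z[i] - p$z)^2)
  }
  tot
}

oracle_frusta <- function(cell) {
  nodes <- as.data.frame(cell)
  root <- nodes$node_id[nodes$parent_id == -1]
  surf <- vol <- 0
  for (i in seq_len(nrow(nodes))) {
    if (nodes$parent_id[i] == -1) next
    p <- nodes[nodes$node_id == nodes$parent_id[i], ]
    h <- sqrt((nodes$x[i] - p$x)^2 + (nodes$y[i] - p$y)^2 +
                (nodes$z[i] - p$z)^2)
    r2 <- nodes$radius[i]
    r1 <- if (nodes$parent_id[i] == root) r2 else p$radius
    surf <- surf + pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2)
    vol <- vol + pi * h * (r1^2 + r1 * r2 + r2^2) / 3
  }
  c(surface = surf, volume = vol)
}

oracle_planar_angle <- function(cell) {
  nodes <- as.data.frame(cell)
  root <- nodes$node_id[nodes$parent_id == -1]
  angs <- c()
  for (b in nodes$node_id) {
    if (b == root) next
    ch <- nodes[nodes$parent_id == b, ]
    if (nrow(ch) < 2) next
    p0 <- unlist(nodes[nodes$node_id == b, c("x", "y", "z")])
    pair_angles <- c()
    for (i in 1:(nrow(ch) - 1)) for (j in (i + 1):nrow(ch)) {
      v1 <- unlist(ch[i, c("x", "y", "z")]) - p0
      v2 <- unlist(ch[j, c("x", "y", "z")]) - p0
      ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      pair_angles <- c(pair_angles, acos(max(-1, min(1, ct))) * 180 / pi)
    }
    angs <- c(angs, mean(pair_angles))
  }
  if (length(angs) == 0) NA_real_ else mean(angs)
}

oracle_vertex <- function(cell) {
  segs <- oracle_segments(cell)
  va <- vb <- vc <- 0
  ends <- vapply(segs, function(s) s$nodes[length(s$nodes)], numeric(1))
  starts <- vapply(segs, function(s) s$nodes[1], numeric(1))
  for (i in seq_along(segs)) {
    if (segs[[i]]$terminal) next
    daughters <- which(starts == ends[i])
    t <- sum(vapply(segs[daughters], `[[`, logical(1), "terminal"))
    if (t >= 2) va <- va + 1
    else if (t == 1) vb <- vb + 1
    else vc <- vc + 1
  }
  c(va = va, vb = vb, vc = vc)
}

# --- brute-force convex hulls ----------------------------------------------

# O(n^3) 2-D hull: a directed pair (i, j) is a hull edge iff all other
# points lie strictly on its left (or on the segment)
oracle_hull2d <- function(xy) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  verts <- c()
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    rel <- (xy[, 1] - xy[i, 1]) * (xy[j, 2] - xy[i, 2]) -
      (xy[, 2] - xy[i, 2]) * (xy[j, 1] - xy[i, 1])
    if (all(rel <= 1e-12)) verts <- union(verts, c(i, j))
  }
  pts <- xy[verts, , drop = FALSE]
  ctr <- colMeans(pts)
  ord <- order(atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]))
  pts <- pts[ord, , drop = FALSE]
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  list(perimeter = sum(sqrt(rowSums((nxt - pts)^2))),
       area = abs(sum(pts[, 1] * nxt[, 2] - nxt[, 1] * pts[, 2]) / 2))
}

# O(n^4) 3-D hull: every point triple whose plane has all points on one
# side is a hull facet
oracle_hull3d <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  ctr <- colMeans(pts)
  surf <- 0
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    nv <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
            (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
            (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    if (sum(nv^2) < 1e-20) next
    s <- as.vector(pts %*% nv) - sum(nv * a)
    if (all(s <= 1e-9) || all(s >= -1e-9)) {
      tri_area <- sqrt(sum(nv^2)) / 2
      surf <- surf + tri_area
      # signed tetra volume against the centroid
      vol <- vol + abs(sum((a - ctr) *
        c((b[2] - ctr[2]) * (cc[3] - ctr[3]) - (b[3] - ctr[3]) * (cc[2] - ctr[2]),
          (b[3] - ctr[3]) * (cc[1] - ctr[1]) - (b[1] - ctr[1]) * (cc[3] - ctr[3]),
          (b[1] - ctr[1]) * (cc[2] - ctr[2]) - (b[2] - ctr[2]) * (cc[1] - ctr[1])))) / 6
    }
  }
  list(surface = surf, volume = vol)
}

# --- naive O(n^3) Ward agglomeration ---------------------------------------

# merge heights of minimum-variance clustering; height convention matches
# hclust ward.D2: sqrt(2 * increase in within-cluster SS)
oracle_ward_heights <- function(X) {
  cl <- as.list(seq_len(nrow(X)))
  hts <- c()
  while (length(cl) > 1) {
    best <- c(Inf, 0, 0)
    for (i in 1:(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      ci <- colMeans(X[cl[[i]], , drop = FALSE])
      cj <- colMeans(X[cl[[j]], , drop = FALSE])
      ni <- length(cl[[i]]); nj <- length(cl[[j]])
      d <- ni * nj / (ni + nj) * sum((ci - cj)^2)
      if (d < best[1]) best <- c(d, i, j)
    }
    hts <- c(hts, sqrt(2 * best[1]))
    cl[[best[2]]] <- c(cl[[best[2]]], cl[[best[3]]])
    cl[[best[3]]] <- NULL
  }
  hts
}

# --- misc -------------------------------------------------------------------

# rotation matrix about a random axis
random_rotation <- function(seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(9), 3, 3)
  qr.Q(qr(A)) * sign(det(qr.Q(qr(A))))
}

transform_cell <- function(cell, R = diag(3), shift = c(0, 0, 0),
                           scale = 1) {
  nodes <- as.data.frame(cell)
  P <- as.matrix(nodes[, c("x", "y", "z")]) %*% t(R) * scale
  nodes$x <- P[, 1] + shift[1]
  nodes$y <- P[, 2] + shift[2]
  nodes$z <- P[, 3] + shift[3]
  nodes$radius <- nodes$radius * scale
  cell_morphology(nodes, cell_id(cell))
}
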