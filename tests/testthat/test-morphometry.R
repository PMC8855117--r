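test_that("segment decomposition matches a recursive traversal oracle", {
  # single unbranched cable: one terminal order-1 segment
  d <- decompose(make_cable())
  expect_equal(nrow(d), 1L)
  expect_equal(d$order, 1L)
  expect_true(d$is_terminal)

  # one bifurcation: three segments, orders 1,2,2, one branch point
  d <- decompose(make_y_tree())
  expect_equal(sort(d$order), c(1L, 2L, 2L))
  expect_equal(attr(d, "n_branch_points"), 1L)
  expect_equal(attr(d, "primary_count"), 1L)

  for (seed in 1:25) {
    cell <- random_tree(seed)
    d <- decompose(cell)
    orc <- oracle_segments(cell)
    expect_equal(nrow(d), length(orc))
    # identical multisets of (node path, order, terminality)
    key <- function(nodes, order, term) {
      paste(paste(nodes, collapse = "-"), order, term)
    }
    got <- sort(mapply(key, d$nodes, d$order, d$is_terminal))
    want <- sort(vapply(orc, function(s) key(s$nodes, s$order, s$terminal),
                        character(1)))
    expect_identical(got, want)
  }
})

test_that("complexity follows its closed form", {
  # unbranched primary of length L: (1 + 1) * L
  expect_equal(cell_complexity(make_cable(length_um = 100)), 200)
  # 10 um primary + two 5 um terminals at orders 2,2:
  # (2+2+2) * (10 + 2*sqrt(50)) / 1 -- with the oracle lengths
  y <- make_y_tree()
  len <- oracle_total_length(y)
  expect_equal(cell_complexity(y), (4 + 2) * len)
  # m unbranched primaries of length L each -> 2 m L
  for (m in c(2, 3, 5)) {
    L <- 40
    nodes <- data.frame(node_id = 1L, parent_id = -1L, x = 0, y = 0, z = 0,
                        radius = 2)
    for (i in seq_len(m)) {
      id0 <- nrow(nodes)
      nodes <- rbind(nodes,
                     data.frame(node_id = id0 + 1L, parent_id = 1L,
                                x = L * cos(2 * pi * i / m),
                                y = L * sin(2 * pi * i / m), z = 0,
                                radius = 1))
    }
    cell <- cell_morphology(nodes, paste0("star", m))
    expect_equal(cell_complexity(cell), 2 * m * L, tolerance = 1e-12)
  }
  d <- decompose(make_cable())
  expect_equal(complexity(d, 100), 200)
})

test_that("path metrics agree with per-edge summation oracles", {
  pm <- path_metrics(make_cable(length_um = 100, n_nodes = 11))
  expect_equal(pm$total_branch_length, 100)
  expect_equal(pm$tortuosity, 1.0)
  expect_equal(pm$segments_per_mm, 1000 / 100)

  # semicircular arc: tortuosity -> pi/2
  th <- seq(0, pi, length.out = 200)
  arc <- data.frame(node_id = seq_along(th),
                    parent_id = c(-1, seq_along(th)[-length(th)]),
                    x = 50 * cos(th), y = 50 * sin(th), z = 0, radius = 1)
  pm <- path_metrics(cell_morphology(arc, "arc"))
  expect_equal(pm$tortuosity, pi / 2, tolerance = 1e-3)

  for (seed in 1:20) {
    cell <- random_tree(seed)
    expect_equal(path_metrics(cell)$total_branch_length,
                 oracle_total_length(cell), tolerance = 1e-9)
  }
})

test_that("frustum surface and volume match closed forms and the oracle", {
  # cylinder r = 1, h = 10
  cyl <- cell_morphology(data.frame(node_id = 1:2, parent_id = c(-1, 1),
                                    x = c(0, 10), y = 0, z = 0, radius = 1),
                         "cyl")
  fm <- frustum_metrics(cyl)
  expect_equal(fm$tree_surface_area, 2 * pi * 10, tolerance = 1e-12)
  expect_equal(fm$total_branch_volume, pi * 10, tolerance = 1e-12)

  # cone r 1 -> ~0 over h = 10 (soma edge rule bypassed via a stub node)
  cone <- cell_morphology(
    data.frame(node_id = 1:3, parent_id = c(-1, 1, 2),
               x = c(-1, 0, 10), y = 0, z = 0, radius = c(1, 1, 1e-9)),
    "cone")
  vol_cone <- frustum_metrics(cone)$total_branch_volume - pi * 1  # minus stub
  expect_equal(vol_cone, pi * 10 / 3, tolerance = 1e-6)

  for (seed in 1:20) {
    cell <- random_tree(seed)
    fm <- frustum_metrics(cell)
    orc <- oracle_frusta(cell)
    expect_equal(fm$tree_surface_area, unname(orc["surface"]),
                 tolerance = 1e-9)
    expect_equal(fm$total_branch_volume, unname(orc["volume"]),
                 tolerance = 1e-9)
    expect_equal(fm$branch_surface_area,
                 fm$tree_surface_area / attr(decompose(cell),
                                             "primary_count"))
  }
})

test_that("planar angle matches the arccos-of-dot-product oracle", {
  # daughters along +x and +y from the branch point: 90 degrees
  tree <- cell_morphology(
    data.frame(node_id = 1:4, parent_id = c(-1, 1, 2, 2),
               x = c(0, 0, 5, 0), y = c(-5, 0, 0, 5), z = 0, radius = 1),
    "t90")
  expect_equal(planar_angle(tree), 90)
  # +x and -x: 180 degrees
  tree <- cell_morphology(
    data.frame(node_id = 1:4, parent_id = c(-1, 1, 2, 2),
               x = c(0, 0, 5, -5), y = c(-5, 0, 0, 0), z = 0, radius = 1),
    "t180")
  expect_equal(planar_angle(tree), 180)
  # no bifurcation: NA, not zero
  expect_true(is.na(planar_angle(make_cable())))

  for (seed in 1:20) {
    cell <- random_tree(seed)
    expect_equal(planar_angle(cell), oracle_planar_angle(cell),
                 tolerance = 1e-9)
  }
})

test_that("vertex analysis classifies bifurcations by daughter terminality", {
  d <- decompose(make_y_tree())
  expect_equal(as.numeric(vertex_analysis(d)), c(1, 0, 0))

  # symmetric depth-2 binary tree: Va = 2, Vb = 0, Vc = 1
  nodes <- data.frame(
    node_id = 1:8,
    parent_id = c(-1, 1, 2, 2, 3, 3, 4, 4),
    x = c(0, 10, 20, 20, 30, 30, 30, 30),
    y = c(0, 0, 5, -5, 8, 2, -2, -8), z = 0, radius = 1)
  d <- decompose(cell_morphology(nodes, "b2"))
  expect_equal(as.numeric(vertex_analysis(d)), c(2, 0, 1))

  for (seed in 1:20) {
    cell <- random_tree(seed)
    v <- vertex_analysis(decompose(cell))
    orc <- oracle_vertex(cell)
    expect_equal(as.numeric(v), unname(orc))
    # binary trees: Va + Vb + Vc = branch points
    expect_equal(sum(as.numeric(v)),
                 attr(decompose(cell), "n_branch_points"))
  }
})

test_that("convex hull metrics match closed forms and brute-force hulls", {
  cube <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  h <- convex_hull_metrics(cube)
  expect_equal(h$hull_volume_3d, 1)
  expect_equal(h$hull_surface_area_3d, 6)
  expect_equal(h$hull_area_2d, 1)
  expect_equal(h$hull_perimeter_2d, 4)

  flat <- data.frame(x = runif(10), y = runif(10), z = 0)
  expect_warning(h <- convex_hull_metrics(flat), "degenerate")
  expect_equal(h$hull_volume_3d, 0)
  expect_true(h$degenerate_3d)

  for (seed in 1:4) {
    set.seed(seed)
    P <- matrix(rnorm(150), 50, 3)
    h <- suppressWarnings(convex_hull_metrics(P))
    o3 <- oracle_hull3d(P)
    o2 <- oracle_hull2d(P[, 1:2])
    expect_equal(h$hull_surface_area_3d, o3$surface, tolerance = 1e-9)
    expect_equal(h$hull_volume_3d, o3$volume, tolerance = 1e-9)
    expect_equal(h$hull_area_2d, o2$area, tolerance = 1e-9)
    expect_equal(h$hull_perimeter_2d, o2$perimeter, tolerance = 1e-9)
  }
})

test_that("box-counting dimension recovers line and plane exponents", {
  expect_equal(fractal_dimension(matrix(c(5, 5, 5), 1, 3)), 0)

  line <- make_cable(length_um = 1000, n_nodes = 21)
  expect_equal(fractal_dimension(line, scales = c(2, 4, 8, 16, 32, 64)),
               1.0, tolerance = 0.1)

  grid_pts <- as.matrix(expand.grid(x = seq(0, 100, 0.5),
                                    y = seq(0, 100, 0.5), z = 0))
  expect_equal(fractal_dimension(grid_pts, scales = c(2, 4, 8, 16, 32)),
               2.0, tolerance = 0.15)

  expect_error(fractal_dimension(line, scales = c(2, 4, 8)), "at least 4")
  expect_error(fractal_dimension(line, scales = c(2, 3, 4, 5)), "decade")
})

test_that("compute_features is self-consistent and well-behaved", {
  f <- compute_features(make_cable(length_um = 100))
  expect_equal(f$total_branch_length, 100)
  expect_equal(f$complexity, 200)
  expect_equal(f$n_segments, 1L)
  expect_equal(f$vertex_va + f$vertex_vb + f$vertex_vc, 0L)

  cells <- lapply(1:10, random_tree)
  fm <- compute_feature_matrix(cells)
  expect_equal(nrow(fm), 10L)
  size_cols <- c("total_branch_length", "branch_surface_area",
                 "total_branch_volume", "tree_surface_area",
                 "hull_perimeter_2d", "hull_area_2d",
                 "hull_surface_area_3d", "hull_volume_3d", "complexity")
  expect_false(any(is.na(fm[size_cols])))
  expect_true(all(fm[size_cols] >= 0))
  expect_true(all(fm$tortuosity >= 1, na.rm = TRUE))
  expect_true(all(fm$n_segments >= fm$n_branch_points))
  expect_true(all(fm$k_dim >= 0 & fm$k_dim <= 3))

  # field-by-field agreement with the individual operations
  for (cell in cells[1:5]) {
    f <- compute_features(cell)
    d <- decompose(cell)
    pm <- path_metrics(cell, d)
    expect_equal(f$total_branch_length, pm$total_branch_length)
    expect_equal(f$tortuosity, pm$tortuosity)
    expect_equal(f$complexity, complexity(d, pm$total_branch_length))
    expect_equal(f$planar_angle, planar_angle(cell))
    hull <- suppressWarnings(
      convex_hull_metrics(as.data.frame(cell)[, c("x", "y", "z")]))
    expect_equal(f$hull_volume_3d, hull$hull_volume_3d)
  }
})

test_that("features respect Euclidean and scaling symmetries", {
  ang <- 0.73
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3)
  exempt <- c("cell_id", "species", "individual", "k_dim")
  for (seed in c(2, 5)) {
    cell <- random_tree(seed)
    f0 <- compute_features(cell)

    # in-plane rigid motion: every feature invariant (box counting on a
    # rotated grid only approximately so)
    f1 <- compute_features(transform_cell(cell, R = Rz,
                                          shift = c(12, -7, 30)))
    for (cl in setdiff(names(f0), exempt)) {
      expect_equal(f1[[cl]], f0[[cl]], tolerance = 1e-6, label = cl)
    }
    expect_equal(f1$k_dim, f0$k_dim, tolerance = 0.1)

    # uniform scaling by s
    s <- 2.5
    f2 <- compute_features(transform_cell(cell, scale = s))
    expect_equal(f2$total_branch_length, s * f0$total_branch_length,
                 tolerance = 1e-6)
    expect_equal(f2$complexity, s * f0$complexity, tolerance = 1e-6)
    expect_equal(f2$tree_surface_area, s^2 * f0$tree_surface_area,
                 tolerance = 1e-6)
    expect_equal(f2$hull_area_2d, s^2 * f0$hull_area_2d, tolerance = 1e-6)
    expect_equal(f2$total_branch_volume, s^3 * f0$total_branch_volume,
                 tolerance = 1e-6)
    expect_equal(f2$hull_volume_3d, s^3 * f0$hull_volume_3d,
                 tolerance = 1e-6)
    expect_equal(f2$n_segments, f0$n_segments)
    expect_equal(f2$tortuosity, f0$tortuosity, tolerance = 1e-6)
    expect_equal(f2$planar_angle, f0$planar_angle, tolerance = 1e-6)
    expect_equal(f2$k_dim, f0$k_dim, tolerance = 1e-6)
    expect_equal(f2$segments_per_mm, f0$segments_per_mm / s,
                 tolerance = 1e-6)
  }

  # complexity strictly increases with total length at fixed topology
  lens <- c(50, 80, 120, 200)
  cx <- vapply(lens, function(L) cell_complexity(make_cable(length_um = L)),
               numeric(1))
  expect_true(all(diff(cx) > 0))
})
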