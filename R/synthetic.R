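#' Specification of a synthetic astrocyte morphology class
#'
#' Parameters of the stochastic binary-branching growth model used to
#' emulate a morphotype: primaries leave the soma in random directions and
#' each segment, drawn as a wiggly polyline, ends in a bifurcation with
#' probability `branch_prob` until `max_order` is reached.  The model is
#' deliberately simple (closed-form expected segment counts) rather than
#' biophysically realistic.
#'
#' @param class_id Label of the class.
#' @param n_primary Number of primary branches (rounded to an integer,
#'   minimum 1).
#' @param branch_prob Per-segment bifurcation probability in `[0, 1]`.
#' @param max_order Maximum centrifugal order.
#' @param segment_length Length-2 vector: mean and SD of segment length
#'   (micrometres).
#' @param wiggle SD of the per-step direction noise (radians).
#' @param base_radius Radius of primary branches at their base
#'   (micrometres).
#' @param taper Per-order radius ratio in `(0, 1]`.
#' @return A list of class `morph_class_spec`.
#' @export
morph_class_spec <- function(class_id, n_primary = 5, branch_prob = 0.5,
                             max_order = 4, segment_length = c(40, 8),
                             wiggle = 0.25, base_radius = 1.2,
                             taper = 0.8) {
  stopifnot(branch_prob >= 0, branch_prob <= 1, max_order >= 1,
            segment_length[1] > 0, segment_length[2] >= 0,
            taper > 0, taper <= 1, base_radius > 0, wiggle >= 0)
  if (n_primary < 1) stop("spec must yield at least one primary",
                          call. = FALSE)
  structure(list(class_id = as.character(class_id), n_primary = n_primary,
                 branch_prob = branch_prob, max_order = max_order,
                 segment_length = segment_length, wiggle = wiggle,
                 base_radius = base_radius, taper = taper),
            class = "morph_class_spec")
}

#' Default morphotype class specs
#'
#' Three (or four) classes graded in bifurcation probability, branch
#' extent and order depth so that the pooled population is multimodal in
#' both complexity and convex-hull volume — the structure the morphotype
#' screen assumes.
#'
#' @param n_classes 3 (default) or 4.
#' @return A list of [morph_class_spec()] objects.
#' @export
default_morph_classes <- function(n_classes = 3) {
  specs <- list(
    morph_class_spec("type3", n_primary = 8, branch_prob = 0.2,
                     max_order = 3, segment_length = c(15, 1.5),
                     wiggle = 0.18, base_radius = 1.0, taper = 0.85),
    morph_class_spec("type2", n_primary = 12, branch_prob = 0.5,
                     max_order = 4, segment_length = c(46, 4.6),
                     wiggle = 0.18, base_radius = 1.2, taper = 0.85),
    morph_class_spec("type1", n_primary = 9, branch_prob = 0.8,
                     max_order = 5, segment_length = c(95, 9.5),
                     wiggle = 0.18, base_radius = 1.4, taper = 0.85),
    morph_class_spec("type0", n_primary = 9, branch_prob = 0.95,
                     max_order = 6, segment_length = c(220, 22),
                     wiggle = 0.18, base_radius = 1.6, taper = 0.85))
  if (!n_classes %in% c(2, 3, 4)) stop("n_classes must be 2, 3 or 4",
                                       call. = FALSE)
  specs[seq_len(n_classes)]
}

# deterministic child-seed derivation (documented stream splitting):
# a Lehmer step keeps every derived seed in [1, 2^31 - 2]
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index) %% 2147483647)
}

#' Generate one synthetic astrocyte
#'
#' Recursive stochastic growth under a [morph_class_spec()]: primaries
#' start at the soma in uniformly random directions; each segment is a
#' 5-step polyline whose direction performs a small random walk
#' (`wiggle`), and bifurcates with probability `branch_prob` while below
#' `max_order`, daughters diverging symmetrically.  The same seed
#' reproduces the identical cell.
#'
#' @param spec A [morph_class_spec()].
#' @param seed Integer seed.
#' @param cell_id Identifier, default derived from the seed.
#' @param species,individual Optional labels.
#' @return A valid [cell_morphology()].
#' @export
generate_astrocyte <- function(spec, seed, cell_id = NULL,
                               species = NA_character_,
                               individual = NA_character_) {
  stopifnot(inherits(spec, "morph_class_spec"))
  set.seed(seed)
  if (is.null(cell_id)) cell_id <- sprintf("%s_seed%d", spec$class_id, seed)

  n_prim <- max(1L, as.integer(round(spec$n_primary)))
  steps_per_segment <- 4L
  # cell-to-cell calibre variability (~15% lognormal), as in real material
  cell_radius <- spec$base_radius * exp(stats::rnorm(1, 0, 0.15))

  nid <- 1L
  rows <- list(list(1L, -1L, 0, 0, 0, max(cell_radius * 2, 3), 1L))
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  perturb <- function(dir, angle_sd) {
    v <- dir + stats::rnorm(3, sd = angle_sd)
    v / sqrt(sum(v^2))
  }
  # stack entries: parent node id, position, direction, order
  stack <- lapply(seq_len(n_prim), function(i) {
    list(parent = 1L, pos = c(0, 0, 0), dir = rand_dir(), order = 1L)
  })
  while (length(stack) > 0) {
    it <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    seg_len <- max(spec$segment_length[1] / 4,
                   stats::rnorm(1, spec$segment_length[1],
                                spec$segment_length[2]))
    step <- seg_len / steps_per_segment
    radius <- cell_radius * spec$taper^(it$order - 1L)
    pos <- it$pos
    dir <- it$dir
    parent <- it$parent
    for (s in seq_len(steps_per_segment)) {
      dir <- perturb(dir, spec$wiggle)
      pos <- pos + dir * step
      nid <- nid + 1L
      rows[[length(rows) + 1]] <- list(nid, parent, pos[1], pos[2], pos[3],
                                       radius, 7L)
      parent <- nid
    }
    if (it$order < spec$max_order &&
        stats::runif(1) < spec$branch_prob) {
      for (k in 1:2) {
        stack[[length(stack) + 1]] <- list(
          parent = parent, pos = pos,
          dir = perturb(dir, spec$wiggle + 0.35),
          order = it$order + 1L)
      }
    }
  }
  m <- do.call(rbind, lapply(rows, function(r) unlist(r)))
  nodes <- tibble::tibble(node_id = as.integer(m[, 1]),
                          parent_id = as.integer(m[, 2]),
                          x = m[, 3], y = m[, 4], z = m[, 5],
                          radius = m[, 6], type_tag = as.integer(m[, 7]))
  cell_morphology(nodes, cell_id = cell_id, species = species,
                  individual = individual)
}

#' Generate a labelled multi-class astrocyte population
#'
#' @param classes List of [morph_class_spec()]s (default
#'   [default_morph_classes()]).
#' @param n_per_class Cells per class, default 40.
#' @param species Character vector of species labels cycled over the
#'   cells of every class (so several species cross each morphology
#'   class); default `"synthetic"`.
#' @param seed Root seed; per-cell seeds are derived deterministically.
#' @return A list of class `synthetic_population`: `cells` (list of
#'   `cell_morphology`), `labels` (tibble `cell_id`, `true_class`,
#'   `species`, `individual`), `seed`.
#' @export
generate_population <- function(classes = default_morph_classes(),
                                n_per_class = 40, species = "synthetic",
                                seed = 1) {
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  cells <- list()
  labels <- list()
  idx <- 0L
  for (ci in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      cid <- sprintf("cell%04d", idx)
      sp <- species[(j - 1L) %% length(species) + 1L]
      cell <- generate_astrocyte(classes[[ci]],
                                 seed = derive_seed(seed, idx),
                                 cell_id = cid, species = sp,
                                 individual = sprintf("%s_ind%d", sp,
                                                      (j - 1L) %% 5L + 1L))
      cells[[idx]] <- cell
      labels[[idx]] <- tibble::tibble(
        cell_id = cid, true_class = classes[[ci]]$class_id,
        species = sp,
        individual = attr(cell, "individual"))
    }
  }
  structure(list(cells = cells, labels = dplyr::bind_rows(labels),
                 seed = seed),
            class = "synthetic_population")
}

#' Generate a synthetic section contour with somata
#'
#' Somata are placed as a homogeneous Poisson process over a rectangular
#' region; the contour is the region's boundary polygon.
#'
#' @param region Length-4 numeric `c(xmin, xmax, ymin, ymax)` in
#'   micrometres.
#' @param soma_density Somata per square millimetre (> 0).
#' @param seed Integer seed.
#' @return A list: `contour` (tibble `x`, `y`), `somata` (tibble
#'   `cell_id`, `x`, `y`), `seed`.
#' @export
generate_section <- function(region = c(0, 2000, 0, 2000),
                             soma_density = 100, seed = 1) {
  stopifnot(length(region) == 4, soma_density > 0)
  w <- region[2] - region[1]
  h <- region[4] - region[3]
  if (w <= 0 || h <= 0) stop("zero-area region", call. = FALSE)
  set.seed(seed)
  area_mm2 <- w * h / 1e6
  n <- stats::rpois(1, soma_density * area_mm2)
  somata <- tibble::tibble(
    cell_id = sprintf("soma%05d", seq_len(n)),
    x = stats::runif(n, region[1], region[2]),
    y = stats::runif(n, region[3], region[4]))
  contour <- tibble::tibble(
    x = c(region[1], region[2], region[2], region[1]),
    y = c(region[3], region[3], region[4], region[4]))
  list(contour = contour, somata = somata, seed = seed)
}

#' Specification of synthetic microsatellite genotypes
#'
#' Per species: an allele ladder (2-bp steps, dinucleotide), a mean and SD
#' of allele size (bp) and a sample size, plus the species' migratory
#' distance.  The default emulates four shorebird species whose mean
#' allele size increases with migratory distance in 4-bp steps (SD 2 bp,
#' 13 individuals per species); `flat = TRUE` gives all species the same
#' mean (the no-association control).
#'
#' @param flat If `TRUE`, all species share the same mean allele size.
#' @param ladder Allele ladder in bp, default `seq(168, 204, 2)`.
#' @param sd_bp Within-species allele-size SD, default 2.
#' @param n_ind Individuals per species, default 13.
#' @return A tibble of class `genotype_spec` with columns `species`,
#'   `mean_bp`, `sd_bp`, `n`, `distance_km`; attribute `ladder`.
#' @export
genotype_spec <- function(flat = FALSE, ladder = seq(168, 204, 2),
                          sd_bp = 2, n_ind = 13) {
  if (any(diff(ladder) != 2)) {
    stop("allele ladder must have 2-bp steps", call. = FALSE)
  }
  dmap <- shorebird_distances()
  dmap <- dmap[order(dmap$distance_km), ]
  means <- if (flat) rep(178, nrow(dmap)) else 172 + 4 * (seq_len(nrow(dmap)) - 1)
  out <- tibble::tibble(species = dmap$species, mean_bp = means,
                        sd_bp = sd_bp, n = n_ind,
                        distance_km = dmap$distance_km)
  structure(out, class = c("genotype_spec", class(tibble::tibble())),
            ladder = ladder)
}

#' Generate a synthetic genotype table
#'
#' For each individual the two alleles are drawn independently (so the
#' population is in Hardy-Weinberg proportions by construction) from a
#' normal distribution with the species' mean and SD, rounded to the 2-bp
#' ladder and clamped to its bounds.
#'
#' @param spec A [genotype_spec()].
#' @param seed Integer seed.
#' @return A [genotype_table()].
#' @export
generate_genotypes <- function(spec = genotype_spec(), seed = 1) {
  stopifnot(inherits(spec, "genotype_spec"))
  ladder <- attr(spec, "ladder", exact = TRUE)
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    n <- spec$n[i]
    draw <- function() {
      x <- stats::rnorm(n, spec$mean_bp[i], spec$sd_bp[i])
      x <- 2 * round(x / 2)
      pmin(max(ladder), pmax(min(ladder), x))
    }
    tibble::tibble(
      individual = sprintf("%s_%02d", spec$species[i], seq_len(n)),
      species = spec$species[i],
      allele1 = draw(), allele2 = draw())
  })
  genotype_table(rows)
}
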