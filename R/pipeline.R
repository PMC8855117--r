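#' Build a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis with the study defaults:
#' z shrinkage 1.75, MMI threshold 0.55, cluster range 2..6, 9999
#' permutations, alpha 0.05.  Either point `swc_dir`/`metadata` (and
#' optionally `genotypes`/`distances`) at real data, or leave them `NULL`
#' to run on synthetic data generated from `synthetic` specs.
#'
#' @param swc_dir Directory of SWC files, or `NULL` for synthetic input.
#' @param metadata Path to the cell metadata CSV
#'   (`cell_id,species,individual,region,soma_x,soma_y`), or `NULL`.
#' @param genotypes Path to the genotype CSV, or `NULL` for synthetic.
#' @param distances Path to a species,distance_km CSV, or `NULL` for the
#'   built-in shorebird map.
#' @param synthetic List with optional entries `n_classes`, `n_per_class`,
#'   `flat_genotypes` controlling the synthetic generators.
#' @param z_factor Z shrinkage correction, default 1.75.
#' @param mmi_threshold MMI screen threshold, default 0.55.
#' @param k_range Candidate morphotype counts, default 2:6.
#' @param n_perm Permutations for all tests, default 9999.
#' @param alpha Significance level, default 0.05.
#' @param seed Root seed, default 1.
#' @param out_dir Output directory, default `"astromorph-output"`.
#' @param run_genetics Include the genotype/association stage, default
#'   `TRUE`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(swc_dir = NULL, metadata = NULL,
                            genotypes = NULL, distances = NULL,
                            synthetic = list(), z_factor = 1.75,
                            mmi_threshold = 0.55, k_range = 2:6,
                            n_perm = 9999, alpha = 0.05, seed = 1,
                            out_dir = "astromorph-output",
                            run_genetics = TRUE) {
  stopifnot(z_factor > 0, mmi_threshold > 0, n_perm >= 1,
            alpha > 0, alpha < 1, all(k_range >= 2))
  syn_defaults <- list(n_classes = 3, n_per_class = 40,
                       flat_genotypes = FALSE)
  synthetic <- utils::modifyList(syn_defaults, synthetic)
  if (!is.null(swc_dir) && is.null(metadata)) {
    stop("config error: 'metadata' is required when 'swc_dir' is set",
         call. = FALSE)
  }
  structure(list(swc_dir = swc_dir, metadata = metadata,
                 genotypes = genotypes, distances = distances,
                 synthetic = synthetic, z_factor = z_factor,
                 mmi_threshold = mmi_threshold, k_range = k_range,
                 n_perm = n_perm, alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir, run_genetics = run_genetics),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file whose keys
#'   match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("config error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$k_range) && length(raw$k_range) == 2) {
    raw$k_range <- seq(raw$k_range[1], raw$k_range[2])
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: morphology input (read or simulate cells; z
#' shrinkage correction for file input), feature computation, MMI screen +
#' variance-shrunk log transform, Ward clustering with discriminant
#' validation, representative cells and density peaks, two-factor
#' PERMANOVA/PERMDISP on the Euclidean distance matrix, and (optionally)
#' the genetics stage (diversity, HWE, FST/RST, distance association,
#' allele-size PERMANOVA).  All tables are written under
#' `config$out_dir`; rerunning with the same config and seed reproduces
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  config_hash <- digest::digest(cfg_for_hash, algo = "sha256")

  # ---- stage 1: morphology input -----------------------------------------
  if (!is.null(config$swc_dir)) {
    meta <- readr::read_csv(config$metadata, show_col_types = FALSE)
    files <- list.files(config$swc_dir, pattern = "\\.swc$",
                        full.names = TRUE)
    if (length(files) == 0) stop("stage morphology: no SWC files in ",
                                 config$swc_dir, call. = FALSE)
    cells <- lapply(files, function(f) {
      cell <- read_swc(f)
      row <- meta[meta$cell_id == cell_id(cell), ]
      if (nrow(row) == 1) {
        attr(cell, "species") <- as.character(row$species)
        attr(cell, "individual") <- as.character(row$individual)
      }
      correct_z_shrinkage(cell, config$z_factor)
    })
    true_labels <- NULL
  } else {
    pop <- generate_population(
      classes = default_morph_classes(config$synthetic$n_classes),
      n_per_class = config$synthetic$n_per_class,
      species = shorebird_distances()$species,
      seed = derive_seed(seed, 1L))
    cells <- pop$cells
    true_labels <- pop$labels
  }

  # ---- stage 2: features --------------------------------------------------
  features <- compute_feature_matrix(cells)
  readr::write_csv(features, file.path(config$out_dir, "features.csv"))

  # ---- stage 3: screen + transform ---------------------------------------
  mmi_tbl <- feature_mmi(features)
  selected <- select_features(features, threshold = config$mmi_threshold)
  transformed <- shrink_log_transform(features, feature_cols = selected)
  readr::write_csv(mmi_tbl, file.path(config$out_dir, "mmi.csv"))

  # ---- stage 4: morphotypes ----------------------------------------------
  cluster <- ward_cluster(transformed, k_range = config$k_range,
                          feature_cols = selected)
  disc <- discriminant_validation(transformed, cluster,
                                  alpha = config$alpha,
                                  feature_cols = selected)
  reps <- representative_cell(transformed, cluster,
                              feature_cols = selected)
  cluster$representatives <- reps
  peaks <- kernel_density_peaks(log10(features$complexity + 1))
  readr::write_csv(cluster$labels,
                   file.path(config$out_dir, "morphotypes.csv"))

  # ---- stage 5: permutation stats ----------------------------------------
  dmat <- assemble_distance_matrix(features, feature_cols = selected)
  design <- data.frame(species = features$species,
                       type = cluster$labels$morphotype)
  multi_species <- length(unique(design$species)) >= 2L
  pa <- permanova(dmat,
                  design[, if (multi_species) c("species", "type") else
                    "type", drop = FALSE],
                  n_perm = config$n_perm,
                  seed = derive_seed(seed, 2L), scheme = "residual")
  pd <- permdisp(dmat,
                 if (multi_species) {
                   interaction(design$species, design$type)
                 } else factor(design$type),
                 n_perm = config$n_perm, seed = derive_seed(seed, 3L))
  pt <- pairwise_pseudo_t(dmat, design$type, n_perm = config$n_perm,
                          seed = derive_seed(seed, 4L))
  glm_ph <- univariate_glm_posthoc(log10(features$complexity + 1),
                                   design$type)
  readr::write_csv(tibble::as_tibble(pa),
                   file.path(config$out_dir, "permanova.csv"))
  readr::write_csv(pt, file.path(config$out_dir, "pairwise_pseudo_t.csv"))

  # ---- stage 6: genetics --------------------------------------------------
  genetics <- NULL
  if (isTRUE(config$run_genetics)) {
    gt <- if (!is.null(config$genotypes)) {
      read_genotypes(config$genotypes)
    } else {
      generate_genotypes(
        genotype_spec(flat = isTRUE(config$synthetic$flat_genotypes)),
        seed = derive_seed(seed, 5L))
    }
    dmap <- if (!is.null(config$distances)) {
      readr::read_csv(config$distances, show_col_types = FALSE)
    } else {
      shorebird_distances()
    }
    div <- allele_summary(gt)
    hwe <- hwe_test(gt, n_perm = min(config$n_perm, 999),
                    seed = derive_seed(seed, 6L))
    diff <- fst_rst(gt, n_perm = min(config$n_perm, 999),
                    seed = derive_seed(seed, 7L))
    assoc <- distance_association(gt, dmap, n_perm = config$n_perm,
                                  seed = derive_seed(seed, 8L))
    sizes <- allele_size_group_comparison(gt, n_perm = config$n_perm,
                                          seed = derive_seed(seed, 9L))
    readr::write_csv(div, file.path(config$out_dir, "diversity.csv"))
    readr::write_csv(diff$pairwise,
                     file.path(config$out_dir, "differentiation.csv"))
    genetics <- list(diversity = div, hwe = hwe,
                     differentiation = diff$pairwise,
                     association = list(rho = assoc$rho,
                                        p_rho = assoc$p_rho,
                                        regression_R = assoc$regression_R),
                     allele_size_permanova =
                       tibble::as_tibble(sizes$overall))
  }

  report <- list(
    provenance = list(package_version =
                        as.character(utils::packageVersion("astromorph")),
                      config_hash = config_hash, seed = seed,
                      n_perm = config$n_perm),
    n_cells = length(cells),
    features_computed = ncol(features) - 3L,
    mmi = mmi_tbl,
    selected_features = selected,
    k = cluster$k,
    morphotype_counts = as.list(table(cluster$labels$morphotype)),
    discriminant = list(
      entered = disc$entered$feature,
      eigenvalues = disc$eigenvalues,
      pct_variance = disc$pct_variance,
      wilks = disc$wilks,
      accuracy_pct = disc$accuracy_pct),
    representatives = reps,
    density_peaks = list(n_peaks = peaks$n_peaks,
                         locations = peaks$peak_locations),
    permanova = tibble::as_tibble(pa),
    permdisp = pd$overall,
    pairwise_pseudo_t = pt,
    glm_posthoc = list(anova = glm_ph$anova, pairwise = glm_ph$pairwise),
    genetics = genetics,
    true_labels_available = !is.null(true_labels))
  if (!is.null(true_labels)) {
    report$ari <- adjusted_rand_index(true_labels$true_class,
                                      cluster$labels$morphotype)
  }
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
  writeLines(json, file.path(config$out_dir, "report.json"))
  structure(c(report, list(cluster = cluster, discriminant_fit = disc,
                           config = config)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", x$n_cells, "cells; k =", x$k, "morphotypes;",
      "selected:", paste(x$selected_features, collapse = ", "), "\n")
  cat(sprintf("  discriminant accuracy %.1f%%; density peaks: %d\n",
              x$discriminant$accuracy_pct, x$density_peaks$n_peaks))
  if (!is.null(x$genetics)) {
    cat(sprintf("  allele size ~ distance: rho = %.3f (p = %.4g)\n",
                x$genetics$association$rho, x$genetics$association$p_rho))
  }
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 the expectation under independence.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  e1 <- sum_comb(rowSums(tab))
  e2 <- sum_comb(colSums(tab))
  expected <- e1 * e2 / choose(n, 2)
  maxidx <- (e1 + e2) / 2
  if (maxidx == expected) return(1)
  (idx - expected) / (maxidx - expected)
}
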