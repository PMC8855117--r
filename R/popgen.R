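#' Construct/validate a diploid microsatellite genotype table
#'
#' One row per individual: `individual`, `species`, `allele1`, `allele2`
#' (allele sizes in base pairs).  For a dinucleotide locus allele sizes
#' should differ by multiples of 2 bp; off-ladder spacing triggers a
#' warning, not an error.
#'
#' @param x A data frame with the four columns above.
#' @return A tibble of class `genotype_table`.
#' @export
genotype_table <- function(x) {
  g <- tibble::as_tibble(x)
  req <- c("individual", "species", "allele1", "allele2")
  missing <- setdiff(req, names(g))
  if (length(missing) > 0) {
    stop("genotype table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(g$allele1) || anyNA(g$allele2)) {
    stop("both alleles must be present for every individual", call. = FALSE)
  }
  if (any(g$allele1 <= 0) || any(g$allele2 <= 0)) {
    stop("allele sizes must be positive", call. = FALSE)
  }
  sizes <- sort(unique(c(g$allele1, g$allele2)))
  if (length(sizes) > 1 && any(diff(sizes) %% 2 != 0)) {
    warning("allele sizes are not on a 2-bp (dinucleotide) ladder",
            call. = FALSE)
  }
  class(g) <- c("genotype_table", class(tibble::tibble()))
  g
}

#' Read a genotype table from CSV
#'
#' Expects columns `individual`, `species`, `allele1`, `allele2` (aliases
#' `allele1_bp`/`allele2_bp` accepted).
#'
#' @param path CSV path.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE)
  names(g) <- sub("_bp$", "", names(g))
  genotype_table(g)
}

#' Read genotypes in GenePop format
#'
#' Minimal reader for the GenePop text format with a single locus:
#' title line, locus name(s), `Pop` separators, and per-individual lines
#' `name , 172174` (2- or 3-digit allele codes, taken directly as allele
#' sizes in bp).  Each `Pop` block becomes a species named after its first
#' individual's label prefix (text before an underscore) or `pop<i>`.
#'
#' @param path GenePop file path.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  if (length(lines) < 3) stop("not a GenePop file: too short", call. = FALSE)
  pop_idx <- which(toupper(lines) == "POP")
  if (length(pop_idx) == 0) stop("no 'Pop' separator found", call. = FALSE)
  rows <- list()
  for (b in seq_along(pop_idx)) {
    from <- pop_idx[b] + 1L
    to <- if (b < length(pop_idx)) pop_idx[b + 1L] - 1L else length(lines)
    block <- lines[seq(from, to)]
    for (ln in block) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) != 2) {
        stop("malformed GenePop genotype line: ", ln, call. = FALSE)
      }
      name <- trimws(parts[1])
      code <- gsub("[[:space:]]", "", parts[2])
      w <- nchar(code) / 2
      if (!w %in% c(2, 3)) {
        stop("allele code must be 4 or 6 digits: ", ln, call. = FALSE)
      }
      a1 <- as.integer(substr(code, 1, w))
      a2 <- as.integer(substr(code, w + 1, 2 * w))
      sp <- sub("_.*$", "", name)
      if (sp == name) sp <- paste0("pop", b)
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = name, species = sp, allele1 = a1, allele2 = a2)
    }
  }
  genotype_table(dplyr::bind_rows(rows))
}

#' Species-to-migratory-distance map for the four study shorebirds
#'
#' Distances flown between the North-American breeding grounds and the
#' South-American wintering site: *Charadrius semipalmatus* 8039 km,
#' *Calidris pusilla* 9309 km, *Actitis macularius* 13139 km, and 0 km for
#' the resident *Charadrius collaris*.
#'
#' @return A tibble with columns `species`, `distance_km`.
#' @export
shorebird_distances <- function() {
  tibble::tibble(
    species = c("C_collaris", "C_semipalmatus", "C_pusilla", "A_macularius"),
    distance_km = c(0, 8039, 9309, 13139))
}

# long format: one row per gene copy
gene_copies <- function(g) {
  tibble::tibble(
    individual = rep(g$individual, 2L),
    species = rep(g$species, 2L),
    allele = c(g$allele1, g$allele2))
}

#' Per-species microsatellite diversity summary
#'
#' For each species: sample size `n`, allele count `A`, number of private
#' alleles (found in no other species), observed heterozygosity `Ho`
#' (fraction of heterozygous individuals) and unbiased expected
#' heterozygosity `He = (2n/(2n-1)) (1 - sum p_i^2)` over the `2n` gene
#' copies.
#'
#' @param g A [genotype_table()].
#' @return A tibble of class `diversity_summary` with columns `species`,
#'   `n`, `A`, `private_alleles`, `Ho`, `He`.
#' @export
allele_summary <- function(g) {
  g <- genotype_table(g)
  gc <- gene_copies(g)
  by_allele <- unique(gc[, c("species", "allele")])
  out <- purrr::map_dfr(unique(g$species), function(sp) {
    sub <- g[g$species == sp, ]
    copies <- c(sub$allele1, sub$allele2)
    p <- table(copies) / length(copies)
    two_n <- length(copies)
    he <- if (two_n > 1) (two_n / (two_n - 1)) * (1 - sum(p^2)) else 0
    own <- unique(copies)
    others <- by_allele$allele[by_allele$species != sp]
    tibble::tibble(
      species = sp, n = nrow(sub), A = length(own),
      private_alleles = sum(!own %in% others),
      Ho = mean(sub$allele1 != sub$allele2),
      He = he)
  })
  class(out) <- c("diversity_summary", class(tibble::tibble()))
  out
}

#' Hardy-Weinberg equilibrium test by gene-copy re-pairing
#'
#' Monte-Carlo exact test per species: the observed heterozygote count is
#' compared with the distribution obtained by randomly re-pairing the
#' observed gene copies into diploid genotypes.  The two-sided p-value
#' uses the distance of the heterozygote count from its re-pairing
#' expectation, with the mid-p correction for the discreteness of the
#' count (half weight on ties), so both heterozygote deficit and excess
#' are detected and the null distribution of p is close to uniform.
#' Monomorphic species return `p = 1`.
#'
#' @param g A [genotype_table()].
#' @param n_perm Number of re-pairings, default 999.
#' @param seed Integer seed.
#' @return A tibble with columns `species`, `n`, `het_obs`, `het_expected`,
#'   `p`.
#' @export
hwe_test <- function(g, n_perm = 999, seed = NULL) {
  g <- genotype_table(g)
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(unique(g$species), function(sp) {
    sub <- g[g$species == sp, ]
    copies <- c(sub$allele1, sub$allele2)
    n_ind <- nrow(sub)
    het_obs <- sum(sub$allele1 != sub$allele2)
    if (length(unique(copies)) == 1L) {
      return(tibble::tibble(species = sp, n = n_ind, het_obs = het_obs,
                            het_expected = 0, p = 1))
    }
    het_perm <- replicate(n_perm, {
      s <- sample(copies)
      sum(s[seq_len(n_ind)] != s[n_ind + seq_len(n_ind)])
    })
    e <- mean(het_perm)
    d_obs <- abs(het_obs - e)
    d_perm <- abs(het_perm - e)
    p <- (sum(d_perm > d_obs) + 0.5 * sum(d_perm == d_obs) + 1) /
      (n_perm + 1)
    tibble::tibble(species = sp, n = n_ind, het_obs = het_obs,
                   het_expected = e, p = min(1, p))
  })
}

# Weir & Cockerham (1984) theta over the alleles of a set of populations.
# g: genotype_table restricted to the populations of interest.
wc_theta <- function(g) {
  pops <- unique(g$species)
  r <- length(pops)
  alleles <- sort(unique(c(g$allele1, g$allele2)))
  n_i <- vapply(pops, function(sp) sum(g$species == sp), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  num <- den <- 0
  for (a in alleles) {
    p_i <- vapply(pops, function(sp) {
      sub <- g[g$species == sp, ]
      mean(c(sub$allele1, sub$allele2) == a)
    }, numeric(1))
    h_i <- vapply(pops, function(sp) {
      sub <- g[g$species == sp, ]
      mean((sub$allele1 == a) != (sub$allele2 == a))
    }, numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a_c <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b_c <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    c_c <- hbar / 2
    num <- num + a_c
    den <- den + a_c + b_c + c_c
  }
  if (den == 0) return(NA_real_)
  num / den
}

# size-based RST via one-way ANOVA variance components on gene copies
rst_stat <- function(g) {
  gc <- gene_copies(g)
  y <- gc$allele
  grp <- factor(gc$species)
  r <- nlevels(grp)
  ns <- as.numeric(table(grp))
  N <- length(y)
  means <- tapply(y, grp, mean)
  ssb <- sum(ns * (means - mean(y))^2)
  ssw <- sum((y - means[grp])^2)
  msb <- ssb / (r - 1)
  msw <- ssw / (N - r)
  n0 <- (N - sum(ns^2) / N) / (r - 1)
  s_a <- (msb - msw) / n0
  if (s_a + msw == 0) return(NA_real_)
  s_a / (s_a + msw)
}

#' Pairwise FST and RST differentiation with permutation p-values
#'
#' FST is Weir & Cockerham's theta computed from allele-identity variance
#' components; RST is its allele-size analogue (among-population variance
#' of microsatellite size over total).  For each species pair the p-value
#' comes from permuting individuals between the two populations.  A pair
#' whose pooled sample is monomorphic yields `NA` statistics.
#'
#' @param g A [genotype_table()].
#' @param n_perm Number of permutations per pair, default 999.
#' @param seed Integer seed.
#' @return A list of class `differentiation_matrix`: `pairwise` (tibble
#'   `species1`, `species2`, `fst`, `p_fst`, `rst`, `p_rst`), `fst` and
#'   `rst` (symmetric matrices, zero diagonal).
#' @export
fst_rst <- function(g, n_perm = 999, seed = NULL) {
  g <- genotype_table(g)
  pops <- unique(g$species)
  if (length(pops) < 2L) stop("need at least 2 species", call. = FALSE)
  if (any(table(g$species) < 2L)) {
    stop("need at least 2 individuals per species", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  prs <- utils::combn(pops, 2)
  rows <- purrr::map_dfr(seq_len(ncol(prs)), function(j) {
    sub <- g[g$species %in% prs[, j], ]
    mono <- length(unique(c(sub$allele1, sub$allele2))) == 1L
    if (mono) {
      return(tibble::tibble(species1 = prs[1, j], species2 = prs[2, j],
                            fst = NA_real_, p_fst = NA_real_,
                            rst = NA_real_, p_rst = NA_real_))
    }
    fst_obs <- wc_theta(sub)
    rst_obs <- rst_stat(sub)
    labs <- sub$species
    perm <- replicate(n_perm, {
      sub$species <- sample(labs)
      c(wc_theta(sub), rst_stat(sub))
    })
    p_fst <- (sum(perm[1, ] >= fst_obs, na.rm = TRUE) + 1) / (n_perm + 1)
    p_rst <- (sum(perm[2, ] >= rst_obs, na.rm = TRUE) + 1) / (n_perm + 1)
    tibble::tibble(species1 = prs[1, j], species2 = prs[2, j],
                   fst = fst_obs, p_fst = p_fst, rst = rst_obs,
                   p_rst = p_rst)
  })
  mk <- function(col) {
    m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_len(nrow(rows))) {
      m[rows$species1[i], rows$species2[i]] <- rows[[col]][i]
      m[rows$species2[i], rows$species1[i]] <- rows[[col]][i]
    }
    m
  }
  structure(list(pairwise = rows, fst = mk("fst"), rst = mk("rst"),
                 seed = seed),
            class = "differentiation_matrix")
}

#' @export
print.differentiation_matrix <- function(x, ...) {
  cat("<differentiation_matrix>\n")
  print(x$pairwise)
  invisible(x)
}

#' Association of allele size with migratory distance
#'
#' Pairs each individual's mean allele size with its species' migratory
#' distance and reports the Spearman rank correlation (midranks for ties)
#' with a permutation p-value, plus the ordinary least-squares (Pearson)
#' correlation R of the same pairing.
#'
#' @param g A [genotype_table()].
#' @param dmap A data frame `species`, `distance_km`; defaults to
#'   [shorebird_distances()].
#' @param n_perm Number of permutations, default 9999.
#' @param seed Integer seed.
#' @return A list of class `distance_association`: `rho`, `p_rho`,
#'   `regression_R`, `n_perm`, `seed`, `data` (tibble `individual`,
#'   `species`, `mean_allele`, `distance_km`).
#' @export
distance_association <- function(g, dmap = shorebird_distances(),
                                 n_perm = 9999, seed = NULL) {
  g <- genotype_table(g)
  dmap <- tibble::as_tibble(dmap)
  dat <- dplyr::inner_join(
    dplyr::mutate(g, mean_allele = (g$allele1 + g$allele2) / 2),
    dmap, by = "species")
  if (nrow(dat) == 0L) stop("no species in common with distance map",
                            call. = FALSE)
  if (length(unique(dat$distance_km)) < 3L) {
    stop("need at least 3 distinct migratory distances", call. = FALSE)
  }
  if (stats::sd(dat$distance_km) == 0) {
    stop("association undefined: all distances equal", call. = FALSE)
  }
  rho_of <- function(y) stats::cor(rank(dat$mean_allele), rank(y))
  rho <- rho_of(dat$distance_km)
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_perm, abs(rho_of(sample(dat$distance_km))))
  p_rho <- (sum(perm >= abs(rho)) + 1) / (n_perm + 1)
  structure(list(rho = rho, p_rho = p_rho,
                 regression_R = stats::cor(dat$mean_allele,
                                           dat$distance_km),
                 n_perm = as.integer(n_perm), seed = seed,
                 data = dat[, c("individual", "species", "mean_allele",
                                "distance_km")]),
            class = "distance_association")
}

#' @export
print.distance_association <- function(x, ...) {
  cat(sprintf("<distance_association> Spearman rho = %.3f (p = %.4g, %d permutations); OLS R = %.3f\n",
              x$rho, x$p_rho, x$n_perm, x$regression_R))
  invisible(x)
}

#' Univariate PERMANOVA on allele size across species
#'
#' Tests species differences in per-individual mean allele size with a
#' univariate Euclidean PERMANOVA under the unrestricted (free raw-data)
#' permutation scheme, plus pairwise pseudo-t comparisons.
#'
#' @param g A [genotype_table()].
#' @param n_perm Number of permutations, default 9999.
#' @param seed Integer seed.
#' @return A list of class `allele_size_comparison`: `overall`
#'   (the `permanova_result`), `pairwise` (pseudo-t tibble).
#' @export
allele_size_group_comparison <- function(g, n_perm = 9999, seed = NULL) {
  g <- genotype_table(g)
  size <- (g$allele1 + g$allele2) / 2
  d <- as_distance_matrix(as.matrix(stats::dist(size)))
  d$ids <- as.character(g$individual)
  dimnames(d$d) <- list(d$ids, d$ids)
  overall <- permanova(d, data.frame(species = g$species),
                       n_perm = n_perm, seed = seed, scheme = "free")
  pairwise <- pairwise_pseudo_t(d, g$species, n_perm = n_perm)
  structure(list(overall = overall, pairwise = pairwise, seed = seed),
            class = "allele_size_comparison")
}

#' @export
print.allele_size_comparison <- function(x, ...) {
  print(x$overall)
  print(x$pairwise)
  invisible(x)
}
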