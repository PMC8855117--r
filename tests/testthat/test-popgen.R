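test_that("allele summary reproduces closed-form Ho/He and private alleles", {
  g <- genotype_table(tibble::tibble(
    individual = c("i1", "i2"), species = "sp1",
    allele1 = c(172, 172), allele2 = c(174, 174)))
  s <- allele_summary(g)
  expect_equal(s$Ho, 1.0)
  expect_equal(s$He, (4 / 3) * (1 - 0.5), tolerance = 1e-12)
  expect_equal(s$A, 2L)

  mono <- genotype_table(tibble::tibble(
    individual = c("i1", "i2", "i3"), species = "m",
    allele1 = 180, allele2 = 180))
  s <- allele_summary(mono)
  expect_equal(s$A, 1L)
  expect_equal(s$Ho, 0)
  expect_equal(s$He, 0)

  two_sp <- genotype_table(tibble::tibble(
    individual = c("a1", "a2", "b1", "b2"),
    species = rep(c("A", "B"), each = 2),
    allele1 = c(170, 170, 170, 170), allele2 = c(172, 170, 174, 174)))
  s <- allele_summary(two_sp)
  expect_equal(s$private_alleles[s$species == "A"], 1L)  # 172 only in A
  expect_equal(s$private_alleles[s$species == "B"], 1L)  # 174 only in B

  # allele frequencies sum to one per species (via He bounds)
  expect_true(all(s$He >= 0 & s$He <= 1))
})

test_that("Ho and He are invariant to allele relabeling", {
  set.seed(20)
  g <- generate_genotypes(seed = 3)
  s1 <- allele_summary(g)
  g2 <- g
  # order-preserving relabeling: shift all sizes by a constant
  g2$allele1 <- g2$allele1 + 10
  g2$allele2 <- g2$allele2 + 10
  s2 <- allele_summary(genotype_table(g2))
  expect_equal(s2$Ho, s1$Ho)
  expect_equal(s2$He, s1$He)
})

test_that("HWE re-pairing test: monomorphic, calibrated, and deficit cases", {
  mono <- genotype_table(tibble::tibble(
    individual = paste0("i", 1:6), species = "m",
    allele1 = 170, allele2 = 170))
  expect_equal(hwe_test(mono, seed = 1)$p, 1)

  # all-homozygote two-allele sample: extreme heterozygote deficit
  extreme <- genotype_table(tibble::tibble(
    individual = paste0("i", 1:20), species = "x",
    allele1 = rep(c(170, 180), each = 10),
    allele2 = rep(c(170, 180), each = 10)))
  expect_lte(hwe_test(extreme, n_perm = 999, seed = 2)$p, 0.01)

  # under random mating the p-value is approximately uniform
  set.seed(30)
  ps <- replicate(200, {
    copies <- sample(seq(168, 180, 2), 100, replace = TRUE)
    g <- genotype_table(tibble::tibble(
      individual = paste0("i", 1:50), species = "u",
      allele1 = copies[1:50], allele2 = copies[51:100]))
    hwe_test(g, n_perm = 999)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("FST and RST: fixed difference, null, and variance-component oracle", {
  fixed <- genotype_table(tibble::tibble(
    individual = paste0("i", 1:8),
    species = rep(c("A", "B"), each = 4),
    allele1 = rep(c(170, 180), each = 4),
    allele2 = rep(c(170, 180), each = 4)))
  res <- fst_rst(fixed, n_perm = 99, seed = 1)
  expect_equal(res$pairwise$fst, 1, tolerance = 1e-9)
  expect_equal(res$pairwise$rst, 1, tolerance = 1e-9)

  # null: same allele frequencies in both populations
  set.seed(40)
  fsts <- replicate(100, {
    copies1 <- sample(c(170, 172, 174, 176), 100, replace = TRUE)
    copies2 <- sample(c(170, 172, 174, 176), 100, replace = TRUE)
    g <- genotype_table(tibble::tibble(
      individual = paste0("i", 1:100),
      species = rep(c("A", "B"), each = 50),
      allele1 = c(copies1[1:50], copies2[1:50]),
      allele2 = c(copies1[51:100], copies2[51:100])))
    astromorph:::wc_theta(g)
  })
  expect_lt(abs(mean(fsts)), 0.02)

  # hand-computed Weir-Cockerham variance components on a toy table
  toy <- genotype_table(tibble::tibble(
    individual = paste0("i", 1:10),
    species = rep(c("A", "B"), each = 5),
    allele1 = c(170, 170, 170, 172, 172, 172, 172, 172, 172, 170),
    allele2 = c(170, 172, 170, 172, 170, 172, 172, 170, 172, 172)))
  # oracle: explicit a, b, c components per allele
  oracle_theta <- local({
    r <- 2; n_i <- c(5, 5); nbar <- 5
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    num <- den <- 0
    for (a in c(170, 172)) {
      A_sub <- toy[toy$species == "A", ]; B_sub <- toy[toy$species == "B", ]
      p_i <- c(mean(c(A_sub$allele1, A_sub$allele2) == a),
               mean(c(B_sub$allele1, B_sub$allele2) == a))
      h_i <- c(mean((A_sub$allele1 == a) != (A_sub$allele2 == a)),
               mean((B_sub$allele1 == a) != (B_sub$allele2 == a)))
      pbar <- mean(p_i); s2 <- sum((p_i - pbar)^2) * 5 / (1 * 5)
      hbar <- mean(h_i)
      aa <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / 4)
      bb <- nbar / 4 * (pbar * (1 - pbar) - s2 / 2 - 9 / 20 * hbar)
      cc <- hbar / 2
      num <- num + aa; den <- den + aa + bb + cc
    }
    num / den
  })
  expect_equal(astromorph:::wc_theta(toy), oracle_theta, tolerance = 1e-9)

  # monomorphic pooled pair: undefined, flagged as NA
  mono_pair <- genotype_table(tibble::tibble(
    individual = paste0("i", 1:6), species = rep(c("A", "B"), each = 3),
    allele1 = 170, allele2 = 170))
  res <- fst_rst(mono_pair, n_perm = 19, seed = 1)
  expect_true(is.na(res$pairwise$fst))
})

test_that("FST ignores a constant size shift but RST does not always", {
  set.seed(41)
  g <- generate_genotypes(seed = 5)
  two <- genotype_table(g[g$species %in% c("C_collaris", "A_macularius"), ])
  f1 <- astromorph:::wc_theta(two)
  r1 <- astromorph:::rst_stat(two)
  shifted <- two
  shifted$allele1 <- shifted$allele1 + 20
  shifted$allele2 <- shifted$allele2 + 20
  expect_equal(astromorph:::wc_theta(genotype_table(shifted)), f1,
               tolerance = 1e-12)
  # RST is computed from allele sizes: scaling sizes about zero changes it
  scaled <- two
  scaled$allele1[two$species == "C_collaris"] <-
    two$allele1[two$species == "C_collaris"] * 2
  scaled$allele2[two$species == "C_collaris"] <-
    two$allele2[two$species == "C_collaris"] * 2
  expect_false(isTRUE(all.equal(
    astromorph:::rst_stat(suppressWarnings(genotype_table(scaled))), r1)))
})

test_that("distance association: exact rank formula and recovery", {
  # x = 1..4 vs y = (2,1,4,3): rho = 0.6 by the sum-of-d^2 formula
  g <- genotype_table(tibble::tibble(
    individual = paste0("i", 1:4),
    species = c("C_collaris", "C_semipalmatus", "C_pusilla",
                "A_macularius"),
    allele1 = c(172, 170, 176, 174), allele2 = c(172, 170, 176, 174)))
  res <- distance_association(g, n_perm = 99, seed = 1)
  expect_equal(res$rho, 0.6, tolerance = 1e-12)

  # perfectly increasing sizes: rho = 1
  g2 <- genotype_table(tibble::tibble(
    individual = paste0("i", 1:4),
    species = c("C_collaris", "C_semipalmatus", "C_pusilla",
                "A_macularius"),
    allele1 = c(170, 172, 174, 176), allele2 = c(170, 172, 174, 176)))
  expect_equal(distance_association(g2, n_perm = 99, seed = 1)$rho, 1)

  flat_map <- tibble::tibble(species = unique(g$species), distance_km = 5)
  expect_error(distance_association(g, flat_map), "distinct")
})

test_that("allele-size PERMANOVA equals classical ANOVA on mean sizes", {
  set.seed(42)
  g <- generate_genotypes(seed = 11)
  res <- allele_size_group_comparison(g, n_perm = 199, seed = 2)
  sizes <- (g$allele1 + g$allele2) / 2
  F_aov <- summary(stats::aov(sizes ~ factor(g$species)))[[1]]$`F value`[1]
  expect_equal(res$overall$pseudo_F[1], F_aov, tolerance = 1e-9)
  expect_equal(nrow(res$pairwise), 6L)
  expect_true(all(res$pairwise$p > 0))
})

test_that("genepop reader parses blocks and allele codes", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("Synthetic shorebird ADCYAP1 export",
               "ADCYAP1",
               "Pop",
               "spA_01 , 172174",
               "spA_02 , 172172",
               "Pop",
               "spB_01 , 180182"), path)
  g <- read_genepop(path)
  expect_equal(nrow(g), 3L)
  expect_equal(g$allele2[1], 174)
  expect_equal(unique(g$species), c("spA", "spB"))
  expect_equal(g$allele1[3], 180)
})
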