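toy_features <- function(n = 24, p = 3, seed = 1, shift = 0,
                         groups = rep(c("a", "b", "c"), each = n / 3)) {
  set.seed(seed)
  X <- matrix(rexp(n * p), n, p)
  X[groups == "b", 1] <- X[groups == "b", 1] + shift
  tibble::tibble(cell_id = sprintf("c%02d", 1:n)) |>
    dplyr::bind_cols(tibble::as_tibble(as.data.frame(X)))
}

test_that("distance assembly transforms, normalizes, and is metric", {
  feats <- tibble::tibble(cell_id = c("a", "b", "c"),
                          v = c(2, 2, 7), w = c(1, 1, 1))
  d <- assemble_distance_matrix(feats)
  expect_equal(d$d["a", "b"], 0)              # identical rows
  expect_equal(diag(d$d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d$d, t(d$d))

  # single feature with transformed values {0, 3}: distance 3
  f2 <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                       v = c(0, 0, 999, 999))
  dv <- log10(f2$v + 1)
  dv <- dv / sd(dv)
  d2 <- assemble_distance_matrix(f2)
  expect_equal(d2$d["a", "c"], abs(dv[3] - dv[1]), tolerance = 1e-12)

  # triangle inequality over all triples of a random matrix
  feats <- toy_features(n = 18, p = 4, seed = 3)
  d <- assemble_distance_matrix(feats)$d
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
  }

  expect_error(assemble_distance_matrix(
    tibble::tibble(cell_id = c("a", "b"), v = c(1, NA))), "missing")
})

test_that("one-way univariate PERMANOVA pseudo-F equals the ANOVA F", {
  set.seed(4)
  y <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  d <- as_distance_matrix(as.matrix(dist(y)))
  res <- permanova(d, data.frame(g = g), n_perm = 99, seed = 1)
  F_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$pseudo_F[1], F_aov, tolerance = 1e-9)

  # same under the free scheme
  res2 <- permanova(d, data.frame(g = g), n_perm = 99, seed = 1,
                    scheme = "free")
  expect_equal(res2$pseudo_F[1], F_aov, tolerance = 1e-9)
})

test_that("PERMANOVA agrees with vegan::adonis2 on a one-factor design", {
  skip_if_not_installed("vegan")
  feats <- toy_features(n = 24, p = 3, seed = 5, shift = 1.5)
  g <- rep(c("a", "b", "c"), each = 8)
  d <- assemble_distance_matrix(feats)
  res <- permanova(d, data.frame(g = g), n_perm = 199, seed = 2)
  ad <- vegan::adonis2(stats::as.dist(d$d) ~ g,
                       data = data.frame(g = g), permutations = 199)
  expect_equal(res$pseudo_F[1], ad$F[1], tolerance = 1e-9)
  expect_equal(res$SS[1], ad$SumOfSqs[1], tolerance = 1e-9)
})

test_that("two-factor PERMANOVA partitions SS with type III terms", {
  set.seed(6)
  n <- 40
  a <- rep(c("x", "y"), each = n / 2)
  b <- rep(rep(c("u", "v"), each = n / 4), 2)
  y <- rnorm(n) + 2 * (a == "y") + 1.5 * (b == "v")
  d <- as_distance_matrix(as.matrix(dist(y)))
  res <- permanova(d, data.frame(a = a, b = b), n_perm = 199, seed = 3)
  expect_setequal(res$term, c("a", "b", "a:b", "Residual", "Total"))
  # balanced design: distance partition equals classical anova SS
  an <- stats::anova(stats::lm(y ~ a * b))
  expect_equal(res$SS[match("a", res$term)], an["a", "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(res$SS[match("a:b", res$term)], an["a:b", "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(res$pseudo_F[match("b", res$term)], an["b", "F value"],
               tolerance = 1e-9)
  # Gower identity: SS terms + residual = total
  expect_equal(sum(res$SS[res$term %in% c("a", "b", "a:b", "Residual")]),
               res$SS[res$term == "Total"], tolerance = 1e-9)

  expect_error(permanova(d, data.frame(g = rep("one", n))), "2 levels")
  same <- as_distance_matrix(matrix(0, 8, 8))
  expect_error(permanova(same, data.frame(g = rep(c("a", "b"), 4)),
                         n_perm = 19), "identical")
})

test_that("total SS from the distance partition obeys the Gower identity", {
  set.seed(61)
  X <- matrix(rnorm(60), 20, 3)
  d <- as_distance_matrix(as.matrix(dist(X)))
  G_total <- permanova(d, data.frame(g = rep(c("a", "b"), 10)),
                       n_perm = 19, seed = 1)
  sst_features <- sum(scale(X, scale = FALSE)^2)
  expect_equal(G_total$SS[G_total$term == "Total"], sst_features,
               tolerance = 1e-9)
})

test_that("PERMANOVA is invariant to joint reordering and reproducible", {
  feats <- toy_features(n = 18, p = 3, seed = 8, shift = 1)
  g <- rep(c("a", "b", "c"), each = 6)
  d <- assemble_distance_matrix(feats)
  res1 <- permanova(d, data.frame(g = g), n_perm = 199, seed = 7)
  perm <- sample(18)
  d2 <- as_distance_matrix(d$d[perm, perm])
  res2 <- permanova(d2, data.frame(g = g[perm]), n_perm = 199, seed = 7)
  expect_equal(res2$pseudo_F[1], res1$pseudo_F[1], tolerance = 1e-9)
  res3 <- permanova(d, data.frame(g = g), n_perm = 199, seed = 7)
  expect_identical(res3$p, res1$p)
  expect_true(all(res1$p[!is.na(res1$p)] > 0))
})

test_that("PERMANOVA power rises with effect size", {
  shifts <- c(0, 0.5, 1, 2)
  set.seed(9)
  pvals <- sapply(shifts, function(s) {
    mean(replicate(30, {
      y <- rnorm(18) + s * rep(c(0, 1, 0), each = 6)
      d <- as_distance_matrix(as.matrix(dist(y)))
      permanova(d, data.frame(g = rep(c("a", "b", "c"), each = 6)),
                n_perm = 99)$p[1] <= 0.05
    }))
  })
  expect_true(all(diff(pvals) >= -0.1))   # monotone up to Monte-Carlo noise
  expect_gt(pvals[4], pvals[1])
})

test_that("PERMDISP F equals ANOVA on centroid distances; detects inflation", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, sd = 1), 20, 2),
             matrix(rnorm(40, sd = 1), 20, 2))
  g <- rep(c("a", "b"), each = 20)
  d <- as_distance_matrix(as.matrix(dist(X)))
  res <- permdisp(d, g, n_perm = 199, seed = 1)
  z <- res$centroid_distances$distance
  F_aov <- summary(stats::aov(z ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(res$overall$F, F_aov, tolerance = 1e-9)

  # against vegan::betadisper centroid distances
  skip_if_not_installed("vegan")
  bd <- vegan::betadisper(stats::as.dist(d$d), g, type = "centroid")
  expect_equal(sort(z), sort(unname(bd$distances)), tolerance = 1e-6)

  # 5x dispersion inflation is detected
  Xi <- rbind(matrix(rnorm(80, sd = 1), 40, 2),
              matrix(rnorm(80, sd = 5), 40, 2))
  gi <- rep(c("a", "b"), each = 40)
  di <- as_distance_matrix(as.matrix(dist(Xi)))
  resi <- permdisp(di, gi, n_perm = 999, seed = 2)
  expect_lte(resi$overall$p, 0.01)

  expect_error(permdisp(d, c(rep("a", 39), "b"), n_perm = 9), "at least 2")
})

test_that("pairwise pseudo-t is the square root of the two-group pseudo-F", {
  set.seed(11)
  y <- c(rnorm(8), rnorm(8, 2), rnorm(8, 4))
  g <- rep(c("a", "b", "c"), each = 8)
  d <- as_distance_matrix(as.matrix(dist(y)))
  pt <- pairwise_pseudo_t(d, g, n_perm = 99, seed = 1)
  expect_equal(nrow(pt), 3L)
  for (j in 1:3) {
    sel <- g %in% c(pt$group1[j], pt$group2[j])
    sub <- as_distance_matrix(d$d[sel, sel])
    F2 <- permanova(sub, data.frame(g = g[sel]), n_perm = 19,
                    scheme = "free")$pseudo_F[1]
    expect_equal(pt$pseudo_t[j]^2, F2, tolerance = 1e-9)
  }
  # univariate pseudo-t equals the classical equal-variance t statistic
  sel <- g %in% c("a", "b")
  t_classic <- stats::t.test(y[g == "a"], y[g == "b"],
                             var.equal = TRUE)$statistic
  expect_equal(pt$pseudo_t[1], abs(unname(t_classic)), tolerance = 1e-6)

  # duplicated identical groups: pseudo-F ~ 0, p ~ 1
  y2 <- rep(c(1, 2, 3, 4), 2)
  g2 <- rep(c("a", "b"), each = 4)
  d2 <- as_distance_matrix(as.matrix(dist(y2)))
  pt2 <- pairwise_pseudo_t(d2, g2, n_perm = 99, seed = 1)
  expect_lt(pt2$pseudo_t[1]^2, 1e-10)
  expect_gt(pt2$p[1], 0.5)
})

test_that("univariate GLM post hocs: Sidak arithmetic and Cohen's d", {
  # two groups with means 0 and 1, pooled SD 1 -> d = 1
  y1 <- c(-1, 0, 1) + 0
  y2 <- c(-1, 0, 1) + 1
  res <- univariate_glm_posthoc(c(y1, y2), rep(c("a", "b"), each = 3))
  expect_equal(abs(res$pairwise$cohen_d), 1.0)

  # identical groups: d = 0 and F ~ 0
  res0 <- univariate_glm_posthoc(rep(c(1, 2, 3), 2),
                                 rep(c("a", "b"), each = 3))
  expect_equal(res0$pairwise$cohen_d, 0)
  expect_lt(res0$anova$F, 1e-10)

  # Sidak: p = 0.01, m = 3 -> 1 - 0.99^3
  expect_equal(astromorph:::sidak_adjust(0.01, 3), 1 - 0.99^3)

  set.seed(12)
  y <- c(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  g <- rep(c("a", "b", "c"), each = 10)
  res <- univariate_glm_posthoc(y, g)
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_sidak >= res$pairwise$p))
  expect_error(univariate_glm_posthoc(1:3, c("a", "b", "b")), "at least 2")
})
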