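#' Euclidean distance matrix from a feature table
#'
#' Applies the pre-analysis transform used throughout the multivariate
#' tests — per feature `log10(x + 1)` (correcting additivity of factor
#' effects) followed by scaling to unit variance (correcting scale
#' diversity) — and returns the pairwise Euclidean distance matrix.
#'
#' @param features A tibble with `cell_id` and numeric feature columns;
#'   missing values are an error.
#' @param feature_cols Optional subset of feature columns.
#' @return A list of class `distance_matrix` with `ids` and `d` (a dense
#'   symmetric matrix, zero diagonal).
#' @export
assemble_distance_matrix <- function(features, feature_cols = NULL) {
  cols <- resolve_feature_cols(features, feature_cols)
  X <- as.matrix(features[cols])
  if (anyNA(X)) {
    bad <- features$cell_id[!stats::complete.cases(X)]
    stop("missing feature values for cell(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(X < 0)) stop("negative feature values; log10(x + 1) undefined",
                       call. = FALSE)
  X <- log10(X + 1)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  X <- sweep(X[, keep, drop = FALSE], 2, sds[keep], "/")
  d <- as.matrix(stats::dist(X))
  ids <- if ("cell_id" %in% names(features)) {
    as.character(features$cell_id)
  } else {
    as.character(seq_len(nrow(features)))
  }
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "distance_matrix")
}

#' Coerce to a distance_matrix
#'
#' @param x A `distance_matrix`, `dist`, or symmetric numeric matrix.
#' @return A `distance_matrix`.
#' @export
as_distance_matrix <- function(x) {
  if (inherits(x, "distance_matrix")) return(x)
  d <- as.matrix(x)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("x must be a symmetric square matrix or dist object", call. = FALSE)
  }
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  structure(list(ids = ids, d = d), class = "distance_matrix")
}

# Gower-centered inner-product matrix G = -1/2 J D^2 J
gower_matrix <- function(d) {
  D2 <- d^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% D2 %*% J
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Distance-based permutational multivariate ANOVA (PERMANOVA)
#'
#' Partitions the total sum of squared distances (via the Gower-centered
#' inner-product matrix) over the terms of a crossed fixed-effect design.
#' Term sums of squares are type III: each term's SS is the drop from the
#' full model to the model without that term, using sum-to-zero contrasts.
#' P-values are obtained by permutation; the default scheme permutes the
#' residuals of the reduced model excluding the tested term
#' ("residuals under a reduced model"), `scheme = "free"` permutes raw
#' observations (the unrestricted model, appropriate for one-way designs).
#'
#' @param d A `distance_matrix` (or anything [as_distance_matrix()]
#'   accepts).
#' @param design A data frame of factors, rows aligned with `d`.
#' @param formula Model formula over `design` columns; default: all
#'   factors fully crossed.
#' @param n_perm Number of permutations, default 9999.
#' @param seed Integer seed for the permutation stream.
#' @param scheme `"residual"` (default) or `"free"`.
#' @return A tibble of class `permanova_result` with one row per term:
#'   `term`, `df`, `SS`, `MS`, `pseudo_F`, `n_perm`, `p`, `seed`,
#'   `scheme`; residual and total rows are included with `NA` F/p.
#' @export
permanova <- function(d, design, formula = NULL, n_perm = 9999, seed = NULL,
                      scheme = c("residual", "free")) {
  scheme <- match.arg(scheme)
  d <- as_distance_matrix(d)
  design <- as.data.frame(design)
  design[] <- lapply(design, function(cl) {
    f <- factor(cl)
    if (nlevels(f) < 2L) stop("each factor needs at least 2 levels",
                              call. = FALSE)
    f
  })
  n <- nrow(d$d)
  stopifnot(nrow(design) == n)
  if (is.null(formula)) {
    formula <- stats::as.formula(
      paste("~", paste(names(design), collapse = " * ")))
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  X <- stats::model.matrix(formula, design)
  assign <- attr(X, "assign")
  terms_lab <- attr(stats::terms(formula, data = design), "term.labels")

  G <- gower_matrix(d$d)
  SS_total <- sum(diag(G))
  if (SS_total <= 1e-12 * n) {
    stop("total sum of squares is zero: all observations identical",
         call. = FALSE)
  }
  H_full <- hat_matrix(X)
  rank_full <- qr(X)$rank
  df_res <- n - rank_full
  if (df_res <= 0) stop("no residual degrees of freedom", call. = FALSE)
  SS_res <- SS_total - sum(H_full * G)

  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)

  rows <- purrr::map_dfr(seq_along(terms_lab), function(ti) {
    keep <- assign != ti
    Xr <- X[, keep, drop = FALSE]
    H_r <- hat_matrix(Xr)
    df_t <- rank_full - qr(Xr)$rank
    if (df_t == 0L) {
      stop("term '", terms_lab[ti], "' has zero degrees of freedom",
           call. = FALSE)
    }
    A <- H_full - H_r
    SS_t <- sum(A * G)
    F_obs <- (SS_t / df_t) / (SS_res / df_res)

    Gp <- if (scheme == "residual") {
      Q <- diag(n) - H_r
      Q %*% G %*% Q
    } else G
    Bres <- diag(n) - H_full
    trGp <- sum(diag(Gp))
    F_perm <- vapply(perms, function(p) {
      Gs <- Gp[p, p]
      ss_t <- sum(A * Gs)
      ss_r <- trGp - sum(H_r * Gs) - ss_t
      (ss_t / df_t) / (ss_r / df_res)
    }, numeric(1))
    p_val <- (sum(F_perm >= F_obs) + 1) / (n_perm + 1)
    tibble::tibble(term = terms_lab[ti], df = df_t, SS = SS_t,
                   MS = SS_t / df_t, pseudo_F = F_obs,
                   n_perm = as.integer(n_perm), p = p_val)
  })
  out <- dplyr::bind_rows(
    rows,
    tibble::tibble(term = c("Residual", "Total"),
                   df = c(df_res, n - 1L),
                   SS = c(SS_res, SS_total),
                   MS = c(SS_res / df_res, NA),
                   pseudo_F = NA_real_, n_perm = NA_integer_, p = NA_real_))
  structure(out, class = c("permanova_result", class(tibble::tibble())),
            seed = seed, scheme = scheme, formula = deparse(formula))
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the distance matrix in principal-coordinate space (negative
#' eigenvalues handled via the imaginary-axis correction), computes each
#' observation's distance to its group centroid, and tests equality of
#' mean centroid distance across groups with the classical one-way F,
#' with the p-value from permutation of the least-squares residuals of
#' those distances.  Pairwise group comparisons use the analogous
#' permutation t-tests.
#'
#' @inheritParams permanova
#' @param groups A factor (or vector) of group membership; every group
#'   must have at least 2 members.
#' @return A list of class `permdisp_result`: `overall` (tibble `F`,
#'   `df1`, `df2`, `n_perm`, `p`), `pairwise` (tibble `group1`, `group2`,
#'   `t`, `p`, `p_sidak`), `centroid_distances` (tibble `id`, `group`,
#'   `distance`), `seed`.
#' @export
permdisp <- function(d, groups, n_perm = 9999, seed = NULL) {
  d <- as_distance_matrix(d)
  g <- factor(groups)
  n <- nrow(d$d)
  stopifnot(length(g) == n)
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 members", call. = FALSE)
  }
  z <- centroid_distances(d$d, g)

  if (!is.null(seed)) set.seed(seed)
  F_obs <- anova_F(z, g)
  r <- z - stats::ave(z, g)
  F_perm <- replicate(n_perm, anova_F(r[sample.int(n)], g))
  p_val <- (sum(F_perm >= F_obs) + 1) / (n_perm + 1)

  lev <- levels(g)
  pair_rows <- list()
  if (length(lev) >= 2L) {
    prs <- utils::combn(lev, 2)
    m <- ncol(prs)
    for (j in seq_len(m)) {
      sel <- g %in% prs[, j]
      zj <- z[sel]; gj <- droplevels(g[sel])
      t_obs <- two_group_t(zj, gj)
      rj <- zj - stats::ave(zj, gj)
      t_perm <- replicate(n_perm, abs(two_group_t(rj[sample.int(length(rj))], gj)))
      pj <- (sum(t_perm >= abs(t_obs)) + 1) / (n_perm + 1)
      pair_rows[[j]] <- tibble::tibble(group1 = prs[1, j],
                                       group2 = prs[2, j],
                                       t = abs(t_obs), p = pj)
    }
  }
  pairwise <- dplyr::bind_rows(pair_rows)
  if (nrow(pairwise) > 0) {
    pairwise$p_sidak <- sidak_adjust(pairwise$p, nrow(pairwise))
  }
  structure(list(
    overall = tibble::tibble(statistic = "F", F = F_obs,
                             df1 = nlevels(g) - 1L, df2 = n - nlevels(g),
                             n_perm = as.integer(n_perm), p = p_val),
    pairwise = pairwise,
    centroid_distances = tibble::tibble(id = d$ids, group = as.character(g),
                                        distance = z),
    seed = seed), class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat(sprintf("<permdisp_result> F(%d, %d) = %.4g, p = %.4g (%d permutations)\n",
              x$overall$df1, x$overall$df2, x$overall$F, x$overall$p,
              x$overall$n_perm))
  invisible(x)
}

# distances to group centroids in principal-coordinate space, with the
# standard correction for negative eigenvalues of the Gower matrix
centroid_distances <- function(d, g) {
  G <- gower_matrix(d)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values))
  pos <- e$values > tol
  neg <- e$values < -tol
  Cr <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                sum(pos))
  Ci <- if (any(neg)) {
    e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  } else NULL
  z2 <- numeric(nrow(d))
  for (lev in levels(g)) {
    sel <- g == lev
    dr <- sweep(Cr[sel, , drop = FALSE], 2, colMeans(Cr[sel, , drop = FALSE]))
    z2[sel] <- rowSums(dr^2)
    if (!is.null(Ci)) {
      di <- sweep(Ci[sel, , drop = FALSE], 2,
                  colMeans(Ci[sel, , drop = FALSE]))
      z2[sel] <- z2[sel] - rowSums(di^2)
    }
  }
  sqrt(pmax(z2, 0))
}

anova_F <- function(y, g) {
  ybar <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ssb <- sum(ns * (means - ybar)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

two_group_t <- function(y, g) {
  lev <- levels(g)
  y1 <- y[g == lev[1]]; y2 <- y[g == lev[2]]
  n1 <- length(y1); n2 <- length(y2)
  sp2 <- ((n1 - 1) * stats::var(y1) + (n2 - 1) * stats::var(y2)) /
    (n1 + n2 - 2)
  (mean(y1) - mean(y2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

sidak_adjust <- function(p, m) pmin(1, 1 - (1 - p)^m)

#' Pairwise PERMANOVA pseudo-t comparisons
#'
#' For each pair of groups runs a two-group one-way PERMANOVA restricted
#' to that pair; the pseudo-t is the square root of the two-group
#' pseudo-F.  Groups of size 1 are skipped with a warning.  Raw and
#' Sidak-adjusted p-values are reported.
#'
#' @inheritParams permdisp
#' @return A tibble with columns `group1`, `group2`, `pseudo_t`, `n_perm`,
#'   `p`, `p_sidak`.
#' @export
pairwise_pseudo_t <- function(d, groups, n_perm = 9999, seed = NULL) {
  d <- as_distance_matrix(d)
  g <- factor(groups)
  lev <- levels(g)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    warning("group(s) of size 1 skipped: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
    lev <- names(sizes)[sizes >= 2L]
  }
  if (length(lev) < 2L) stop("need at least 2 usable groups", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  prs <- utils::combn(lev, 2)
  rows <- purrr::map_dfr(seq_len(ncol(prs)), function(j) {
    sel <- which(g %in% prs[, j])
    sub <- as_distance_matrix(d$d[sel, sel, drop = FALSE])
    res <- permanova(sub, data.frame(group = droplevels(g[sel])),
                     n_perm = n_perm, scheme = "free")
    tibble::tibble(group1 = prs[1, j], group2 = prs[2, j],
                   pseudo_t = sqrt(max(res$pseudo_F[1], 0)),
                   n_perm = as.integer(n_perm), p = res$p[1])
  })
  rows$p_sidak <- sidak_adjust(rows$p, nrow(rows))
  rows
}

#' Univariate GLM with Sidak-adjusted post hocs and Cohen's d
#'
#' One-way fixed-effect F-test on a single response, pairwise t-tests on
#' the pooled residual mean square with Sidak adjustment
#' (`1 - (1 - p)^m` over the `m` pairwise comparisons), and pairwise
#' Cohen's d (mean difference over the two groups' pooled SD; `NA` when
#' the pooled variance is zero).
#'
#' @param values Numeric response.
#' @param groups Group factor; at least 2 groups of at least 2.
#' @return A list of class `glm_posthoc`: `anova` (tibble `F`, `df1`,
#'   `df2`, `p`), `pairwise` (tibble `group1`, `group2`, `diff`, `t`, `p`,
#'   `p_sidak`, `cohen_d`).
#' @export
univariate_glm_posthoc <- function(values, groups) {
  g <- factor(groups)
  y <- as.numeric(values)
  stopifnot(length(y) == length(g))
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("need at least 2 groups with at least 2 observations each",
         call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  F_val <- an$`F value`[1]
  df1 <- an$Df[1]; df2 <- an$Df[2]
  mse <- an$`Mean Sq`[2]
  p_F <- an$`Pr(>F)`[1]

  lev <- levels(g)
  prs <- utils::combn(lev, 2)
  m <- ncol(prs)
  rows <- purrr::map_dfr(seq_len(m), function(j) {
    y1 <- y[g == prs[1, j]]; y2 <- y[g == prs[2, j]]
    n1 <- length(y1); n2 <- length(y2)
    diff <- mean(y1) - mean(y2)
    t_val <- diff / sqrt(mse * (1 / n1 + 1 / n2))
    p_t <- 2 * stats::pt(abs(t_val), df2, lower.tail = FALSE)
    sp2 <- ((n1 - 1) * stats::var(y1) + (n2 - 1) * stats::var(y2)) /
      (n1 + n2 - 2)
    d_val <- if (sp2 > 0) diff / sqrt(sp2) else NA_real_
    tibble::tibble(group1 = prs[1, j], group2 = prs[2, j], diff = diff,
                   t = t_val, p = p_t, cohen_d = d_val)
  })
  rows$p_sidak <- sidak_adjust(rows$p, m)
  rows <- rows[, c("group1", "group2", "diff", "t", "p", "p_sidak",
                   "cohen_d")]
  structure(list(anova = tibble::tibble(F = F_val, df1 = df1, df2 = df2,
                                        p = p_F),
                 pairwise = rows),
            class = "glm_posthoc")
}

#' @export
print.glm_posthoc <- function(x, ...) {
  cat(sprintf("<glm_posthoc> F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  print(x$pairwise)
  invisible(x)
}
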