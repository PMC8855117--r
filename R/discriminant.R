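#' Stepwise canonical discriminant validation of morphotypes
#'
#' Validates a clustering by (1) forward stepwise variable entry — at each
#' step the candidate feature with the smallest partial-F p-value enters if
#' `p < alpha`, stopping when no candidate qualifies — and (2) canonical
#' discriminant analysis on the entered variables: eigenvalues of the
#' between/within scatter eigenproblem, per-function percent of variance,
#' Wilks's lambda for each sequential function test
#' (`Lambda_k = prod_{i>=k} 1/(1+lambda_i)`, with Bartlett chi-square
#' p-values), the structure matrix (pooled within-group correlations of
#' each entered feature with each canonical function), and a
#' resubstitution confusion table with percent correctly classified.
#'
#' @param features A tibble with `cell_id` and numeric feature columns
#'   (transformed scale recommended).
#' @param labels A `morphotype_result` or vector of group ids aligned with
#'   `features` rows.
#' @param alpha Entry threshold for the partial-F p-value, default 0.05.
#' @param feature_cols Optional candidate feature subset.
#' @param ridge Ridge fraction added to the within-group scatter diagonal
#'   when it is singular (with a warning), default `1e-8`.
#' @param tol_entry Minimum within-group tolerance (share of a candidate's
#'   within-group variance unexplained by the already-entered variables)
#'   required to enter, default `1e-4`; near-collinear candidates are
#'   skipped.
#' @return A list of class `discriminant_summary`: `entered` (features in
#'   entry order, with partial F and p), `eigenvalues`, `pct_variance`,
#'   `wilks` (tibble `test`, `lambda`, `chisq`, `df`, `p`),
#'   `structure_matrix`, `scores` (canonical scores per cell), `confusion`,
#'   `accuracy_pct`.
#' @export
discriminant_validation <- function(features, labels, alpha = 0.05,
                                    feature_cols = NULL, ridge = 1e-8,
                                    tol_entry = 1e-4) {
  if (inherits(labels, "morphotype_result")) labels <- labels$labels$morphotype
  stopifnot(length(labels) == nrow(features))
  cols <- resolve_feature_cols(features, feature_cols)
  g <- factor(labels)
  ng <- nlevels(g)
  n <- nrow(features)
  if (ng < 2L) stop("need at least 2 groups", call. = FALSE)
  X <- as.matrix(features[cols])

  wilks_of <- function(vars) {
    M <- X[, vars, drop = FALSE]
    sc <- scatter_matrices(M, g)
    det_ratio(sc$W, sc$W + sc$B)
  }
  logdet_W <- function(vars) {
    sc <- scatter_matrices(X[, vars, drop = FALSE], g)
    as.numeric(determinant(sc$W, logarithm = TRUE)$modulus)
  }

  # ---- forward stepwise entry on partial Wilks F
  entered <- character(0)
  steps <- list()
  lambda_cur <- 1
  repeat {
    cand <- setdiff(cols, entered)
    if (length(cand) == 0L) break
    p_s <- length(entered)
    df2 <- n - ng - p_s
    if (df2 <= 0) break
    ld_S <- if (length(entered) > 0) logdet_W(entered) else 0
    stats_c <- purrr::map_dfr(cand, function(v) {
      # within-group tolerance of the candidate given the entered set;
      # zero within-group variance would make the scatter singular
      ld_v <- logdet_W(v)
      tol_v <- if (!is.finite(ld_v)) 0 else
        exp(logdet_W(c(entered, v)) - ld_S - ld_v)
      if (!is.finite(tol_v) || tol_v < tol_entry) {
        return(tibble::tibble(feature = v, lambda = NA_real_,
                              partial_F = NA_real_, p = Inf))
      }
      lam <- wilks_of(c(entered, v))
      if (!is.finite(lam)) {
        return(tibble::tibble(feature = v, lambda = NA_real_,
                              partial_F = NA_real_, p = Inf))
      }
      ratio <- lam / lambda_cur
      ratio <- min(1, max(ratio, .Machine$double.eps))
      Fv <- (df2 / (ng - 1)) * (1 - ratio) / ratio
      tibble::tibble(feature = v, lambda = lam, partial_F = Fv,
                     p = stats::pf(Fv, ng - 1, df2, lower.tail = FALSE))
    })
    best <- stats_c[order(stats_c$p, -stats_c$partial_F), ][1, ]
    if (!is.finite(best$partial_F) || best$p >= alpha) break
    entered <- c(entered, best$feature)
    lambda_cur <- best$lambda
    steps[[length(steps) + 1]] <- best
  }
  if (length(entered) == 0L) {
    stop("no feature passed the stepwise entry criterion (alpha = ",
         alpha, ")", call. = FALSE)
  }
  entered_tbl <- dplyr::bind_rows(steps)

  # ---- canonical eigenproblem on the entered variables
  M <- X[, entered, drop = FALSE]
  sc <- scatter_matrices(M, g)
  W <- sc$W
  if (rcond_sym(W) < 1e-12) {
    warning("singular within-group scatter: ridge regularization applied",
            call. = FALSE)
    W <- W + diag(ridge * mean(diag(W)), nrow(W))
  }
  m <- min(ncol(M), ng - 1L)
  ev <- eigen(solve(W, sc$B))
  lam <- Re(ev$values)[seq_len(m)]
  lam[lam < 0] <- 0
  A <- Re(ev$vectors)[, seq_len(m), drop = FALSE]
  # normalize: unit pooled within-group variance of each canonical score
  Sp <- W / (n - ng)
  for (j in seq_len(m)) {
    s <- sqrt(drop(t(A[, j]) %*% Sp %*% A[, j]))
    if (s > 0) A[, j] <- A[, j] / s
  }
  scores <- M %*% A
  colnames(scores) <- paste0("function_", seq_len(m))

  pct <- if (sum(lam) > 0) 100 * lam / sum(lam) else rep(100 / m, m)

  wilks <- purrr::map_dfr(seq_len(m), function(k) {
    lambda_k <- prod(1 / (1 + lam[k:m]))
    p_k <- length(entered)
    chisq <- -(n - 1 - (p_k + ng) / 2) * log(lambda_k)
    df <- (p_k - k + 1) * (ng - k)
    tibble::tibble(test = paste0(k, "-", m), lambda = lambda_k,
                   chisq = chisq, df = df,
                   p = stats::pchisq(chisq, df, lower.tail = FALSE))
  })

  # ---- structure matrix: pooled within-group correlations
  Mw <- M - group_means(M, g)[g, , drop = FALSE]
  Sw <- scores - group_means(scores, g)[g, , drop = FALSE]
  structure_matrix <- stats::cor(Mw, Sw)
  rownames(structure_matrix) <- entered
  colnames(structure_matrix) <- colnames(scores)

  # ---- resubstitution classification (linear rule, pooled covariance,
  #      priors proportional to group size)
  mu <- group_means(M, g)
  Sp_inv <- solve(Sp)
  prior <- as.numeric(table(g)) / n
  disc <- sapply(seq_len(ng), function(j) {
    m_j <- mu[j, ]
    drop(M %*% (Sp_inv %*% m_j)) - 0.5 * drop(t(m_j) %*% Sp_inv %*% m_j) +
      log(prior[j])
  })
  pred <- levels(g)[max.col(disc, ties.method = "first")]
  confusion <- table(observed = g, predicted = factor(pred, levels(g)))
  accuracy <- 100 * sum(diag(confusion)) / sum(confusion)

  structure(list(entered = entered_tbl, eigenvalues = lam,
                 pct_variance = pct, wilks = wilks,
                 structure_matrix = structure_matrix,
                 scores = dplyr::bind_cols(
                   tibble::tibble(cell_id = as.character(features$cell_id),
                                  group = as.character(g),
                                  predicted = pred),
                   tibble::as_tibble(scores)),
                 confusion = confusion, accuracy_pct = accuracy,
                 alpha = alpha),
            class = "discriminant_summary")
}

#' @export
print.discriminant_summary <- function(x, ...) {
  cat("<discriminant_summary>\n  entered:",
      paste(x$entered$feature, collapse = ", "), "\n")
  cat(sprintf("  function 1 explains %.1f%% of variance; Wilks lambda (%s) = %.3f (p = %.3g)\n",
              x$pct_variance[1], x$wilks$test[1], x$wilks$lambda[1],
              x$wilks$p[1]))
  cat(sprintf("  resubstitution accuracy: %.1f%%\n", x$accuracy_pct))
  invisible(x)
}

group_means <- function(M, g) {
  mu <- rowsum(M, g) / as.numeric(table(g))
  mu[levels(g), , drop = FALSE]
}

scatter_matrices <- function(M, g) {
  mu <- group_means(M, g)
  ctr <- M - mu[g, , drop = FALSE]
  W <- crossprod(ctr)
  tot <- sweep(M, 2, colMeans(M))
  B <- crossprod(tot) - W
  list(W = W, B = B)
}

# |W| / |T| via Cholesky-stable determinant ratio
det_ratio <- function(W, T) {
  dW <- determinant(W, logarithm = TRUE)
  dT <- determinant(T, logarithm = TRUE)
  if (!is.finite(dW$modulus) || !is.finite(dT$modulus)) return(NA_real_)
  exp(as.numeric(dW$modulus - dT$modulus))
}

rcond_sym <- function(W) {
  e <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (max(e) <= 0) return(0)
  max(min(e), 0) / max(e)
}
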