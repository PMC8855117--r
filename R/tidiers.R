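#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PERMANOVA table
#'
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy permanova_result
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a PERMDISP result
#'
#' @param x A `permdisp_result`.
#' @param ... Unused.
#' @return A tibble: the overall F row followed by the pairwise t rows.
#' @method tidy permdisp_result
#' @export
tidy.permdisp_result <- function(x, ...) {
  overall <- tibble::tibble(term = "groups", statistic = "F",
                            value = x$overall$F, n_perm = x$overall$n_perm,
                            p = x$overall$p, p_sidak = NA_real_)
  if (nrow(x$pairwise) == 0) return(overall)
  dplyr::bind_rows(
    overall,
    tibble::tibble(term = paste(x$pairwise$group1, x$pairwise$group2,
                                sep = " vs "),
                   statistic = "pseudo-t", value = x$pairwise$t,
                   n_perm = x$overall$n_perm, p = x$pairwise$p,
                   p_sidak = x$pairwise$p_sidak))
}

#' Tidy a discriminant summary
#'
#' @param x A `discriminant_summary`.
#' @param ... Unused.
#' @return A tibble with one row per canonical function: eigenvalue,
#'   percent of variance, Wilks's lambda of the sequential test and its
#'   p-value.
#' @method tidy discriminant_summary
#' @export
tidy.discriminant_summary <- function(x, ...) {
  tibble::tibble(func = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 pct_variance = x$pct_variance,
                 wilks_lambda = x$wilks$lambda,
                 p = x$wilks$p)
}

#' One-line summary of a discriminant validation
#'
#' @param x A `discriminant_summary`.
#' @param ... Unused.
#' @return A one-row tibble: number of entered features, first-function
#'   percent variance, Wilks's lambda of the full test, resubstitution
#'   accuracy.
#' @method glance discriminant_summary
#' @export
glance.discriminant_summary <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$entered),
                 pct_variance_f1 = x$pct_variance[1],
                 wilks_lambda = x$wilks$lambda[1],
                 p = x$wilks$p[1],
                 accuracy_pct = x$accuracy_pct)
}

#' One-line summary of a morphotype clustering
#'
#' @param x A `morphotype_result`.
#' @param ... Unused.
#' @return A one-row tibble: cells, k, selected feature count, the merge
#'   height ratio at the chosen cut.
#' @method glance morphotype_result
#' @export
glance.morphotype_result <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$labels), k = x$k,
                 n_features = length(x$selected_features),
                 gap_ratio = unname(x$gap_ratio[as.character(x$k)]))
}

#' Tidy a diversity summary
#'
#' @param x A `diversity_summary`.
#' @param ... Unused.
#' @return The underlying per-species tibble.
#' @method tidy diversity_summary
#' @export
tidy.diversity_summary <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a distance association result
#'
#' @param x A `distance_association`.
#' @param ... Unused.
#' @return A one-row tibble with rho, its permutation p-value and the OLS
#'   correlation R.
#' @method tidy distance_association
#' @export
tidy.distance_association <- function(x, ...) {
  tibble::tibble(rho = x$rho, p = x$p_rho, regression_R = x$regression_R,
                 n = nrow(x$data), n_perm = x$n_perm)
}
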