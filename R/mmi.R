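#' Multimodality index (bimodality coefficient)
#'
#' `MMI = (M3^2 + 1) / (M4 + 3 (n-1)^2 / ((n-2)(n-3)))`, where `M3` is the
#' bias-corrected sample skewness and `M4` the bias-corrected sample
#' *excess* kurtosis.  With this convention the index approaches 1/3 for a
#' normal sample, 5/9 (~0.555) for a uniform sample and 1 for a symmetric
#' two-point sample, so the classical 0.555 benchmark separates unimodal
#' from multimodal shapes and motivates the 0.55 screening threshold used
#' by [select_features()].  Location/scale invariant.
#'
#' @param values Numeric sample, `n >= 4`, non-constant.
#' @return A list of class `mmi_stats` with fields `m3`, `m4`, `n`, `mmi`.
#' @export
multimodality_index <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 4L) stop("MMI needs at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("MMI undefined for constant sample",
                              call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  m3 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  m4 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  mmi <- (m3^2 + 1) / (m4 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  structure(list(m3 = m3, m4 = m4, n = n, mmi = mmi), class = "mmi_stats")
}

#' @export
print.mmi_stats <- function(x, ...) {
  cat(sprintf("<mmi_stats> n = %d, skewness = %.4f, excess kurtosis = %.4f, MMI = %.4f\n",
              x$n, x$m3, x$m4, x$mmi))
  invisible(x)
}

#' MMI of every feature column
#'
#' @param features A feature tibble (e.g. from [compute_feature_matrix()]).
#' @param feature_cols Optional character vector of columns to score;
#'   defaults to all numeric non-identity columns.
#' @return A tibble with columns `feature`, `n`, `m3`, `m4`, `mmi`.
#' @export
feature_mmi <- function(features, feature_cols = NULL) {
  cols <- resolve_feature_cols(features, feature_cols)
  purrr::map_dfr(cols, function(cl) {
    s <- multimodality_index(features[[cl]])
    tibble::tibble(feature = cl, n = s$n, m3 = s$m3, m4 = s$m4, mmi = s$mmi)
  })
}

id_cols <- c("cell_id", "species", "individual", "region", "morphotype",
             "true_class")

resolve_feature_cols <- function(features, feature_cols = NULL) {
  if (!is.null(feature_cols)) {
    missing <- setdiff(feature_cols, names(features))
    if (length(missing) > 0) {
      stop("unknown feature column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    return(feature_cols)
  }
  nm <- names(features)[vapply(features, is.numeric, logical(1))]
  setdiff(nm, id_cols)
}

#' Screen features by multimodality
#'
#' Retains, in input order, the feature columns whose MMI is strictly
#' greater than `threshold` (default 0.55): features with MMI exactly at
#' the threshold are dropped.  Features that are undefined for some cells
#' (e.g. planar angle on unbranched arbors) are excluded with a message,
#' since they cannot enter the distance-based analyses downstream.
#'
#' @inheritParams feature_mmi
#' @param threshold MMI cut-off, default 0.55.
#' @return Character vector of retained feature names.
#' @export
select_features <- function(features, threshold = 0.55, feature_cols = NULL) {
  cols <- resolve_feature_cols(features, feature_cols)
  incomplete <- cols[vapply(cols, function(cl) {
    any(!is.finite(features[[cl]]))
  }, logical(1))]
  if (length(incomplete) > 0) {
    message("feature(s) undefined for some cells excluded from the screen: ",
            paste(incomplete, collapse = ", "))
  }
  scores <- feature_mmi(features, setdiff(cols, incomplete))
  kept <- scores$feature[scores$mmi > threshold]
  if (length(kept) == 0L) {
    stop("no feature exceeds the MMI threshold (", threshold,
         "); review the threshold or the data", call. = FALSE)
  }
  kept
}

#' Variance-shrunk log transform
#'
#' Per feature: decimal log, then scaling to unit variance, so that
#' features of very different magnitudes (lengths vs volumes) contribute
#' comparably to Euclidean distances.  Features containing zeros fall back
#' to `log10(x + 1)` (recorded in the `offset_features` attribute);
#' features constant after the log are dropped with a warning.  Negative
#' values are an error.
#'
#' @param features A feature tibble.
#' @param feature_cols Columns to transform; default all numeric
#'   non-identity columns.
#' @return The tibble with transformed feature columns; attribute
#'   `offset_features` lists columns where the `+1` offset was applied.
#' @export
shrink_log_transform <- function(features, feature_cols = NULL) {
  cols <- resolve_feature_cols(features, feature_cols)
  offset <- character(0)
  dropped <- character(0)
  for (cl in cols) {
    x <- features[[cl]]
    if (any(x < 0, na.rm = TRUE)) {
      stop("feature '", cl, "' has negative values; cannot log-transform",
           call. = FALSE)
    }
    if (any(x == 0, na.rm = TRUE)) {
      x <- log10(x + 1)
      offset <- c(offset, cl)
    } else {
      x <- log10(x)
    }
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      dropped <- c(dropped, cl)
      features[[cl]] <- NULL
      next
    }
    features[[cl]] <- x / s
  }
  if (length(dropped) > 0) {
    warning("constant-after-log feature(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  attr(features, "offset_features") <- offset
  features
}
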