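#' Principal component analysis of model residuals
#'
#' Eigen-decomposition of the item-by-item correlation matrix of
#' standardized partial-credit-model residuals (pairwise-complete
#' observations). Under a unidimensional model the residuals carry no
#' shared structure, so all eigenvalues should stay below about 2; a large
#' first eigenvalue with loadings that split the items into clusters
#' signals a second dimension. The loadings on the first contrast are the
#' leading eigenvector scaled by the square root of its eigenvalue,
#' oriented so the largest-magnitude loading is positive.
#'
#' @param res A `resid_matrix` from [pcm_residuals()].
#' @return List with `eigenvalues` (descending; they sum to the item
#'   count), `loadings` (first contrast, named by item), `cor` (the
#'   residual correlation matrix) and `n_persons`.
#' @export
residual_pca <- function(res) {
  stopifnot(inherits(res, "resid_matrix"))
  Z <- res$z[apply(is.finite(res$z), 1L, any), , drop = FALSE]
  if (nrow(Z) < ncol(Z))
    warning("fewer persons than items: residual correlations are rank-deficient")
  R <- stats::cor(Z, use = "pairwise.complete.obs")
  e <- eigen(R, symmetric = TRUE)
  lo <- e$vectors[, 1L] * sqrt(e$values[1L])
  if (lo[which.max(abs(lo))] < 0) lo <- -lo
  names(lo) <- colnames(Z)
  list(eigenvalues = e$values, loadings = lo, cor = R, n_persons = nrow(Z))
}

#' Residual correlations with relative cutoff screening
#'
#' Q3-type local dependence screening: correlations between item pairs of
#' standardized residuals, compared against a relative cutoff of
#' `rel_cutoff` above the average over all item pairs. Pairs above the
#' cutoff indicate locally dependent (or redundant) items.
#'
#' @param res A `resid_matrix`, or a ready-made item-by-item residual
#'   correlation matrix (e.g. from a published table).
#' @param rel_cutoff Margin above the mean pairwise correlation (default
#'   0.2).
#' @return List with `cor`, `mean_r` (average over the off-diagonal
#'   pairs), `cutoff`, and `flagged` (data frame of item pairs with
#'   correlation strictly above the cutoff). The estimator is labelled in
#'   the `estimator` element ("Q3 on standardized residuals").
#' @export
residual_correlations <- function(res, rel_cutoff = 0.2) {
  R <- if (inherits(res, "resid_matrix")) residual_pca(res)$cor
       else as.matrix(res)
  ut <- upper.tri(R)
  mean_r <- mean(R[ut], na.rm = TRUE)
  cutoff <- mean_r + rel_cutoff
  hits <- which(ut & R > cutoff, arr.ind = TRUE)
  flagged <- data.frame(
    item1 = rownames(R)[hits[, 1L]],
    item2 = colnames(R)[hits[, 2L]],
    r = R[hits],
    stringsAsFactors = FALSE)
  flagged <- flagged[order(flagged$item1, flagged$item2), , drop = FALSE]
  rownames(flagged) <- NULL
  list(cor = R, mean_r = mean_r, cutoff = cutoff, flagged = flagged,
       estimator = "Q3 on standardized residuals")
}

#' Dimensionality report
#'
#' Combines the residual PCA and the residual-correlation screening for
#' an instrument, optionally attaching item locations for a
#' location-vs-loading display.
#'
#' @param rm A [response_matrix()] object.
#' @param ip Fitted `item_parameters`.
#' @param pe Optional `person_estimates`.
#' @param rel_cutoff Passed to [residual_correlations()].
#' @return Object of class `dim_report` combining both analyses.
#' @export
dimensionality_report <- function(rm, ip, pe = NULL, rel_cutoff = 0.2) {
  res <- pcm_residuals(rm, ip, pe)
  pca <- residual_pca(res)
  q3 <- residual_correlations(res, rel_cutoff)
  structure(list(eigenvalues = pca$eigenvalues, loadings = pca$loadings,
                 locations = ip$locations[names(pca$loadings)],
                 cor = q3$cor, mean_r = q3$mean_r, cutoff = q3$cutoff,
                 flagged = q3$flagged, estimator = q3$estimator),
            class = "dim_report")
}

#' Unidimensionality verdict
#'
#' Declares an instrument multidimensional if any residual-PCA eigenvalue
#' reaches 2.0 or any residual correlation exceeds the relative cutoff;
#' otherwise unidimensional. The rationale lists the triggering values.
#'
#' @param report A `dim_report` (or a list with `eigenvalues` and
#'   `flagged`).
#' @param eigen_cutoff Eigenvalue threshold (default 2.0).
#' @return List with `verdict` ("unidimensional"/"multidimensional") and
#'   `rationale` (character vector).
#' @export
assess_unidimensionality <- function(report, eigen_cutoff = 2.0) {
  ev <- report$eigenvalues
  reasons <- character(0)
  if (any(ev >= eigen_cutoff))
    reasons <- c(reasons,
                 sprintf("first eigenvalue %.2f >= %.1f", max(ev), eigen_cutoff))
  if (!is.null(report$flagged) && nrow(report$flagged) > 0)
    reasons <- c(reasons,
                 sprintf("residual correlation above cutoff: %s-%s (r = %.2f)",
                         report$flagged$item1, report$flagged$item2,
                         report$flagged$r))
  if (length(reasons) == 0)
    reasons <- sprintf("all eigenvalues below %.1f (max %.2f) and no flagged residual pairs",
                       eigen_cutoff, max(ev))
  list(verdict = if (any(ev >= eigen_cutoff) ||
                     (!is.null(report$flagged) && nrow(report$flagged) > 0))
                   "multidimensional" else "unidimensional",
       rationale = reasons)
}

#' @export
print.dim_report <- function(x, ...) {
  cat("Dimensionality report (", x$estimator, ")\n", sep = "")
  cat("eigenvalues:", paste(round(x$eigenvalues, 2), collapse = " "), "\n")
  cat(sprintf("mean residual correlation %.3f, cutoff %.3f\n",
              x$mean_r, x$cutoff))
  if (nrow(x$flagged)) {
    cat("flagged pairs:\n"); print(x$flagged, row.names = FALSE)
  } else cat("no flagged pairs\n")
  v <- assess_unidimensionality(x)
  cat("verdict:", v$verdict, "\n")
  invisible(x)
}
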