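# replace missing calls by the per-site mean of the non-missing calls
impute_mean <- function(geno) {
  X <- geno
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(mu))
    stop("site(s) with all calls missing cannot be mean-imputed; filter first")
  na_idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_idx)) X[na_idx] <- mu[na_idx[, 2]]
  X
}

#' Principal component analysis with mean imputation
#'
#' Missing calls are replaced by the per-site mean of the non-missing calls,
#' columns are centered (and optionally unit-variance scaled), and the
#' centered matrix is decomposed by SVD. Per-axis percentages of variance are
#' eigenvalue shares of the trace.
#'
#' @param G a [genotype_matrix()].
#' @param scale logical; scale columns to unit variance (default `FALSE`,
#'   centering only).
#' @return A `pca_result` list: `coords` (individuals x axes), `pct_var`
#'   (percent variance per axis, non-increasing), `sdev`.
#' @export
pca_mean_impute <- function(G, scale = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$geno) < 2) stop("need at least two individuals")
  X <- impute_mean(G$geno)
  keep <- apply(X, 2, function(v) var(v) > 0)
  if (!any(keep)) stop("no variable sites after imputation")
  if (scale) X <- X[, keep, drop = FALSE]
  fit <- prcomp(if (scale) X else X, center = TRUE, scale. = scale)
  pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  structure(list(coords = fit$x, pct_var = pct, sdev = fit$sdev,
                 scaled = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$pct_var))
  cat("<pca_result>", nrow(x$coords), "individuals\n")
  cat("  % variance:",
      paste(sprintf("PC%d=%.1f", seq_len(k), x$pct_var[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
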