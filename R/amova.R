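#' Analysis of molecular variance (one level) with permutation test
#'
#' Excoffier-style AMOVA on squared pairwise distances: total and
#' within-group sums of squares give mean squares, from which the variance
#' components `sigma2_among` and `sigma2_within` and the Phi statistic
#' `Phi = sigma2_among / (sigma2_among + sigma2_within)` follow. Significance
#' is assessed by randomly permuting group labels; the p-value uses the
#' add-one correction `p = (1 + #{Phi* >= Phi}) / (n_perm + 1)`.
#'
#' For a [genotype_matrix()] input, distances are squared Euclidean on
#' mean-imputed allele-count vectors; for a [marker_alignment()] input, the
#' Hamming proportion from [pairwise_distance()] is squared. A precomputed
#' distance object (`dist` or square matrix) is used as-is (and squared).
#'
#' @param data a [genotype_matrix()], [marker_alignment()], `dist`, or square
#'   numeric distance matrix.
#' @param groups factor of group labels, one per individual. Defaults to the
#'   population labels carried by `data` when available.
#' @param n_perm number of label permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @return An `amova_result` list: `sigma2_among`, `sigma2_within`,
#'   `pct_among`, `pct_within`, `phi`, `p_value`, `n_perm`, `distance`
#'   (metric label).
#' @export
amova <- function(data, groups = NULL, n_perm = 9999, seed = 1) {
  if (inherits(data, "genotype_matrix")) {
    if (is.null(groups)) groups <- data$pop
    X <- impute_mean(data$geno)
    d2 <- as.matrix(stats::dist(X))^2
    metric <- "squared Euclidean on mean-imputed allele counts"
  } else if (inherits(data, "marker_alignment")) {
    if (is.null(groups)) groups <- attr(data, "groups")
    d2 <- pairwise_distance(data)^2
    metric <- "squared Hamming proportion"
  } else if (inherits(data, "dist")) {
    d2 <- as.matrix(data)^2
    metric <- "user-supplied distance, squared"
  } else if (is.matrix(data) && nrow(data) == ncol(data)) {
    d2 <- data^2
    metric <- "user-supplied distance, squared"
  } else {
    stop("unsupported input type for amova()")
  }
  if (is.null(groups)) stop("groups must be supplied for distance input")
  groups <- factor(groups)
  n <- nrow(d2)
  if (length(groups) != n) stop("groups length must match individuals")
  sizes <- tabulate(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("singleton group(s): ",
         paste(levels(groups)[sizes < 2], collapse = ", "),
         "; every group needs >= 2 members")

  comps <- amova_components(d2, groups)
  obs_phi <- comps$phi

  ge <- n_perm
  if (ge > 0) {
    withr::with_seed(seed, {
      count <- 0L
      for (b in seq_len(n_perm)) {
        gp <- groups[sample.int(n)]
        if (amova_components(d2, gp)$phi >= obs_phi) count <- count + 1L
      }
    })
    p <- (1 + count) / (n_perm + 1)
  } else {
    p <- NA_real_
  }
  structure(c(comps, list(p_value = p, n_perm = n_perm, distance = metric)),
            class = "amova_result")
}

# variance components from a squared-distance matrix and group factor
amova_components <- function(d2, groups) {
  n <- nrow(d2)
  g_int <- as.integer(groups)
  sizes <- tabulate(g_int)
  G <- length(sizes)
  ssd_total <- sum(d2[upper.tri(d2)]) / n
  ssd_within <- 0
  for (g in seq_len(G)) {
    idx <- which(g_int == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssd_within <- ssd_within + sum(sub[upper.tri(sub)]) / sizes[g]
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- G - 1
  df_within <- n - G
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n0 <- (n - sum(sizes^2) / n) / (G - 1)
  s2_within <- ms_within
  s2_among <- (ms_among - ms_within) / n0
  tot <- s2_among + s2_within
  list(sigma2_among = s2_among, sigma2_within = s2_within,
       pct_among = 100 * s2_among / tot, pct_within = 100 * s2_within / tot,
       phi = s2_among / tot)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  cat(sprintf("  among groups : sigma2 = %.4g (%.1f%%)\n",
              x$sigma2_among, x$pct_among))
  cat(sprintf("  within groups: sigma2 = %.4g (%.1f%%)\n",
              x$sigma2_within, x$pct_within))
  cat(sprintf("  Phi = %.4f, p = %.4g (%d permutations)\n",
              x$phi, x$p_value, x$n_perm))
  cat("  distance:", x$distance, "\n")
  invisible(x)
}
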