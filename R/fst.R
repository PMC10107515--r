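#' Weir-Cockerham F_ST at a single site
#'
#' Method-of-moments estimator theta for two (or more) populations of diploid
#' calls, via the variance components a (among populations), b (among
#' individuals within populations) and c (within individuals):
#' `theta = a / (a + b + c)`. Negative estimates are retained; when the
#' denominator is zero the estimate is undefined and returned as `NA` with a
#' reason attribute.
#'
#' @param geno_by_pop list of integer vectors of diploid calls (0/1/2, `NA`
#'   allowed), one vector per population.
#' @return A single numeric estimate, `NA` when undefined. Attribute
#'   `"components"` holds `c(a, b, c)`; attribute `"reason"` explains an
#'   undefined estimate.
#' @export
wc_fst_site <- function(geno_by_pop) {
  if (!is.list(geno_by_pop) || length(geno_by_pop) < 2)
    stop("need genotype vectors for at least two populations")
  geno_by_pop <- lapply(geno_by_pop, function(g) g[!is.na(g)])
  n_i <- vapply(geno_by_pop, length, integer(1))
  if (any(n_i == 0)) {
    out <- NA_real_
    attr(out, "reason") <- "site entirely missing in at least one population"
    return(out)
  }
  r <- length(geno_by_pop)
  p_i <- vapply(geno_by_pop, function(g) sum(g) / (2 * length(g)), numeric(1))
  h_i <- vapply(geno_by_pop, function(g) mean(g == 1L), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc == 0) {
    out <- NA_real_
    attr(out, "reason") <- "all populations are singletons"
    return(out)
  }
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  if (denom == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero total variance (monomorphic site)"
    attr(out, "components") <- c(a = a, b = b, c = cc)
    return(out)
  }
  out <- a / denom
  attr(out, "components") <- c(a = a, b = b, c = cc)
  out
}

#' Per-SNP and global Weir-Cockerham F_ST profile
#'
#' Computes the per-site estimator in input site order, the global value as
#' the unweighted arithmetic mean of the defined per-site estimates (the
#' "average across all SNPs" convention), the ratio-of-sums alternative
#' (sum of a over sum of a+b+c) for reference, and a fixed-bin-width
#' histogram summary.
#'
#' @param G a [genotype_matrix()].
#' @param pops the two population labels, default `c("D", "T")`.
#' @return An `fst_result` list: `per_site`, `global` (mean), `ratio_of_sums`,
#'   `histogram` (data frame with `bin_lo`, `bin_hi`, `count`), `n_defined`.
#' @export
fst_profile <- function(G, pops = c("D", "T")) {
  stopifnot(inherits(G, "genotype_matrix"))
  rows <- lapply(pops, function(p) which(G$pop == p))
  if (any(lengths(rows) == 0))
    stop("populations ", paste(pops, collapse = ", "),
         " must both be present")
  n_site <- ncol(G$geno)
  per_site <- numeric(n_site)
  comp <- matrix(NA_real_, n_site, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (j in seq_len(n_site)) {
    est <- wc_fst_site(lapply(rows, function(rr) G$geno[rr, j]))
    per_site[j] <- as.numeric(est)
    if (!is.null(attr(est, "components"))) comp[j, ] <- attr(est, "components")
  }
  defined <- !is.na(per_site)
  if (!any(defined))
    stop("no site yields a defined F_ST estimate")
  global <- mean(per_site[defined])
  denom <- sum(comp[defined, , drop = FALSE])
  ratio_of_sums <- sum(comp[defined, "a"]) / denom
  lo <- min(0, floor(min(per_site[defined]) / 0.05) * 0.05)
  breaks <- seq(lo, 1, by = 0.05)
  if (max(per_site[defined]) > max(breaks)) breaks <- c(breaks, max(breaks) + 0.05)
  counts <- table(cut(per_site[defined], breaks, include.lowest = TRUE,
                      right = FALSE))
  histogram <- data.frame(bin_lo = breaks[-length(breaks)],
                          bin_hi = breaks[-1],
                          count = as.integer(counts))
  structure(list(per_site = per_site, global = global,
                 ratio_of_sums = ratio_of_sums, histogram = histogram,
                 n_defined = sum(defined)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result>", x$n_defined, "defined per-SNP estimates\n")
  cat(sprintf("  global F_ST (mean of per-SNP): %.4f\n", x$global))
  cat(sprintf("  ratio-of-sums F_ST:            %.4f\n", x$ratio_of_sums))
  invisible(x)
}
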