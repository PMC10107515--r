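# Independent oracles used across the suite. Each is a deliberately direct,
# unoptimized transcription kept separate from the package implementation.

# Weir & Cockerham (1984) theta for two populations of diploid calls,
# transcribed term by term from the published variance components.
oracle_wc_fst <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  r <- 2
  n <- c(length(g1), length(g2))
  p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
  h <- c(mean(g1 == 1), mean(g2 == 1))
  n_bar <- mean(n)
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Brute-force one-level AMOVA from explicit double loops over the squared
# distance matrix (Excoffier sums of squares).
oracle_amova <- function(d2, groups) {
  groups <- factor(groups)
  n <- nrow(d2)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    s <- 0
    if (length(idx) >= 2)
      for (ii in seq_len(length(idx) - 1)) for (jj in (ii + 1):length(idx))
        s <- s + d2[idx[ii], idx[jj]]
    ss_within <- ss_within + s / length(idx)
  }
  ss_among <- ss_total - ss_within
  G <- nlevels(groups)
  ms_among <- ss_among / (G - 1)
  ms_within <- ss_within / (n - G)
  sizes <- as.integer(table(groups))
  n0 <- (n - sum(sizes^2) / n) / (G - 1)
  s2w <- ms_within
  s2a <- (ms_among - ms_within) / n0
  list(sigma2_among = s2a, sigma2_within = s2w,
       phi = s2a / (s2a + s2w), pct_among = 100 * s2a / (s2a + s2w))
}

# Exhaustive enumeration of hypergeometric subsampling: probability that a
# draw of n_to copies from n_from (k derived) contains i derived copies,
# by enumerating all choose(n_from, n_to) subsets.
oracle_projection_row <- function(k, n_from, n_to) {
  copies <- c(rep(1, k), rep(0, n_from - k))
  subsets <- utils::combn(n_from, n_to)
  counts <- apply(subsets, 2, function(ix) sum(copies[ix]))
  vapply(0:n_to, function(i) mean(counts == i), numeric(1))
}

# small deterministic genotype matrix with planted values
toy_genotype_matrix <- function(geno, pop, scaffold = NULL, pos = NULL) {
  n_site <- ncol(geno)
  if (is.null(scaffold)) scaffold <- sprintf("scf%03d", seq_len(n_site))
  if (is.null(pos)) pos <- seq_len(n_site)
  genotype_matrix(geno, scaffold = scaffold, pos = pos, pop = pop)
}

# random small genotype matrix with missingness
random_genotype_matrix <- function(n_ind, n_site, p_missing = 0.1,
                                   pop = NULL, n_scaffold = NULL) {
  g <- matrix(sample(c(0:2, NA), n_ind * n_site, replace = TRUE,
                     prob = c((1 - p_missing) * c(0.4, 0.3, 0.3), p_missing)),
              n_ind, n_site)
  if (is.null(pop)) pop <- rep(c("D", "T"), length.out = n_ind)
  if (is.null(n_scaffold)) n_scaffold <- n_site
  scaffold <- sprintf("scf%03d", sample.int(n_scaffold, n_site, replace = TRUE))
  genotype_matrix(g, scaffold = scaffold,
                  pos = sample.int(1000, n_site, replace = TRUE), pop = pop)
}
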