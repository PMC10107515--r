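# Core EM for the K = 2 admixture model with an inbreeding-aware genotype
# emission. Generative model per individual i, locus l: with probability
# F_ibd the two gene copies are identical by descent (one cluster draw
# k ~ Bern(q_i), one allele draw duplicated); otherwise each copy
# independently picks a cluster and an allele, so the genotype is
# Binomial(2, x) with x = q_i p1_l + (1 - q_i) p2_l. F_ibd = 0 recovers the
# standard admixture likelihood. Missing calls are skipped. All E/M updates
# are closed-form; see the methods vignette for the derivation.
admixture_em <- function(geno, q0, p1, p2, F_ibd = 0, tol = 1e-6,
                         max_iter = 2000L, lambda = 1) {
  eps <- 1e-9
  G <- geno
  storage.mode(G) <- "double"
  obs <- !is.na(G)
  G0 <- G
  G0[!obs] <- 0
  two_obs <- 2 * obs
  is0 <- (G0 == 0) & obs
  is2 <- (G0 == 2) & obs
  n <- nrow(G); L <- ncol(G)
  q <- q0
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P1 <- matrix(p1, n, L, byrow = TRUE)
    P2 <- matrix(p2, n, L, byrow = TRUE)
    X <- q * P1 + (1 - q) * P2
    X <- pmin(pmax(X, eps), 1 - eps)
    # emission probabilities
    pr_not <- is0 * (1 - X)^2 + (G0 == 1) * obs * 2 * X * (1 - X) +
      is2 * X^2
    ibd0 <- q * (1 - P1) + (1 - q) * (1 - P2)   # P(g = 0 | IBD)
    ibd2 <- q * P1 + (1 - q) * P2               # P(g = 2 | IBD) = X
    pr_ibd <- is0 * ibd0 + is2 * ibd2           # g = 1 impossible under IBD
    pr <- F_ibd * pr_ibd + (1 - F_ibd) * pr_not
    pr[!obs] <- 1
    pr <- pmax(pr, 1e-300)
    ll <- sum(log(pr[obs]))

    # E-step
    w <- (F_ibd * pr_ibd) / pr                  # P(IBD | g), 0 where g = 1
    w[!obs] <- 0
    # IBD branch: posterior that the single cluster draw was cluster 1
    g1_ibd <- is0 * (q * (1 - P1)) / pmax(ibd0, eps) +
      is2 * (q * P1) / pmax(ibd2, eps)
    # non-IBD branch: expected copies attributed to cluster 1
    A <- G0 * (q * P1) / pmax(q * P1 + (1 - q) * P2, eps)       # alt copies
    B <- (two_obs - G0) * (q * (1 - P1)) /
      pmax(q * (1 - P1) + (1 - q) * (1 - P2), eps)              # ref copies
    A[!obs] <- 0; B[!obs] <- 0

    # M-step: cluster-draw bookkeeping (IBD loci contribute one draw,
    # non-IBD loci two)
    draws1 <- w * g1_ibd + (1 - w) * (A + B)
    draws_tot <- w * obs + (1 - w) * two_obs
    q <- rowSums(draws1) / pmax(rowSums(draws_tot), eps)
    q <- pmin(pmax(q, 0), 1)
    # Dirichlet(lambda, lambda) smoothing keeps cluster frequencies off the
    # boundary: a single unseen allele must not make Q = 1 impossible
    alt1 <- w * g1_ibd * is2 + (1 - w) * A
    p1 <- (colSums(alt1) + lambda) / (colSums(draws1) + 2 * lambda)
    draws2 <- draws_tot - draws1
    alt2 <- w * (1 - g1_ibd) * is2 + (1 - w) * (G0 - A)
    p2 <- (colSums(alt2) + lambda) / (colSums(draws2) + 2 * lambda)
    p1 <- pmin(pmax(p1, eps), 1 - eps)
    p2 <- pmin(pmax(p2, eps), 1 - eps)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(q = q, p1 = p1, p2 = p2, loglik = ll, iter = iter,
       converged = converged)
}

# Exact per-individual ML of Q given fixed cluster frequencies: the
# per-locus genotype probability is a quadratic polynomial in q under both
# emission branches, so the profile likelihood is evaluated on a coarse grid
# (boundaries included) and refined twice around the maximum.
q_profile_ml <- function(gvec, p1, p2, F_ibd) {
  obs <- !is.na(gvec)
  if (!any(obs)) return(c(q = NA_real_))
  g <- gvec[obs]; a1 <- p1[obs]; a2 <- p2[obs]
  d <- a1 - a2
  # binomial branch: X = a2 + q d
  # IBD branch: P(0) = (1-a2) - q d; P(2) = a2 + q d; P(1) = 0
  ll_of <- function(qs) {
    X <- outer(qs, d) + rep(a2, each = length(qs))
    X <- pmin(pmax(X, 1e-9), 1 - 1e-9)
    G <- matrix(g, length(qs), length(g), byrow = TRUE)
    pr_not <- (G == 0) * (1 - X)^2 + (G == 1) * 2 * X * (1 - X) +
      (G == 2) * X^2
    pr_ibd <- (G == 0) * (1 - X) + (G == 2) * X
    rowSums(log(pmax(F_ibd * pr_ibd + (1 - F_ibd) * pr_not, 1e-300)))
  }
  qs <- seq(0, 1, length.out = 101)
  step <- qs[2] - qs[1]
  for (round in 1:3) {
    ll <- ll_of(qs)
    qb <- qs[which.max(ll)]
    lo <- max(0, qb - step); hi <- min(1, qb + step)
    qs <- seq(lo, hi, length.out = 21)
    step <- qs[2] - qs[1]
  }
  qb
}

# Profile-likelihood interval for Q at fixed cluster frequencies: all q whose
# log-likelihood lies within chi-square(1)/2 of the maximum (LR inversion).
# Attains 0 or 1 exactly when purity cannot be rejected at the given level.
q_profile_interval <- function(gvec, p1, p2, F_ibd, level = 0.90,
                               n_grid = 1001L) {
  obs <- !is.na(gvec)
  if (!any(obs)) return(c(q = 0.5, lo = 0, hi = 1))
  g <- gvec[obs]; a1 <- p1[obs]; a2 <- p2[obs]
  d <- a1 - a2
  qs <- seq(0, 1, length.out = n_grid)
  X <- outer(qs, d) + rep(a2, each = n_grid)
  X <- pmin(pmax(X, 1e-9), 1 - 1e-9)
  G <- matrix(g, n_grid, length(g), byrow = TRUE)
  pr_not <- (G == 0) * (1 - X)^2 + (G == 1) * 2 * X * (1 - X) + (G == 2) * X^2
  pr_ibd <- (G == 0) * (1 - X) + (G == 2) * X
  ll <- rowSums(log(pmax(F_ibd * pr_ibd + (1 - F_ibd) * pr_not, 1e-300)))
  cut <- max(ll) - stats::qchisq(level, df = 1) / 2
  inside <- which(ll >= cut)
  c(q = qs[which.max(ll)], lo = qs[min(inside)], hi = qs[max(inside)])
}

# draw genotypes from the fitted admixture model (bootstrap resampling)
simulate_admixture_geno <- function(q, p1, p2, F_ibd, obs) {
  n <- length(q); L <- length(p1)
  P1 <- matrix(p1, n, L, byrow = TRUE)
  P2 <- matrix(p2, n, L, byrow = TRUE)
  ibd <- matrix(runif(n * L) < F_ibd, n, L)
  # IBD: one cluster draw, one allele draw duplicated
  k1 <- matrix(runif(n * L) < q, n, L)
  pk <- ifelse(k1, P1, P2)
  g_ibd <- 2L * (matrix(runif(n * L), n, L) < pk)
  # non-IBD: two independent copies
  ka <- matrix(runif(n * L) < q, n, L)
  kb <- matrix(runif(n * L) < q, n, L)
  ga <- matrix(runif(n * L), n, L) < ifelse(ka, P1, P2)
  gb <- matrix(runif(n * L), n, L) < ifelse(kb, P1, P2)
  g <- ifelse(ibd, g_ibd, ga + gb)
  g[!obs] <- NA_integer_
  storage.mode(g) <- "integer"
  g
}

#' K = 2 admixture-proportion estimation with bootstrap intervals
#'
#' Maximum-likelihood admixture model: each individual's gene copies at a
#' locus derive from cluster 1 with probability `Q_i`, with cluster-specific
#' allele frequencies; `Q` and the frequencies are estimated jointly by
#' expectation-maximization. The genotype emission includes an
#' identity-by-descent branch with probability `F_ibd` (both copies share
#' one cluster and allele draw), accommodating the excess homozygosity of
#' selfing populations; `F_ibd = 0` gives the standard binomial admixture
#' likelihood. Ninety-percent intervals come from a parametric bootstrap
#' (genotypes resampled from the fitted model, EM refit per replicate,
#' percentile interval). Label switching is resolved by forcing cluster 1 to
#' be the majority cluster among individuals labeled `"D"`. An individual is
#' flagged a nonhybrid when its interval overlaps 0 or 1 (within `epsilon`),
#' the interval-overlap rule used to call pure parentals.
#'
#' Two interval constructions are available. `"profile"` (default) inverts
#' the likelihood-ratio test for `Q` at the fitted cluster frequencies; it
#' attains the boundary exactly when purity cannot be rejected, which is the
#' scientific content of the interval-overlap rule. `"bootstrap"` is the
#' parametric-bootstrap percentile interval; note that resampling from an
#' interior point estimate can never recover the boundary, so the percentile
#' construction systematically under-covers there.
#'
#' @param G a [genotype_matrix()].
#' @param K number of clusters; only 2 is supported.
#' @param F_ibd inbreeding (identity-by-descent) probability of the genotype
#'   emission, in `[0, 1)`.
#' @param interval `"profile"` or `"bootstrap"`.
#' @param seed integer seed (initialization and bootstrap).
#' @param n_boot parametric-bootstrap replicates (>= 200 recommended; only
#'   used for `interval = "bootstrap"`).
#' @param level interval coverage, default 0.90.
#' @param epsilon numerical guard for the interval-overlap rule.
#' @param tol,max_iter EM convergence controls (absolute log-likelihood
#'   change; iteration cap). Non-convergence is flagged, not silent.
#' @return An `admixture_result` list: `table` (data frame with `sample`,
#'   `pop`, `Q`, `lo`, `hi`, `nonhybrid`), `p1`, `p2`, `loglik`, `converged`.
#' @export
estimate_admixture <- function(G, K = 2, F_ibd = 0,
                               interval = c("profile", "bootstrap"),
                               seed = 1, n_boot = 200,
                               level = 0.90, epsilon = 1e-6,
                               tol = 1e-6, max_iter = 2000L) {
  stopifnot(inherits(G, "genotype_matrix"))
  interval <- match.arg(interval)
  if (K != 2) stop("only K = 2 is supported")
  if (F_ibd < 0 || F_ibd >= 1) stop("F_ibd must lie in [0, 1)")
  if (nrow(G$geno) < 2) stop("need at least two individuals")
  geno <- G$geno
  alpha <- (1 - level) / 2

  withr::with_seed(seed, {
    # moment-based initialization plus jitter
    freq <- colMeans(geno, na.rm = TRUE) / 2
    freq[is.na(freq)] <- 0.5
    p1 <- pmin(pmax(freq + runif(ncol(geno), 0.05, 0.25), 0.01), 0.99)
    p2 <- pmin(pmax(freq - runif(ncol(geno), 0.05, 0.25), 0.01), 0.99)
    q0 <- runif(nrow(geno), 0.25, 0.75)
    fit <- admixture_em(geno, q0, p1, p2, F_ibd = F_ibd, tol = tol,
                        max_iter = max_iter)

    # anchor cluster 1 to population D
    if (any(G$pop == "D") && mean(fit$q[G$pop == "D"]) < 0.5) {
      fit$q <- 1 - fit$q
      tmp <- fit$p1; fit$p1 <- fit$p2; fit$p2 <- tmp
    }
    # profile ML of Q per individual at the fitted frequencies (the EM path
    # for Q flattens near the boundary; the grid maximizer is exact)
    n <- nrow(geno)
    fit$q <- vapply(seq_len(n), function(i)
      q_profile_ml(geno[i, ], fit$p1, fit$p2, F_ibd), numeric(1))
    fit$q[is.na(fit$q)] <- 0.5

    if (interval == "profile") {
      ivl <- t(vapply(seq_len(n), function(i)
        q_profile_interval(geno[i, ], fit$p1, fit$p2, F_ibd, level = level),
        numeric(3)))
      lo <- ivl[, "lo"]
      hi <- ivl[, "hi"]
    } else {
      # parametric bootstrap; cluster frequencies held at their estimates
      # (their sampling error is second-order for per-individual intervals)
      obs <- !is.na(geno)
      Qboot <- matrix(NA_real_, n_boot, n)
      for (b in seq_len(n_boot)) {
        gb <- simulate_admixture_geno(fit$q, fit$p1, fit$p2, F_ibd, obs)
        Qboot[b, ] <- vapply(seq_len(n), function(i)
          q_profile_ml(gb[i, ], fit$p1, fit$p2, F_ibd), numeric(1))
      }
      Qboot[is.na(Qboot)] <- 0.5
      lo <- apply(Qboot, 2, quantile, probs = alpha, names = FALSE)
      hi <- apply(Qboot, 2, quantile, probs = 1 - alpha, names = FALSE)
    }
  })
  lo <- pmin(lo, fit$q)
  hi <- pmax(hi, fit$q)
  nonhybrid <- (lo <= epsilon) | (hi >= 1 - epsilon)
  tab <- data.frame(sample = G$samples, pop = as.character(G$pop),
                    Q = fit$q, lo = lo, hi = hi, nonhybrid = nonhybrid,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, p1 = fit$p1, p2 = fit$p2,
                 loglik = fit$loglik, converged = fit$converged,
                 iterations = fit$iter, F_ibd = F_ibd, level = level,
                 epsilon = epsilon),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat("<admixture_result> K = 2,", nrow(x$table), "individuals, F_ibd =",
      x$F_ibd, "\n")
  cat(sprintf("  log-likelihood: %.2f (%s, %d iterations)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  nonhybrid rule (interval overlapping 0 or 1): %d / %d\n",
              sum(x$table$nonhybrid), nrow(x$table)))
  invisible(x)
}
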