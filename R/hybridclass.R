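# gene-origin proportions over ancestry pairs (DD, DT, TT) for the six
# hybrid categories; Mendelian consequences of the category definitions
hybrid_category_phi <- function() {
  rbind(PureD = c(1, 0, 0),
        PureT = c(0, 0, 1),
        F1    = c(0, 1, 0),
        F2    = c(0.25, 0.5, 0.25),
        BC_D  = c(0.5, 0.5, 0),
        BC_T  = c(0, 0.5, 0.5))
}

# P(genotype g | ancestry pair, parental freqs): columns g = 0, 1, 2
pair_genotype_probs <- function(pD, pT) {
  list(
    DD = cbind((1 - pD)^2, 2 * pD * (1 - pD), pD^2),
    DT = cbind((1 - pD) * (1 - pT), pD * (1 - pT) + pT * (1 - pD), pD * pT),
    TT = cbind((1 - pT)^2, 2 * pT * (1 - pT), pT^2)
  )
}

#' Six-category hybrid-class posterior assignment
#'
#' NewHybrids-style classifier: each of six categories (PureD, PureT, F1, F2,
#' BC_D, BC_T) is defined by fixed gene-origin proportions over the ancestry
#' pairs (D,D), (D,T), (T,T); the per-locus genotype likelihood of an
#' individual in a category mixes Hardy-Weinberg genotype probabilities over
#' those pairs using the parental allele frequencies. Parental frequencies
#' are initialized from the labeled populations and refined by a small number
#' of classification-EM passes in which individuals contribute to a parental
#' pool in proportion to their posterior probability of being pure. The
#' posterior uses a uniform prior over the six categories.
#'
#' @param G a [genotype_matrix()] with populations `"D"` and `"T"` present
#'   (additional individuals, e.g. putative hybrids, may carry other labels).
#' @param prior numeric vector of six category prior probabilities (default
#'   uniform).
#' @param n_em number of parental-frequency refinement passes.
#' @param seed accepted for interface symmetry; the estimator is
#'   deterministic.
#' @return A `hybrid_posterior` list: `posterior` (individuals x 6, rows sum
#'   to 1), `map` (MAP category per individual), `flagged` (individuals with
#'   all loci missing, given a uniform posterior), `p_D`, `p_T`.
#' @export
classify_hybrids <- function(G, prior = rep(1 / 6, 6), n_em = 5L, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!any(G$pop == "D") || !any(G$pop == "T"))
    stop("both parental gene pools ('D' and 'T') must be represented")
  if (length(prior) != 6 || any(prior < 0) || sum(prior) == 0)
    stop("prior must be six non-negative values")
  prior <- prior / sum(prior)
  phi <- hybrid_category_phi()
  cats <- rownames(phi)
  geno <- G$geno
  n <- nrow(geno); L <- ncol(geno)

  # smoothed parental frequency estimate from weighted genotype sums
  wfreq <- function(w) {
    w <- as.vector(w)
    alt <- colSums(geno * w, na.rm = TRUE)
    tot <- colSums(2 * (!is.na(geno)) * w)
    (alt + 0.5) / (tot + 1)
  }
  pD <- wfreq(as.numeric(G$pop == "D"))
  pT <- wfreq(as.numeric(G$pop == "T"))

  post <- NULL
  for (pass in seq_len(n_em + 1L)) {
    pg <- pair_genotype_probs(pD, pT)
    # per-category log-likelihood for every individual
    logL <- matrix(0, n, 6, dimnames = list(G$samples, cats))
    for (k in seq_along(cats)) {
      # mixture over ancestry pairs per locus: L x 3 matrix of P(g | cat)
      mix <- phi[k, 1] * pg$DD + phi[k, 2] * pg$DT + phi[k, 3] * pg$TT
      mix <- pmax(mix, 1e-300)
      lp <- log(mix)
      # index per-individual genotypes into the L x 3 table
      for (g in 0:2) {
        idx <- which(geno == g, arr.ind = TRUE)
        if (nrow(idx))
          logL[, k] <- logL[, k] +
            rowsum_by(lp[cbind(idx[, 2], g + 1L)], idx[, 1], n)
      }
    }
    lpost <- sweep(logL, 2, log(prior), `+`)
    lpost <- lpost - apply(lpost, 1, max)
    post <- exp(lpost)
    post <- post / rowSums(post)
    if (pass > n_em) break
    # refine parental pools with posterior-pure weights
    pD <- wfreq(post[, "PureD"])
    pT <- wfreq(post[, "PureT"])
  }
  all_missing <- rowSums(!is.na(geno)) == 0
  if (any(all_missing)) post[all_missing, ] <- 1 / 6
  map <- cats[max.col(post, ties.method = "first")]
  structure(list(posterior = post, map = setNames(map, G$samples),
                 flagged = G$samples[all_missing], p_D = pD, p_T = pT,
                 prior = prior),
            class = "hybrid_posterior")
}

# sum values by integer group index into a vector of length n
rowsum_by <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.hybrid_posterior <- function(x, ...) {
  cat("<hybrid_posterior>", nrow(x$posterior), "individuals\n")
  print(table(factor(x$map, levels = colnames(x$posterior))))
  if (length(x$flagged))
    cat("  flagged (all loci missing):", paste(x$flagged, collapse = ", "),
        "\n")
  invisible(x)
}

#' Combined nonhybrid verdict from admixture and six-class analyses
#'
#' Joins the interval-overlap nonhybrid rule from [estimate_admixture()] with
#' the MAP category from [classify_hybrids()]. Disagreements between the two
#' analyses are reported, not resolved.
#'
#' @param admix an `admixture_result`.
#' @param hyb a `hybrid_posterior`.
#' @return A `nonhybrid_report` data frame with per-individual columns
#'   `sample`, `pop`, `Q`, `lo`, `hi`, `admix_nonhybrid`, `map_category`,
#'   `map_pure`, `verdict` (one of `"nonhybrid"`, `"hybrid"`,
#'   `"disagreement"`); category counts in attribute `"counts"`.
#' @export
nonhybrid_report <- function(admix, hyb) {
  stopifnot(inherits(admix, "admixture_result"),
            inherits(hyb, "hybrid_posterior"))
  tab <- admix$table
  if (!identical(tab$sample, rownames(hyb$posterior)))
    stop("admixture and hybrid-posterior results cover different samples")
  map <- hyb$map[tab$sample]
  map_pure <- map %in% c("PureD", "PureT")
  verdict <- ifelse(tab$nonhybrid & map_pure, "nonhybrid",
                    ifelse(!tab$nonhybrid & !map_pure, "hybrid",
                           "disagreement"))
  out <- data.frame(tab[, c("sample", "pop", "Q", "lo", "hi")],
                    admix_nonhybrid = tab$nonhybrid,
                    map_category = unname(map), map_pure = map_pure,
                    verdict = verdict, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(map, levels = colnames(hyb$posterior)))
  class(out) <- c("nonhybrid_report", "data.frame")
  out
}
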