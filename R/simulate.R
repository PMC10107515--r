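#' Simulation configuration
#'
#' Sampling-design parameters for the synthetic contact-zone generator. The
#' defaults mirror the study design the package is built around: 45 diploid
#' and 50 tetraploid individuals scored at 356 unlinked biallelic SNPs, each
#' on its own scaffold, with GBS-like sparsity.
#'
#' @param n_D,n_T numbers of diploid-coded individuals per population (>= 2).
#' @param n_sites number of unlinked biallelic SNPs to emit (>= 1).
#' @param site_missing_rate,indiv_missing_rate per-call masking probabilities
#'   in `[0, 1)`; a call is masked if either the site-level or the
#'   individual-level coin fires, so the expected masked fraction is the
#'   combined rate.
#' @param maf_min minimum overall minor-allele frequency for a site to be
#'   emitted, emulating the discovery bias of reduced-representation SNP
#'   panels (rare variants are systematically under-recovered). Set to 0 for
#'   an unascertained site-frequency spectrum.
#' @param n_panel gene copies per deme in the coalescent frequency panel from
#'   which population allele frequencies are read.
#' @param seed integer seed; every random draw in the generator derives from
#'   it.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_D = 45, n_T = 50, n_sites = 356,
                              site_missing_rate = 0.10,
                              indiv_missing_rate = 0.05,
                              maf_min = 0.15,
                              n_panel = 200, seed = 1) {
  if (n_D < 2 || n_T < 2) stop("n_D and n_T must be >= 2")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (site_missing_rate < 0 || site_missing_rate >= 1 ||
      indiv_missing_rate < 0 || indiv_missing_rate >= 1)
    stop("missingness rates must lie in [0, 1)")
  if (n_panel < 10) stop("n_panel must be >= 10")
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must lie in [0, 0.5)")
  structure(
    list(n_D = as.integer(n_D), n_T = as.integer(n_T),
         n_sites = as.integer(n_sites),
         site_missing_rate = site_missing_rate,
         indiv_missing_rate = indiv_missing_rate,
         maf_min = maf_min,
         n_panel = as.integer(n_panel), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' The study-condition demographic model
#'
#' Constant gene flow between a diploid and a tetraploid population with the
#' parameter values inferred for the contact zone the package emulates:
#' slightly smaller tetraploid population (`nu = (1.0, 0.8)`), fewer than one
#' migrant per generation in each direction (`M_DT = 0.3`, `M_TD = 0.4`),
#' high fixed inbreeding (`F_D = 0.81`, `F_T = 0.75`), and a split time
#' (`T0 = 2.5`) calibrated once so that, together with the default
#' discovery-bias ascertainment of [simulation_config()], the realized
#' global Weir-Cockerham F_ST of the synthetic panel falls in the strong
#' divergence regime (about 0.4-0.5) with a bimodal per-SNP distribution.
#'
#' @return A [demographic_model()].
#' @export
study_model <- function() {
  demographic_model("constant_gene_flow", nu_D = 1.0, nu_T = 0.8, T0 = 2.5,
                    M_DT = 0.3, M_TD = 0.4, F_D = 0.81, F_T = 0.75)
}

# genotype class probabilities given allele frequency p and inbreeding F:
# P(0) = (1-p)^2 + F p (1-p); P(1) = 2 p (1-p) (1-F); P(2) = p^2 + F p (1-p)
genotype_class_probs <- function(p, F) {
  pq <- p * (1 - p)
  cbind(p0 = (1 - p)^2 + F * pq,
        p1 = 2 * pq * (1 - F),
        p2 = p^2 + F * pq)
}

# draw an n_ind x n_sites genotype block given per-site frequency p
draw_genotypes <- function(p, F, n_ind) {
  pr <- genotype_class_probs(p, F)
  u <- matrix(runif(n_ind * length(p)), n_ind, length(p))
  thr0 <- matrix(pr[, 1], n_ind, length(p), byrow = TRUE)
  thr1 <- matrix(pr[, 1] + pr[, 2], n_ind, length(p), byrow = TRUE)
  g <- (u >= thr0) + (u >= thr1)
  storage.mode(g) <- "integer"
  g
}

#' Simulate a two-population SNP genotype matrix with known truth
#'
#' Each site is an independent realization of the two-population structured
#' coalescent under `model`: a frequency panel of `config$n_panel` gene copies
#' per deme is simulated, a mutation is placed uniformly on the genealogy's
#' branches, and the panel-derived allele frequencies `(p_D, p_T)` are read
#' off. Individual genotypes are then drawn independently given the local
#' frequency, with inbreeding entering as genotype-level excess homozygosity:
#' `P(het) = 2 p (1 - p) (1 - F)`. Only sites segregating in the emitted
#' genotype sample are retained; non-segregating draws are resampled up to a
#' bounded budget.
#'
#' @param model a [demographic_model()].
#' @param config a [simulation_config()].
#' @param max_rounds resampling budget: maximum number of candidate batches
#'   (each of `n_sites` draws) before giving up.
#' @return A list with components `G` (a [genotype_matrix()]) and `truth`
#'   (a `truth_record`: the model, the config, realized panel frequencies per
#'   retained site, and the per-individual true category).
#' @export
simulate_genotypes <- function(model, config = simulation_config(),
                               max_rounds = 50L) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(config, "simulation_config"))
  epochs <- model_epochs(model)
  n_pan <- config$n_panel
  withr::with_seed(config$seed, {
    engine_seed <- sample.int(.Machine$integer.max, 1)
    keep_p <- matrix(NA_real_, 2, 0)
    gD <- matrix(NA_integer_, config$n_D, 0)
    gT <- matrix(NA_integer_, config$n_T, 0)
    round <- 0L
    while (ncol(gD) < config$n_sites) {
      round <- round + 1L
      if (round > max_rounds)
        stop("could not obtain ", config$n_sites, " segregating sites within ",
             max_rounds, " resampling rounds; the model may be a ",
             "non-segregating corner case")
      cfgs <- coal_sample_sites(n_pan, n_pan, epochs, config$n_sites,
                                engine_seed + round)
      pD <- cfgs[, 1] / n_pan
      pT <- cfgs[, 2] / n_pan
      bD <- draw_genotypes(pD, model$F_D, config$n_D)
      bT <- draw_genotypes(pT, model$F_T, config$n_T)
      tot <- colSums(bD) + colSums(bT)
      copies <- 2 * (config$n_D + config$n_T)
      maf <- pmin(tot, copies - tot) / copies
      seg <- tot > 0 & tot < copies & maf >= config$maf_min
      if (any(seg)) {
        gD <- cbind(gD, bD[, seg, drop = FALSE])
        gT <- cbind(gT, bT[, seg, drop = FALSE])
        keep_p <- cbind(keep_p, rbind(pD[seg], pT[seg]))
      }
    }
    sel <- seq_len(config$n_sites)
    gD <- gD[, sel, drop = FALSE]
    gT <- gT[, sel, drop = FALSE]
    keep_p <- keep_p[, sel, drop = FALSE]
    scaffold <- sprintf("scaffold_%05d", sel)
    pos <- sample.int(100000L, config$n_sites, replace = TRUE)
    samples <- c(sprintf("D_%03d", seq_len(config$n_D)),
                 sprintf("T_%03d", seq_len(config$n_T)))
    G <- genotype_matrix(rbind(gD, gT), scaffold = scaffold, pos = pos,
                         pop = rep(c("D", "T"), c(config$n_D, config$n_T)),
                         samples = samples)
  })
  rownames(keep_p) <- c("D", "T")
  truth <- structure(
    list(model = model, config = config, freq = keep_p,
         category = setNames(rep(c("pure_D", "pure_T"),
                                 c(config$n_D, config$n_T)), G$samples)),
    class = "truth_record")
  list(G = G, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record>", length(x$category), "individuals,",
      ncol(x$freq), "sites; model:", x$model$family, "\n")
  print(table(x$category))
  invisible(x)
}

# one Mendelian gamete per locus from a diploid genotype vector (NA -> draw
# from the population panel frequency as fallback)
mendelian_gamete <- function(geno, fallback_p) {
  pr <- geno / 2
  na <- is.na(pr)
  if (any(na)) pr[na] <- fallback_p[na]
  as.integer(runif(length(pr)) < pr)
}

#' Inject known hybrid individuals into a simulated panel
#'
#' Appends positive-control hybrids built by Mendelian gamete sampling from
#' randomly chosen parental genotypes: F1 = gamete(D) + gamete(T); F2 = a
#' cross of two internally generated F1s; BC_D / BC_T = F1 backcrossed to a
#' random parent from the respective population. Injected individuals carry
#' population label `"HYB"`; their true categories are recorded in the truth
#' record.
#'
#' @param G a [genotype_matrix()] containing populations `"D"` and `"T"`.
#' @param truth the matching `truth_record`.
#' @param counts named integer vector with any of the names
#'   `"F1"`, `"F2"`, `"BC_D"`, `"BC_T"`.
#' @param seed integer seed.
#' @return A list with updated `G` and `truth`.
#' @export
inject_hybrids <- function(G, truth, counts = c(F1 = 5), seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(truth, "truth_record"))
  bad <- setdiff(names(counts), c("F1", "F2", "BC_D", "BC_T"))
  if (length(bad)) stop("unknown hybrid categories: ",
                        paste(bad, collapse = ", "))
  idx_D <- which(G$pop == "D")
  idx_T <- which(G$pop == "T")
  if (!length(idx_D) || !length(idx_T))
    stop("both parental populations must be non-empty to inject hybrids")
  pD <- truth$freq["D", ]
  pT <- truth$freq["T", ]
  new_rows <- list()
  new_names <- character(0)
  new_cat <- character(0)
  withr::with_seed(seed, {
    make_f1 <- function() {
      d <- G$geno[sample(idx_D, 1), ]
      t <- G$geno[sample(idx_T, 1), ]
      mendelian_gamete(d, pD) + mendelian_gamete(t, pT)
    }
    pH <- (pD + pT) / 2  # fallback frequency for hybrid-parent missing calls
    for (cat in names(counts)) {
      for (r in seq_len(counts[[cat]])) {
        g <- switch(cat,
          F1 = make_f1(),
          F2 = mendelian_gamete(make_f1(), pH) + mendelian_gamete(make_f1(), pH),
          BC_D = mendelian_gamete(make_f1(), pH) +
                 mendelian_gamete(G$geno[sample(idx_D, 1), ], pD),
          BC_T = mendelian_gamete(make_f1(), pH) +
                 mendelian_gamete(G$geno[sample(idx_T, 1), ], pT))
        new_rows[[length(new_rows) + 1L]] <- as.integer(g)
        new_names <- c(new_names, sprintf("%s_%02d", cat, r))
        new_cat <- c(new_cat, cat)
      }
    }
  })
  if (!length(new_rows)) return(list(G = G, truth = truth))
  H <- do.call(rbind, new_rows)
  G2 <- genotype_matrix(rbind(G$geno, H),
                        scaffold = G$scaffold, pos = G$pos,
                        pop = c(as.character(G$pop), rep("HYB", nrow(H))),
                        samples = c(G$samples, new_names))
  truth$category <- c(truth$category, setNames(new_cat, new_names))
  list(G = G2, truth = truth)
}

#' Mask genotype calls with GBS-like missingness
#'
#' Every call is masked independently: a site-level coin with probability
#' `site_missing_rate` and an individual-level coin with probability
#' `indiv_missing_rate`, so the expected masked fraction is their combined
#' rate. Fully masked individuals remain in the matrix as all-missing rows.
#'
#' @param G a [genotype_matrix()].
#' @param config a [simulation_config()] carrying the two rates.
#' @param seed integer seed.
#' @return The masked `genotype_matrix`.
#' @export
apply_missingness <- function(G, config, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(config, "simulation_config"))
  rate <- 1 - (1 - config$site_missing_rate) * (1 - config$indiv_missing_rate)
  if (rate == 0) return(G)
  geno <- G$geno
  withr::with_seed(seed, {
    mask <- matrix(runif(length(geno)) < rate, nrow(geno), ncol(geno))
  })
  geno[mask] <- NA_integer_
  genotype_matrix(geno, G$scaffold, G$pos, G$pop, G$samples)
}

#' Simulate a marker-sequence alignment with fixed inter-group differences
#'
#' Builds an ITS-like alignment of `n_D + n_T` sequences: exactly
#' `n_fixed_diffs` columns are fixed for different bases between the two
#' groups, a Poisson(`singleton_rate * length`) number of columns carry a
#' singleton substitution in one random sequence, and all remaining columns
#' are invariant.
#'
#' @param n_D,n_T group sizes.
#' @param length alignment length in columns.
#' @param n_fixed_diffs number of fixed inter-group difference columns.
#' @param singleton_rate per-column singleton substitution rate.
#' @param seed integer seed.
#' @return A `marker_alignment`: character matrix (rows = sequences, lowercase
#'   bases) with a `groups` attribute.
#' @export
simulate_marker_alignment <- function(n_D = 26, n_T = 36, length = 658,
                                      n_fixed_diffs = 58,
                                      singleton_rate = 0.01, seed = 1) {
  if (n_fixed_diffs > length)
    stop("impossible column budget: n_fixed_diffs (", n_fixed_diffs,
         ") exceeds alignment length (", length, ")")
  bases <- c("a", "c", "g", "t")
  withr::with_seed(seed, {
    cons <- sample(bases, length, replace = TRUE)
    aln <- matrix(rep(cons, each = n_D + n_T), n_D + n_T, length)
    n_single <- rpois(1, singleton_rate * length)
    if (n_fixed_diffs + n_single > length)
      stop("impossible column budget: ", n_fixed_diffs, " fixed + ",
           n_single, " singleton columns exceed alignment length ", length)
    special <- sample.int(length, n_fixed_diffs + n_single)
    fixed_cols <- special[seq_len(n_fixed_diffs)]
    single_cols <- special[-seq_len(n_fixed_diffs)]
    for (j in fixed_cols) {
      two <- sample(bases, 2)
      aln[seq_len(n_D), j] <- two[1]
      aln[n_D + seq_len(n_T), j] <- two[2]
    }
    for (j in single_cols) {
      i <- sample.int(n_D + n_T, 1)
      aln[i, j] <- sample(setdiff(bases, aln[i, j]), 1)
    }
  })
  rownames(aln) <- c(sprintf("D_%03d", seq_len(n_D)),
                     sprintf("T_%03d", seq_len(n_T)))
  structure(aln,
            groups = factor(rep(c("D", "T"), c(n_D, n_T))),
            class = c("marker_alignment", "matrix"))
}

#' @export
print.marker_alignment <- function(x, ...) {
  g <- attr(x, "groups")
  cat("<marker_alignment>", nrow(x), "sequences x", ncol(x), "columns;",
      "groups:", paste(sprintf("%s=%d", levels(g), tabulate(g)),
                       collapse = ", "), "\n")
  invisible(x)
}
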