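test_that("generation is bit-reproducible given the seed", {
  m <- study_model()
  cfg <- simulation_config(n_D = 8, n_T = 8, n_sites = 40, seed = 9)
  a <- simulate_genotypes(m, cfg)
  b <- simulate_genotypes(m, cfg)
  expect_identical(a$G$geno, b$G$geno)
  expect_identical(a$truth$freq, b$truth$freq)
  cfg2 <- simulation_config(n_D = 8, n_T = 8, n_sites = 40, seed = 10)
  expect_false(identical(simulate_genotypes(m, cfg2)$G$geno, a$G$geno))
})

test_that("complete inbreeding yields zero heterozygous calls", {
  m <- demographic_model("constant_gene_flow", nu_D = 1, nu_T = 1, T0 = 1,
                         M_DT = 0.5, M_TD = 0.5, F_D = 1, F_T = 1)
  sim <- simulate_genotypes(m, simulation_config(n_D = 10, n_T = 10,
                                                 n_sites = 200, maf_min = 0,
                                                 seed = 2))
  expect_identical(sum(sim$G$geno == 1L, na.rm = TRUE), 0L)
})

test_that("deep isolation drives almost all sites to fixed differences", {
  # interdeme branch length ~ 2 * T0 dominates the within-deme tree length
  # (~4 * harmonic(n)) only for very old splits
  m <- demographic_model("no_gene_flow", nu_D = 1, nu_T = 1, T0 = 200)
  sim <- simulate_genotypes(m, simulation_config(n_D = 20, n_T = 20,
                                                 n_sites = 300, maf_min = 0,
                                                 seed = 4))
  ac <- allele_counts(sim$G)
  fD <- ac$alt["D", ] / ac$called["D", ]
  fT <- ac$alt["T", ] / ac$called["T", ]
  fixed <- (fD == 0 & fT == 1) | (fD == 1 & fT == 0)
  expect_gt(mean(fixed), 0.9)
})

test_that("genotype draws honour the inbreeding-adjusted Hardy-Weinberg law", {
  # P(het) = 2 p (1 - p) (1 - F): check within binomial bounds at fixed p
  for (F in c(0, 0.5)) {
    p <- 0.35
    n <- 20000
    withr::with_seed(11, {
      g <- crossploidy:::draw_genotypes(rep(p, n), F, 1)
    })
    phet <- 2 * p * (1 - p) * (1 - F)
    obs <- sum(g == 1L)
    bounds <- qbinom(c(0.0005, 0.9995), n, phet)
    expect_gte(obs, bounds[1])
    expect_lte(obs, bounds[2])
  }
})

test_that("population-label symmetry: swapped parameters transpose the SFS", {
  base <- demographic_model("constant_gene_flow", nu_D = 1.4, nu_T = 0.6,
                            T0 = 1, M_DT = 0.2, M_TD = 0.8,
                            F_D = 0.3, F_T = 0.7)
  swap <- demographic_model("constant_gene_flow", nu_D = 0.6, nu_T = 1.4,
                            T0 = 1, M_DT = 0.8, M_TD = 0.2,
                            F_D = 0.7, F_T = 0.3)
  E1 <- expected_sfs(base, n = c(12, 12), fold = FALSE, n_panel = 40,
                     n_trees = 8000, seed = 5)
  E2 <- expected_sfs(swap, n = c(12, 12), fold = FALSE, n_panel = 40,
                     n_trees = 8000, seed = 6)
  # transpose in distribution: compare marginal masses, not cellwise noise
  expect_equal(rowSums(E1$counts), colSums(E2$counts), tolerance = 0.05)
  expect_equal(sum(E1$counts), sum(E2$counts), tolerance = 0.03)
})

test_that("with an instantaneous split both populations share one frequency law", {
  m <- demographic_model("no_gene_flow", nu_D = 1, nu_T = 1, T0 = 1e-4)
  sim <- simulate_genotypes(m, simulation_config(n_D = 15, n_T = 15,
                                                 n_sites = 400, maf_min = 0,
                                                 seed = 8))
  ac <- allele_counts(sim$G)
  fD <- ac$alt["D", ] / ac$called["D", ]
  fT <- ac$alt["T", ] / ac$called["T", ]
  expect_gt(suppressWarnings(ks.test(fD, fT)$p.value), 0.01)
})

test_that("simulator matches the frozen independent-simulator F_ST envelope", {
  # Envelope precomputed once with msprime (50,000 sites, constant gene flow,
  # nu = (1, 1), M = (0.3, 0.4), T0 = 1, F = 0): mean per-SNP Weir-Cockerham
  # F_ST 0.14588, between-site sd 0.20082. The 2000-site mean must fall
  # within 4 standard errors of the oracle mean.
  oracle_mean <- 0.14588
  oracle_sd <- 0.20082
  m <- demographic_model("constant_gene_flow", nu_D = 1, nu_T = 1, T0 = 1,
                         M_DT = 0.3, M_TD = 0.4, F_D = 0, F_T = 0)
  sim <- simulate_genotypes(m, simulation_config(n_D = 20, n_T = 20,
                                                 n_sites = 2000, maf_min = 0,
                                                 site_missing_rate = 0,
                                                 indiv_missing_rate = 0,
                                                 seed = 3))
  got <- fst_profile(sim$G)$global
  half <- 4 * oracle_sd / sqrt(2000)
  expect_gt(got, oracle_mean - half)
  expect_lt(got, oracle_mean + half)
})

test_that("non-segregating corners fail with the resampling budget named", {
  m <- demographic_model("no_gene_flow", nu_D = 1, nu_T = 1, T0 = 1)
  cfg <- simulation_config(n_D = 2, n_T = 2, n_sites = 50, maf_min = 0.45,
                           seed = 1)
  expect_error(simulate_genotypes(m, cfg, max_rounds = 2L),
               "2 resampling rounds")
})

test_that("hybrid injection follows Mendelian gamete sampling", {
  # parents fixed 0/0 and 2/2: F1 always het, F2 1/4-1/2-1/4, BC_D half-half
  g <- rbind(matrix(0L, 5, 60), matrix(2L, 5, 60))
  G <- toy_genotype_matrix(g, pop = rep(c("D", "T"), each = 5))
  truth <- structure(list(model = study_model(),
                          config = simulation_config(n_D = 5, n_T = 5,
                                                     n_sites = 60),
                          freq = rbind(D = rep(0, 60), T = rep(1, 60)),
                          category = setNames(rep(c("pure_D", "pure_T"),
                                                  each = 5), G$samples)),
                     class = "truth_record")
  inj <- inject_hybrids(G, truth, counts = c(F1 = 4, F2 = 30, BC_D = 30),
                        seed = 7)
  hyb <- inj$G$geno[inj$G$pop == "HYB", ]
  cat_of <- inj$truth$category[rownames(hyb)]
  f1 <- hyb[cat_of == "F1", ]
  expect_true(all(f1 == 1L))
  f2 <- as.vector(hyb[cat_of == "F2", ])
  f2_frac <- tabulate(f2 + 1L, 3) / length(f2)
  expect_equal(f2_frac, c(0.25, 0.5, 0.25), tolerance = 0.05)
  bc <- as.vector(hyb[cat_of == "BC_D", ])
  bc_frac <- tabulate(bc + 1L, 3) / length(bc)
  expect_equal(bc_frac[1:2], c(0.5, 0.5), tolerance = 0.05)
  expect_equal(bc_frac[3], 0)
  # truth covers every individual
  expect_setequal(names(inj$truth$category), inj$G$samples)
  expect_error(inject_hybrids(subset_genotypes(G, individuals = G$pop == "D"),
                              truth, counts = c(F1 = 1)),
               "non-empty")
})

test_that("masking matches the combined rate and never drops rows", {
  G <- toy_genotype_matrix(matrix(1L, 10, 1000), pop = rep(c("D", "T"), 5))
  cfg0 <- simulation_config(n_D = 5, n_T = 5, n_sites = 10,
                            site_missing_rate = 0, indiv_missing_rate = 0)
  expect_identical(apply_missingness(G, cfg0, seed = 1)$geno, G$geno)
  cfg <- simulation_config(n_D = 5, n_T = 5, n_sites = 10,
                           site_missing_rate = 0.5, indiv_missing_rate = 0)
  masked <- apply_missingness(G, cfg, seed = 1)
  n_na <- sum(is.na(masked$geno))
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(n_na, bounds[1])
  expect_lte(n_na, bounds[2])
  expect_identical(nrow(masked$geno), 10L)
})

test_that("marker alignments carry exactly the requested column structure", {
  aln0 <- simulate_marker_alignment(6, 8, length = 100, n_fixed_diffs = 0,
                                    singleton_rate = 0, seed = 2)
  s0 <- alignment_summary(aln0)
  expect_identical(s0$n_variable, 0L)
  aln <- simulate_marker_alignment(26, 36, length = 658, n_fixed_diffs = 58,
                                   singleton_rate = 0, seed = 5)
  s <- alignment_summary(aln)
  expect_identical(s$n_fixed_diff, 58L)
  expect_identical(s$n_variable, 58L)
  expect_error(simulate_marker_alignment(4, 4, length = 10,
                                         n_fixed_diffs = 11),
               "impossible column budget")
})
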