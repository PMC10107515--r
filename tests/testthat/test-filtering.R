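test_that("site missingness filter uses a strict threshold", {
  g <- matrix(0L, 10, 3)
  g[1:6, 1] <- NA        # 60% missing: removed at 0.5
  g[1:5, 2] <- NA        # exactly 50%: retained
  G <- toy_genotype_matrix(g, pop = rep(c("D", "T"), 5))
  out <- filter_sites_by_missingness(G, 0.5)
  expect_identical(out$scaffold, G$scaffold[2:3])
})

test_that("individual missingness filter mirrors the site rule on rows", {
  g <- matrix(0L, 4, 8)
  g[1, ] <- NA           # all missing: removed
  g[2, 1:6] <- NA        # exactly 75%: retained
  G <- toy_genotype_matrix(g, pop = c("D", "D", "T", "T"))
  out <- filter_individuals_by_missingness(G, 0.75)
  expect_identical(out$samples, G$samples[2:4])
})

test_that("random matrices filter to the brute-force recount", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      G <- random_genotype_matrix(20, 50, p_missing = 0.4)
      out <- filter_sites_by_missingness(G, 0.5)
      keep <- colSums(is.na(G$geno)) / 20 <= 0.5
      expect_identical(ncol(out$geno), sum(keep))
      out2 <- filter_individuals_by_missingness(G, 0.3)
      keep2 <- rowSums(is.na(G$geno)) / 50 <= 0.3
      expect_identical(nrow(out2$geno), sum(keep2))
    }
  })
})

test_that("scaffold subsetting keeps order and warns on empty intersections", {
  G <- random_genotype_matrix(6, 30, p_missing = 0, n_scaffold = 10)
  all_ids <- unique(G$scaffold)
  expect_identical(subset_scaffolds(G, all_ids)$geno, G$geno)
  expect_warning(out <- subset_scaffolds(G, "no_such_scaffold"),
                 "conserved")
  expect_identical(ncol(out$geno), 0L)
  some <- all_ids[1:3]
  out2 <- subset_scaffolds(G, some)
  expect_identical(out2$scaffold, G$scaffold[G$scaffold %in% some])
  expect_error(subset_scaffolds(G, character(0)), "non-empty")
})

test_that("invariant-site removal keeps single-heterozygote sites", {
  g <- cbind(rep(0L, 6),              # invariant: removed
             c(0L, 1L, 0L, 0L, 0L, 0L),  # one het: retained
             rep(2L, 6),              # invariant alt: removed
             c(NA, NA, 2L, 2L, 2L, 2L))  # invariant over called: removed
  G <- toy_genotype_matrix(g, pop = rep(c("D", "T"), 3))
  out <- remove_invariant(G)
  expect_identical(out$scaffold, G$scaffold[2])
  # oracle on random matrices
  withr::with_seed(7, {
    G2 <- random_genotype_matrix(12, 40, p_missing = 0.2)
    out2 <- remove_invariant(G2)
    alt <- colSums(G2$geno, na.rm = TRUE)
    tot <- 2 * colSums(!is.na(G2$geno))
    expect_identical(ncol(out2$geno), sum(pmin(alt, tot - alt) > 0))
  })
})

test_that("pruning keeps the lowest-position site per scaffold", {
  G <- toy_genotype_matrix(matrix(1L, 4, 6), pop = c("D", "D", "T", "T"),
                           scaffold = c("s1", "s2", "s2", "s3", "s3", "s3"),
                           pos = c(5L, 9L, 3L, 7L, 7L, 2L))
  out <- prune_one_per_scaffold(G)
  expect_identical(out$scaffold, c("s1", "s2", "s3"))
  expect_identical(out$pos, c(5L, 3L, 2L))
  withr::with_seed(8, {
    G2 <- random_genotype_matrix(6, 60, p_missing = 0, n_scaffold = 15)
    out2 <- prune_one_per_scaffold(G2)
    expect_identical(sort(unique(G2$scaffold)), sort(out2$scaffold))
    expect_false(any(duplicated(out2$scaffold)))
  })
})

test_that("every filter is idempotent", {
  withr::with_seed(13, {
    G <- random_genotype_matrix(15, 60, p_missing = 0.35, n_scaffold = 20)
  })
  for (f in list(function(g) filter_sites_by_missingness(g, 0.5),
                 function(g) filter_individuals_by_missingness(g, 0.75),
                 remove_invariant,
                 prune_one_per_scaffold)) {
    once <- f(G)
    expect_identical(f(once)$geno, once$geno)
  }
})

test_that("the full chain yields a clean analysis matrix and a monotone report", {
  sim <- simulate_genotypes(study_model(),
                            simulation_config(n_D = 20, n_T = 20,
                                              n_sites = 120, seed = 5))
  G <- apply_missingness(sim$G, simulation_config(n_D = 20, n_T = 20,
                                                  n_sites = 120,
                                                  site_missing_rate = 0.3,
                                                  indiv_missing_rate = 0.1),
                         seed = 6)
  res <- filter_chain(G)
  out <- res$G
  expect_false(any(duplicated(out$scaffold)))
  alt <- colSums(out$geno, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(out$geno))
  expect_true(all(pmin(alt, tot - alt) > 0))
  expect_true(all(colMeans(is.na(out$geno)) <= 0.5))
  expect_true(all(diff(res$report$n_sites) <= 0))
  expect_true(all(diff(res$report$n_individuals) <= 0))
  path <- file.path(withr::local_tempdir(), "report.tsv")
  write_filter_report(res$report, path)
  expect_identical(nrow(read.table(path, header = TRUE, sep = "\t")),
                   nrow(res$report))
})
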