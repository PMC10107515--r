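test_that("a fixed inter-population difference lands on one folded cell", {
  g <- rbind(matrix(0L, 2, 1), matrix(2L, 2, 1))
  G <- toy_genotype_matrix(g, pop = c("D", "D", "T", "T"))
  S <- joint_sfs(G, fold = TRUE)
  expect_identical(S$n, c(4L, 4L))
  # (0, 4) folds onto itself or its complement (4, 0): exactly one cell holds
  # the site
  nz <- which(S$counts != 0, arr.ind = TRUE)
  expect_identical(nrow(nz), 1L)
  expect_true(all(S$counts[nz] == 1))
  hit <- as.integer(c(nz[1, 1] - 1, nz[1, 2] - 1))
  expect_true(identical(hit, c(0L, 4L)) || identical(hit, c(4L, 0L)))
})

test_that("spectrum mass equals the number of retained segregating sites", {
  sim <- simulate_genotypes(study_model(),
                            simulation_config(n_D = 8, n_T = 8, n_sites = 77,
                                              seed = 3))
  S <- joint_sfs(sim$G, fold = TRUE)
  expect_equal(sum(S$counts), 77)
  expect_equal(sum(S$counts[!S$mask]), 77)  # no fixed-corner mass
})

test_that("cells match a brute-force per-site tally on random matrices", {
  withr::with_seed(21, {
    G <- random_genotype_matrix(8, 40, p_missing = 0)
  })
  S <- joint_sfs(G, fold = FALSE)
  tally <- matrix(0, S$n[1] + 1, S$n[2] + 1)
  for (j in seq_len(ncol(G$geno))) {
    kD <- sum(G$geno[G$pop == "D", j])
    kT <- sum(G$geno[G$pop == "T", j])
    tally[kD + 1, kT + 1] <- tally[kD + 1, kT + 1] + 1
  }
  expect_equal(S$counts, tally)
})

test_that("projection kernels are normalized and identity at equal size", {
  S <- joint_sfs(toy_genotype_matrix(rbind(c(0L, 1L), c(2L, 1L),
                                           c(2L, 0L), c(0L, 2L)),
                                     pop = c("D", "D", "T", "T")),
                 fold = FALSE)
  expect_identical(project_sfs(S, S$n), S)
  K <- crossploidy:::hyper_kernel(6, 4)
  expect_equal(rowSums(K), rep(1, 7), tolerance = 1e-12)
  # projecting a single site preserves unit mass
  one <- matrix(0, 7, 7); one[3, 5] <- 1
  S1 <- joint_sfs_obj(one, c(6L, 6L), folded = FALSE)
  expect_equal(sum(project_sfs(S1, c(4L, 4L))$counts), 1, tolerance = 1e-12)
})

test_that("6 -> 4 projection equals exhaustive subset enumeration", {
  for (k in 0:6) {
    expect_equal(crossploidy:::hyper_kernel_row(k, 6, 4),
                 oracle_projection_row(k, 6, 4), tolerance = 1e-12)
  }
  # a hand-built joint spectrum, both axes projected
  withr::with_seed(2, {
    M <- matrix(rpois(49, 3), 7, 7)
  })
  S <- joint_sfs_obj(M, c(6L, 6L), folded = FALSE)
  P <- project_sfs(S, c(4L, 4L))
  expected <- matrix(0, 5, 5)
  for (i in 0:6) for (j in 0:6) {
    ri <- oracle_projection_row(i, 6, 4)
    rj <- oracle_projection_row(j, 6, 4)
    expected <- expected + M[i + 1, j + 1] * outer(ri, rj)
  }
  expect_equal(P$counts, expected, tolerance = 1e-12)
})

test_that("projection target larger than the current size is refused", {
  S <- joint_sfs_obj(matrix(1, 5, 5), c(4L, 4L), folded = FALSE)
  expect_error(project_sfs(S, c(6L, 4L)), "exceeds")
})

test_that("folding is idempotent, mass-preserving and commutes with projection", {
  withr::with_seed(8, {
    M <- matrix(runif(11 * 9), 11, 9)
  })
  S <- joint_sfs_obj(M, c(10L, 8L), folded = FALSE)
  Ff <- fold_sfs(S)
  expect_identical(fold_sfs(Ff), Ff)
  expect_equal(sum(Ff$counts), sum(M), tolerance = 1e-12)
  # fold(project(S)) == project(fold(S))
  a <- fold_sfs(project_sfs(S, c(6L, 4L)))
  b <- project_sfs(Ff, c(6L, 4L))
  expect_equal(a$counts, b$counts, tolerance = 1e-12)
  expect_identical(a$mask, b$mask)
})

test_that("per-site hypergeometric projection absorbs missing data", {
  g <- rbind(c(0L), c(1L), c(NA), c(2L), c(2L), c(NA))
  G <- toy_genotype_matrix(g, pop = rep(c("D", "T"), each = 3))
  S <- joint_sfs(G, fold = FALSE, size = c(4L, 4L), na_action = "project")
  expect_equal(sum(S$counts), 1, tolerance = 1e-12)
  # exclusion drops the site instead
  S2 <- joint_sfs(G, fold = FALSE, size = c(4L, 4L), na_action = "exclude")
  expect_equal(sum(S2$counts), 0)
  expect_identical(attr(S2, "n_dropped"), 1L)
})

test_that("spectra survive a plain-text round-trip", {
  withr::with_seed(4, {
    M <- matrix(rpois(25, 2), 5, 5)
  })
  S <- fold_sfs(joint_sfs_obj(M, c(4L, 4L), folded = FALSE))
  path <- file.path(withr::local_tempdir(), "sfs.txt")
  write_sfs(S, path)
  S2 <- read_sfs(path)
  expect_equal(S2$counts, S$counts, tolerance = 1e-12)
  expect_identical(S2$n, S$n)
  expect_identical(S2$folded, TRUE)
  expect_error(read_sfs(system.file("DESCRIPTION", package = "crossploidy")),
               "header")
})
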