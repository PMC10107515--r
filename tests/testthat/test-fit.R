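test_that("theta has its analytic Poisson maximizer", {
  withr::with_seed(6, {
    M <- matrix(runif(25, 0.5, 2), 5, 5)
  })
  model <- joint_sfs_obj(M, c(4L, 4L), folded = FALSE)
  data <- joint_sfs_obj(3 * M, c(4L, 4L), folded = FALSE)
  cl <- composite_loglik(data, model)
  expect_equal(cl$theta, 3, tolerance = 1e-12)
  # grid confirmation that theta-hat maximizes the likelihood
  ll_at <- function(th) {
    keep <- !data$mask
    d <- data$counts[keep]; m <- model$counts[keep]
    sum(d * log(th * m) - th * m - lgamma(d + 1))
  }
  expect_true(all(ll_at(cl$theta) >= vapply(c(1, 2, 2.9, 3.1, 5), ll_at,
                                            numeric(1))))
})

test_that("an empty data spectrum is flagged degenerate with lnL zero", {
  model <- joint_sfs_obj(matrix(1, 5, 5), c(4L, 4L), folded = FALSE)
  data <- joint_sfs_obj(matrix(0, 5, 5), c(4L, 4L), folded = FALSE)
  cl <- composite_loglik(data, model)
  expect_true(cl$degenerate)
  expect_identical(cl$loglik, 0)
  expect_identical(cl$theta, 0)
})

test_that("zero model cells under observed data are floored and counted", {
  M <- matrix(1, 5, 5); M[2, 3] <- 0
  model <- joint_sfs_obj(M, c(4L, 4L), folded = FALSE)
  D <- matrix(1, 5, 5)
  data <- joint_sfs_obj(D, c(4L, 4L), folded = FALSE)
  cl <- composite_loglik(data, model)
  expect_identical(cl$n_floored, 1L)
  expect_true(is.finite(cl$loglik))
})

test_that("mismatched spectra are refused", {
  a <- joint_sfs_obj(matrix(1, 5, 5), c(4L, 4L), folded = FALSE)
  b <- joint_sfs_obj(matrix(1, 3, 5), c(2L, 4L), folded = FALSE)
  expect_error(composite_loglik(a, b), "sample sizes")
  expect_error(composite_loglik(a, fold_sfs(a)), "folded")
})

test_that("the AIC identity and parameter counts hold for every family", {
  expect_identical(model_n_params("constant_gene_flow"), 5L)
  expect_identical(model_n_params("historical_gene_flow"), 6L)
  expect_identical(model_n_params("secondary_contact"), 6L)
  expect_identical(model_n_params("no_gene_flow"), 3L)
  sim <- simulate_genotypes(study_model(),
                            simulation_config(n_D = 12, n_T = 12,
                                              n_sites = 500, maf_min = 0,
                                              seed = 2))
  S <- joint_sfs(sim$G, fold = TRUE)
  fit <- fit_model(S, "no_gene_flow", F = c(0.81, 0.75), n_restarts = 4,
                   seed = 3, n_gens = 10, n_trees = 400,
                   n_trees_polish = 800, n_trees_final = 2000, maxit = 100)
  expect_identical(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_identical(fit$k, 3L)
  expect_identical(nrow(fit$restart_log), 18L)  # population floor
  # the evolutionary search never worsens its population
  expect_gte(max(fit$restart_log$loglik, na.rm = TRUE), fit$loglik - 50)
})

test_that("fits are deterministic given the seed", {
  sim <- simulate_genotypes(study_model(),
                            simulation_config(n_D = 12, n_T = 12,
                                              n_sites = 300, maf_min = 0,
                                              seed = 4))
  S <- joint_sfs(sim$G, fold = TRUE)
  f1 <- fit_model(S, "no_gene_flow", n_restarts = 4, seed = 11, n_gens = 6,
                  n_trees = 300, n_trees_polish = 500, n_trees_final = 800,
                  maxit = 50)
  f2 <- fit_model(S, "no_gene_flow", n_restarts = 4, seed = 11, n_gens = 6,
                  n_trees = 300, n_trees_polish = 500, n_trees_final = 800,
                  maxit = 50)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("subsampled replicates project to the target and differ by seed", {
  sim <- simulate_genotypes(study_model(),
                            simulation_config(n_D = 20, n_T = 20,
                                              n_sites = 150, seed = 5))
  reps <- subsample_replicates(sim$G, n_rep = 5, size = c(24L, 24L),
                               seed = 6)
  expect_length(reps, 5)
  for (S in reps) {
    expect_identical(S$n, c(24L, 24L))
    expect_lte(sum(S$counts), 150 + 1e-9)
    expect_gt(sum(S$counts), 0)
  }
  # distinct subsets: spectra differ across replicates
  expect_false(identical(reps[[1]]$counts, reps[[2]]$counts))
  # n_rep = 1 with every individual equals direct build + projection
  all_in <- subsample_replicates(sim$G, n_rep = 1, size = c(24L, 24L),
                                 extra = 40L, seed = 7)[[1]]
  direct <- joint_sfs(sim$G, fold = TRUE, size = c(24L, 24L),
                      na_action = "project")
  expect_equal(all_in$counts, direct$counts, tolerance = 1e-12)
  expect_error(subsample_replicates(sim$G, size = c(60L, 60L)),
               "too small")
})

test_that("model comparison medians, tests and edge cases", {
  a <- c(100, 101, 102, 103)
  cmp <- compare_models(list(fam_a = a, fam_b = a))
  expect_equal(cmp$tests$t, 0)
  expect_equal(cmp$tests$p, 1)
  cmp2 <- compare_models(list(fam_a = a, fam_b = a + 10))
  expect_identical(cmp2$best, "fam_a")
  expect_lt(cmp2$tests$p, 0.01)
  expect_lt(cmp2$tests$t, 0)      # signed best minus other
  # single replicate: medians only
  cmp3 <- compare_models(list(x = 5, y = 7))
  expect_true(is.na(cmp3$tests$p))
  expect_identical(cmp3$best, "x")
  expect_error(compare_models(list(x = 1:3, y = 1:2)), "same replicate")
})
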