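#' Poisson composite log-likelihood of a joint SFS under a model spectrum
#'
#' Treats unmasked spectrum cells as independent Poisson counts with mean
#' `theta * m_ij`, where the mutation scale `theta` has the analytic maximizer
#' `theta_hat = sum(data) / sum(model)` over unmasked cells:
#' `lnL = sum d * log(theta * m) - theta * m - log(d!)`.
#' Model cells that are zero (or negative from Monte-Carlo noise) where data
#' are observed are floored at a tiny positive value; the number of floored
#' cells is reported.
#'
#' @param data,model_sfs [joint_sfs_obj()]s of matching size and folded
#'   state.
#' @param floor_value positive floor for degenerate model cells.
#' @return A list: `loglik`, `theta`, `n_floored`, `degenerate` (`TRUE` for
#'   an empty data spectrum, for which `lnL = 0`).
#' @export
composite_loglik <- function(data, model_sfs, floor_value = 1e-10) {
  stopifnot(inherits(data, "joint_sfs"), inherits(model_sfs, "joint_sfs"))
  if (!identical(data$n, model_sfs$n))
    stop("data and model spectra have different sample sizes")
  if (!identical(data$folded, model_sfs$folded))
    stop("data and model spectra differ in folded state")
  keep <- !data$mask
  d <- data$counts[keep]
  m <- model_sfs$counts[keep]
  n_floored <- sum(m <= 0 & d > 0)
  m <- pmax(m, floor_value)
  sum_d <- sum(d)
  if (sum_d == 0)
    return(list(loglik = 0, theta = 0, n_floored = 0L, degenerate = TRUE))
  theta <- sum_d / sum(m)
  mu <- theta * m
  ll <- sum(d * log(mu) - mu - lgamma(d + 1))
  list(loglik = ll, theta = theta, n_floored = as.integer(n_floored),
       degenerate = FALSE)
}

# free-parameter layout per family (names in model order)
family_param_names <- function(family) {
  switch(family,
         constant_gene_flow = c("nu_D", "nu_T", "T0", "M_DT", "M_TD"),
         historical_gene_flow = c("nu_D", "nu_T", "T0", "T1", "M_DT", "M_TD"),
         secondary_contact = c("nu_D", "nu_T", "T0", "T1", "M_DT", "M_TD"),
         no_gene_flow = c("nu_D", "nu_T", "T0"),
         stop("unknown model family '", family, "'"))
}

params_to_model <- function(family, par, F) {
  nm <- family_param_names(family)
  p <- as.list(setNames(par, nm))
  demographic_model(family,
                    nu_D = p$nu_D, nu_T = p$nu_T, T0 = p$T0,
                    T1 = if ("T1" %in% nm) p$T1 else NULL,
                    M_DT = if ("M_DT" %in% nm) p$M_DT else 0,
                    M_TD = if ("M_TD" %in% nm) p$M_TD else 0,
                    F_D = F[1], F_T = F[2])
}

# parameter bounds (natural scale); migration's lower bound is a small
# positive value standing in for 0 so that log-space search is defined
param_bounds <- function(names) {
  lo <- ifelse(grepl("^M_", names), 1e-4, 1e-3)
  hi <- ifelse(grepl("^M_", names), 50, 100)
  cbind(lo = lo, hi = hi)
}

default_start <- function(family) {
  nm <- family_param_names(family)
  st <- c(nu_D = 1, nu_T = 1, T0 = 1, T1 = 0.5, M_DT = 1, M_TD = 1)
  st[nm]
}

#' Fit a demographic model to a joint SFS by composite likelihood
#'
#' Bounded derivative-free maximization in log-parameter space. The
#' `n_restarts` start points, each equal to the default start with every
#' parameter multiplied by an independent `2^u`, `u ~ Uniform(-2, 2)`, form
#' the initial population of a differential-evolution search (rand/1/bin,
#' weight 0.7, crossover 0.9) whose best member is then polished by
#' Nelder-Mead; the composite-likelihood surface of
#' isolation-with-migration models is both multimodal and, under a
#' Monte-Carlo expected spectrum, locally rugged, which defeats isolated
#' simplex runs but not a population-based search. The inbreeding
#' coefficients are fixed, never optimized. The expected spectrum is
#' evaluated with a fixed engine seed per fit (common random numbers), so
#' the objective is deterministic given `seed`.
#'
#' @param data a [joint_sfs_obj()], typically projected and folded.
#' @param family model family name.
#' @param F fixed inbreeding coefficients `c(F_D, F_T)`.
#' @param n_restarts number of perturbed start points (the search population
#'   holds at least 18 members; extra members beyond `n_restarts` reuse the
#'   same perturbation kernel).
#' @param seed integer seed (perturbations and engine). Fits of different
#'   families to the same data with the same `seed` share the engine seed,
#'   so their final log-likelihoods are evaluated on common random numbers
#'   and AIC differences are directly comparable.
#' @param n_panel,n_trees engine precision of each expected-spectrum
#'   evaluation during the population search.
#' @param n_trees_polish,maxit precision and iteration cap of the
#'   Nelder-Mead polish of the best member.
#' @param n_trees_final higher-precision tree count for the reported
#'   log-likelihood at the optimum.
#' @param n_gens differential-evolution generations.
#' @return A `fit_result` list: `family`, `params` (named vector), `loglik`,
#'   `theta`, `aic` (`2k - 2 lnL` with `k` the free-parameter count),
#'   `k`, `restart_log` (data frame of per-restart final log-likelihoods),
#'   `convergence` codes.
#' @export
fit_model <- function(data, family, F = c(0.81, 0.75), n_restarts = 99L,
                      seed = 1, n_panel = 60L, n_trees = 800L,
                      n_trees_polish = 2500L, n_trees_final = 10000L,
                      maxit = 200L, n_gens = 50L) {
  stopifnot(inherits(data, "joint_sfs"))
  nm <- family_param_names(family)
  bounds <- param_bounds(nm)
  k <- model_n_params(family)
  np <- length(nm)
  z_lo <- log(bounds[, "lo"])
  z_hi <- log(bounds[, "hi"])

  objective <- function(z, engine_seed, trees) {
    par <- exp(pmin(pmax(z, z_lo), z_hi))
    model <- params_to_model(family, par, F)
    E <- expected_sfs(model, n = data$n, fold = data$folded,
                      n_panel = n_panel, n_trees = trees, n_batches = 1L,
                      seed = engine_seed)
    -composite_loglik(data, E)$loglik
  }

  z0 <- log(default_start(family))
  NP <- max(18L, min(as.integer(n_restarts), 30L))
  withr::with_seed(seed, {
    engine_seed <- sample.int(.Machine$integer.max, 1)
    # start points: default start perturbed by 2^u per parameter
    P <- t(vapply(seq_len(NP), function(r)
      z0 + log(2) * runif(np, -2, 2), numeric(np)))
    val <- vapply(seq_len(NP), function(i)
      tryCatch(objective(P[i, ], engine_seed, n_trees),
               error = function(e) Inf), numeric(1))
    if (all(!is.finite(val)))
      stop("all ", NP, " start points failed to evaluate")
    # differential evolution (rand/1/bin)
    Fw <- 0.7; CR <- 0.9
    for (g in seq_len(n_gens)) {
      for (i in seq_len(NP)) {
        idx <- sample(setdiff(seq_len(NP), i), 3)
        v <- P[idx[1], ] + Fw * (P[idx[2], ] - P[idx[3], ])
        cross <- runif(np) < CR
        cross[sample(np, 1)] <- TRUE
        u <- ifelse(cross, v, P[i, ])
        u <- pmin(pmax(u, z_lo), z_hi)
        fu <- tryCatch(objective(u, engine_seed, n_trees),
                       error = function(e) Inf)
        if (fu <= val[i]) { P[i, ] <- u; val[i] <- fu }
      }
    }
    ord <- order(val)
    # Nelder-Mead polish of the best member at higher engine precision
    polish <- tryCatch(
      optim(P[ord[1], ], objective, engine_seed = engine_seed,
            trees = n_trees_polish, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) NULL)
  })
  restart_log <- data.frame(restart = seq_len(NP), loglik = -val)
  if (!is.null(polish) &&
      polish$value <= objective(P[ord[1], ], engine_seed, n_trees_polish)) {
    best <- list(par = polish$par, convergence = polish$convergence)
  } else {
    best <- list(par = P[ord[1], ], convergence = 1L)
  }
  if (!is.finite(min(val)) && is.null(polish))
    stop("all ", NP, " restarts failed; restart log:\n",
         paste(utils::capture.output(print(restart_log)), collapse = "\n"))
  par <- exp(best$par)
  par <- setNames(pmin(pmax(par, bounds[, "lo"]), bounds[, "hi"]), nm)
  model <- params_to_model(family, par, F)
  E <- expected_sfs(model, n = data$n, fold = data$folded,
                    n_panel = n_panel, n_trees = n_trees_final,
                    n_batches = 1L, seed = engine_seed)
  cl <- composite_loglik(data, E)
  loglik <- cl$loglik
  structure(list(family = family, params = par, F = setNames(F, c("F_D", "F_T")),
                 loglik = loglik, theta = cl$theta, k = k,
                 aic = 2 * k - 2 * loglik, restart_log = restart_log,
                 convergence = best$convergence, engine_seed = engine_seed,
                 n_panel = n_panel, n_trees_final = n_trees_final),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$family, sprintf("(k = %d)", x$k), "\n")
  cat("  params:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  lnL = %.3f, theta = %.4g, AIC = %.3f (%d restarts)\n",
              x$loglik, x$theta, x$aic, nrow(x$restart_log)))
  invisible(x)
}

#' Subsampled SFS replicates for uncertainty assessment
#'
#' Each replicate draws, per population, a without-replacement subset of
#' individuals sufficient for the target projection, rebuilds the joint SFS
#' with per-site hypergeometric projection (absorbing missing data), and
#' folds if requested. Deterministic given `seed`.
#'
#' @param G a [genotype_matrix()].
#' @param n_rep number of replicates (default 99).
#' @param size haploid target sizes.
#' @param extra individuals drawn per population beyond the minimum
#'   `size / 2`, providing slack against missing calls.
#' @param fold fold replicate spectra.
#' @param seed integer seed.
#' @param pops population labels.
#' @return A list of `n_rep` [joint_sfs_obj()]s.
#' @export
subsample_replicates <- function(G, n_rep = 99L, size = c(24L, 24L),
                                 extra = 3L, fold = TRUE, seed = 1,
                                 pops = c("D", "T")) {
  stopifnot(inherits(G, "genotype_matrix"))
  size <- as.integer(size)
  need <- size %/% 2L + as.integer(extra)
  idx <- lapply(pops, function(p) which(G$pop == p))
  avail <- lengths(idx)
  if (any(avail < size %/% 2L))
    stop("population(s) too small for the (", paste(size, collapse = ", "),
         ") projection: have ", paste(avail, collapse = ", "), " individuals")
  need <- pmin(need, avail)
  withr::with_seed(seed, {
    reps <- lapply(seq_len(n_rep), function(r) {
      take <- c(idx[[1]][sample.int(avail[1], need[1])],
                idx[[2]][sample.int(avail[2], need[2])])
      sub <- subset_genotypes(G, individuals = sort(take))
      joint_sfs(sub, pops = pops, fold = fold, size = size,
                na_action = "project")
    })
  })
  reps
}

#' Compare fitted model families by AIC over replicates
#'
#' Computes the median AIC per family, identifies the best family (lowest
#' median), and runs a Welch two-sample t-test of every other family's AIC
#' distribution against the best family's (paper-style `t` and `p` values,
#' with `t` signed as best minus other).
#'
#' @param fits a named list: one element per family, each a list of
#'   `fit_result`s (or a numeric vector of AICs) over the same replicate
#'   set.
#' @return A `model_comparison` list: `aic` (replicates x families matrix),
#'   `medians`, `best`, `tests` (data frame with `family`, `t`, `p`).
#' @export
compare_models <- function(fits) {
  if (!is.list(fits) || is.null(names(fits)))
    stop("fits must be a named list keyed by model family")
  aic_of <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(f) f$aic, numeric(1))
  }
  aics <- lapply(fits, aic_of)
  len <- unique(lengths(aics))
  if (length(len) != 1)
    stop("all families must cover the same replicate set")
  A <- do.call(cbind, aics)
  medians <- apply(A, 2, median)
  best <- names(medians)[which.min(medians)]
  if (nrow(A) < 2) {
    tests <- data.frame(family = setdiff(colnames(A), best),
                        t = NA_real_, p = NA_real_)
  } else {
    others <- setdiff(colnames(A), best)
    tests <- do.call(rbind, lapply(others, function(fam) {
      if (sd(A[, best]) == 0 && sd(A[, fam]) == 0) {
        if (all(A[, best] == A[, fam]))
          return(data.frame(family = fam, t = 0, p = 1))
      }
      ht <- t.test(A[, best], A[, fam], var.equal = FALSE)
      data.frame(family = fam, t = unname(ht$statistic),
                 p = unname(ht$p.value))
    }))
  }
  structure(list(aic = A, medians = medians, best = best, tests = tests),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>", nrow(x$aic), "replicates\n")
  ord <- order(x$medians)
  for (fam in names(x$medians)[ord]) {
    line <- sprintf("  %-22s median AIC %.2f", fam, x$medians[fam])
    if (fam == x$best) line <- paste(line, "(best)")
    else {
      row <- x$tests[x$tests$family == fam, ]
      line <- paste(line, sprintf(" t = %.2f, p = %.3g", row$t, row$p))
    }
    cat(line, "\n")
  }
  invisible(x)
}
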