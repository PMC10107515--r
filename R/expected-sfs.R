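# distribution of the summed alt-allele count of n_ind diploid genotypes
# drawn iid at frequency p with inbreeding F (vector over 0..2*n_ind)
genotype_count_dist <- function(p, F, n_ind) {
  pr <- genotype_class_probs(p, F)[1, ]
  v <- 1
  for (i in seq_len(n_ind)) {
    nv <- numeric(length(v) + 2)
    nv[seq_along(v)] <- nv[seq_along(v)] + v * pr[1]
    nv[seq_along(v) + 1] <- nv[seq_along(v) + 1] + v * pr[2]
    nv[seq_along(v) + 2] <- nv[seq_along(v) + 2] + v * pr[3]
    v <- nv
  }
  v
}

# kernel matrix mapping panel counts 0..n_panel to genotype-sample counts
# 0..2*n_ind under the inbreeding-distorted genotype draw; memoised because
# fits re-evaluate it with identical arguments thousands of times
.kernel_cache <- new.env(parent = emptyenv())

panel_genotype_kernel <- function(n_panel, F, n_ind) {
  key <- sprintf("%d_%.12g_%d", n_panel, F, n_ind)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  K <- matrix(0, n_panel + 1, 2 * n_ind + 1)
  for (a in 0:n_panel)
    K[a + 1, ] <- genotype_count_dist(a / n_panel, F, n_ind)
  .kernel_cache[[key]] <- K
  K
}

#' Expected joint SFS under a demographic model (unit mutation scale)
#'
#' Monte-Carlo structured-coalescent computation: genealogies of a frequency
#' panel (`n_panel` gene copies per deme) are simulated under the model, and
#' the expected branch length subtending every derived-allele configuration
#' is accumulated, giving the relative density of segregating sites per panel
#' frequency under the infinite-sites model. The panel spectrum is then
#' pushed through the same inbreeding-distorted genotype-sampling kernel the
#' simulator uses (diploid genotypes drawn iid given the panel frequency, so
#' that fitting and simulation form a consistent pair), yielding the expected
#' spectrum for `n[k] / 2` diploid individuals per population. Per-cell
#' Monte-Carlo standard errors are estimated from batch means.
#'
#' @param model a [demographic_model()]; its `F_D`, `F_T` enter the genotype
#'   kernel.
#' @param n haploid sample sizes `c(n_D, n_T)`; must be even.
#' @param fold fold the spectrum (default `TRUE`).
#' @param n_panel panel gene copies per deme.
#' @param n_trees Monte-Carlo genealogies.
#' @param n_batches batches for the standard-error estimate.
#' @param seed integer seed for the engine.
#' @return A [joint_sfs_obj()] with relative expected counts (unit theta) and
#'   an `se` matrix of declared Monte-Carlo standard errors.
#' @export
expected_sfs <- function(model, n = c(24L, 24L), fold = TRUE,
                         n_panel = 80L, n_trees = 1000L, n_batches = 10L,
                         seed = 1) {
  stopifnot(inherits(model, "demographic_model"))
  n <- as.integer(n)
  if (any(n %% 2L != 0L))
    stop("haploid sample sizes must be even (diploid-coded genotypes)")
  epochs <- model_epochs(model)
  res <- coal_branch_spectrum(n_panel, n_panel, epochs, as.integer(n_trees),
                              as.integer(n_batches), seed)
  KD <- panel_genotype_kernel(n_panel, model$F_D, n[1] %/% 2L)
  KT <- panel_genotype_kernel(n_panel, model$F_T, n[2] %/% 2L)
  E <- t(KD) %*% res$W %*% KT
  Eb <- lapply(res$batches, function(B) t(KD) %*% B %*% KT)
  nb <- length(Eb)
  if (nb > 1) {
    Ebar <- Reduce(`+`, Eb) / nb
    V <- Reduce(`+`, lapply(Eb, function(B) (B - Ebar)^2)) / (nb - 1)
    se <- sqrt(V / nb)
  } else {
    se <- matrix(NA_real_, n[1] + 1, n[2] + 1)
  }
  S <- joint_sfs_obj(pmax(E, 0), n, folded = FALSE, se = se)
  if (fold) S <- fold_sfs(S)
  S
}
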