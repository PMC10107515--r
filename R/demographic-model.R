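#' Two-population isolation-with-migration model
#'
#' Describes an ancestral population of relative effective size 1 splitting
#' into a diploid population D and a tetraploid population T. The four
#' families differ only in when migration is allowed:
#' \describe{
#'   \item{`constant_gene_flow`}{one epoch of length `T0` with migration
#'     throughout (5 free parameters).}
#'   \item{`historical_gene_flow`}{migration during the older epoch `T0`
#'     only; it ceased `T1` time units ago (6 free parameters).}
#'   \item{`secondary_contact`}{isolation during the older epoch `T0`,
#'     migration during the recent epoch `T1` (6 free parameters).}
#'   \item{`no_gene_flow`}{complete isolation since the split `T0` ago
#'     (3 free parameters).}
#' }
#' Times are in coalescent units of `2 * N_anc` generations; `nu_D`, `nu_T`
#' are present-day sizes relative to the ancestral population; `M_DT` is the
#' number of migrants per generation moving from D into T (and `M_TD` the
#' reverse), i.e. `M = 2 * N * m`. Inbreeding coefficients `F_D`, `F_T` act
#' at the genotype level (excess homozygosity) and are fixed, never fitted.
#'
#' @param family one of `"constant_gene_flow"`, `"historical_gene_flow"`,
#'   `"secondary_contact"`, `"no_gene_flow"`.
#' @param nu_D,nu_T relative present-day population sizes (> 0).
#' @param T0 duration of the older epoch (> 0).
#' @param T1 duration of the recent epoch; required for the two-epoch
#'   families, must be `NULL` otherwise.
#' @param M_DT,M_TD migrants per generation (>= 0); must be 0 for
#'   `no_gene_flow`.
#' @param F_D,F_T inbreeding coefficients in `[0, 1]`.
#'
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(family = c("constant_gene_flow",
                                         "historical_gene_flow",
                                         "secondary_contact",
                                         "no_gene_flow"),
                              nu_D = 1, nu_T = 1, T0 = 1, T1 = NULL,
                              M_DT = 0, M_TD = 0, F_D = 0, F_T = 0) {
  family <- match.arg(family)
  two_epoch <- family %in% c("historical_gene_flow", "secondary_contact")
  if (!two_epoch && !is.null(T1))
    stop("family '", family, "' has no recent epoch: T1 must be NULL")
  if (two_epoch && (is.null(T1) || T1 <= 0))
    stop("family '", family, "' needs T1 > 0")
  if (nu_D <= 0 || nu_T <= 0 || T0 <= 0)
    stop("sizes and times must be > 0")
  if (M_DT < 0 || M_TD < 0) stop("migration rates must be >= 0")
  if (family == "no_gene_flow" && (M_DT != 0 || M_TD != 0))
    stop("no_gene_flow requires M_DT = M_TD = 0")
  if (F_D < 0 || F_D > 1 || F_T < 0 || F_T > 1)
    stop("inbreeding coefficients must lie in [0, 1]")
  structure(
    list(family = family, nu_D = nu_D, nu_T = nu_T, T0 = T0, T1 = T1,
         M_DT = M_DT, M_TD = M_TD, F_D = F_D, F_T = F_T),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> family:", x$family, "\n")
  cat(sprintf("  nu_D = %.4g, nu_T = %.4g, T0 = %.4g%s\n", x$nu_D, x$nu_T,
              x$T0, if (is.null(x$T1)) "" else sprintf(", T1 = %.4g", x$T1)))
  cat(sprintf("  M_DT = %.4g, M_TD = %.4g, F_D = %.3g, F_T = %.3g\n",
              x$M_DT, x$M_TD, x$F_D, x$F_T))
  invisible(x)
}

#' Number of free parameters per model family
#'
#' Inbreeding coefficients are fixed and excluded from the count.
#'
#' @param family model family name.
#' @return Integer: 5 (constant flow), 6 (historical flow or secondary
#'   contact) or 3 (no flow).
#' @export
model_n_params <- function(family) {
  switch(family,
         constant_gene_flow = 5L,
         historical_gene_flow = 6L,
         secondary_contact = 6L,
         no_gene_flow = 3L,
         stop("unknown model family '", family, "'"))
}

# Backward-time epoch table consumed by the C++ engine: rows of
# (duration, nu_D, nu_T, m12, m21), where m12 is the backward rate at which a
# lineage in D traces to T. Forward migrants into D come from T at rate M_TD,
# so backward m12 = M_TD; likewise m21 = M_DT.
model_epochs <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  m12 <- model$M_TD
  m21 <- model$M_DT
  switch(model$family,
    constant_gene_flow = matrix(
      c(model$T0, model$nu_D, model$nu_T, m12, m21), nrow = 1),
    no_gene_flow = matrix(
      c(model$T0, model$nu_D, model$nu_T, 0, 0), nrow = 1),
    historical_gene_flow = rbind(
      c(model$T1, model$nu_D, model$nu_T, 0, 0),
      c(model$T0, model$nu_D, model$nu_T, m12, m21)),
    secondary_contact = rbind(
      c(model$T1, model$nu_D, model$nu_T, m12, m21),
      c(model$T0, model$nu_D, model$nu_T, 0, 0)))
}
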