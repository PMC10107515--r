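#' Genotype matrix container
#'
#' Holds diploid-coded biallelic SNP calls for a set of individuals sampled
#' from two populations, together with per-site scaffold/position metadata.
#' Calls count copies of the alternative allele (0, 1 or 2); `NA` marks a
#' missing call. The tetraploid population is diploid-coded as well, mirroring
#' conserved-subgenome GBS calls under assumed disomic inheritance.
#'
#' @param geno integer matrix, individuals in rows, sites in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param scaffold character vector of scaffold ids, one per site.
#' @param pos integer vector of 1-based positions, one per site.
#' @param pop factor or character vector of population labels, one per
#'   individual. Labels `"D"` (diploid) and `"T"` (tetraploid) are the two
#'   analysis populations; other labels (e.g. `"HYB"` for injected hybrids)
#'   are carried through.
#' @param samples character vector of sample ids; defaults to rownames of
#'   `geno` or generated ids.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, scaffold, pos, pop, samples = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_ind <- nrow(geno)
  n_site <- ncol(geno)
  if (length(scaffold) != n_site)
    stop("length(scaffold) must equal the number of sites (", n_site, ")")
  if (length(pos) != n_site)
    stop("length(pos) must equal the number of sites (", n_site, ")")
  if (length(pop) != n_ind)
    stop("length(pop) must equal the number of individuals (", n_ind, ")")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad))
    stop("genotype calls must be 0, 1, 2 or NA; found ",
         paste(unique(geno[bad]), collapse = ", "))
  if (is.null(samples)) {
    samples <- rownames(geno)
    if (is.null(samples)) samples <- sprintf("ind_%03d", seq_len(n_ind))
  }
  rownames(geno) <- samples
  colnames(geno) <- sprintf("%s:%d", as.character(scaffold), as.integer(pos))
  structure(
    list(geno = geno,
         scaffold = as.character(scaffold),
         pos = as.integer(pos),
         pop = factor(pop),
         samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " sites\n", sep = "")
  cat("  populations:",
      paste(sprintf("%s=%d", levels(x$pop), tabulate(x$pop)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.1f%%; scaffolds: %d\n", 100 * miss,
              length(unique(x$scaffold))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by individuals and/or sites
#'
#' @param G a [genotype_matrix()].
#' @param individuals,sites logical or integer index vectors.
#' @return A `genotype_matrix` with the selected rows/columns.
#' @export
subset_genotypes <- function(G, individuals = NULL, sites = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(individuals)) individuals <- seq_len(nrow(G$geno))
  if (is.null(sites)) sites <- seq_len(ncol(G$geno))
  genotype_matrix(G$geno[individuals, sites, drop = FALSE],
                  scaffold = G$scaffold[sites],
                  pos = G$pos[sites],
                  pop = factor(G$pop[individuals]),
                  samples = G$samples[individuals])
}

#' Per-population alternative-allele counts at every site
#'
#' @param G a [genotype_matrix()].
#' @param pops character vector of the two population labels, default
#'   `c("D", "T")`.
#' @return A list with matrices `alt` (alt-allele copies) and `called`
#'   (non-missing gene copies), each 2 x n_sites with rows named by
#'   population.
#' @export
allele_counts <- function(G, pops = c("D", "T")) {
  stopifnot(inherits(G, "genotype_matrix"), length(pops) == 2)
  alt <- matrix(0, 2, ncol(G$geno), dimnames = list(pops, NULL))
  called <- alt
  for (k in 1:2) {
    rows <- G$pop == pops[k]
    if (!any(rows)) stop("no individuals in population '", pops[k], "'")
    sub <- G$geno[rows, , drop = FALSE]
    alt[k, ] <- colSums(sub, na.rm = TRUE)
    called[k, ] <- 2 * colSums(!is.na(sub))
  }
  list(alt = alt, called = called)
}
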