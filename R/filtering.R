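#' Site filter: missing-data fraction
#'
#' Removes sites whose fraction of missing calls is strictly greater than
#' `max_missing` (a site missing in exactly half the individuals survives a
#' 0.5 threshold).
#'
#' @param G a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction in `[0, 1]`.
#' @return The filtered `genotype_matrix`.
#' @export
filter_sites_by_missingness <- function(G, max_missing = 0.5) {
  stopifnot(inherits(G, "genotype_matrix"),
            max_missing >= 0, max_missing <= 1)
  frac <- colMeans(is.na(G$geno))
  subset_genotypes(G, sites = frac <= max_missing)
}

#' Individual filter: missing-data fraction
#'
#' Removes individuals whose fraction of missing calls is strictly greater
#' than `max_missing`.
#'
#' @inheritParams filter_sites_by_missingness
#' @export
filter_individuals_by_missingness <- function(G, max_missing = 0.75) {
  stopifnot(inherits(G, "genotype_matrix"),
            max_missing >= 0, max_missing <= 1)
  frac <- rowMeans(is.na(G$geno))
  subset_genotypes(G, individuals = frac <= max_missing)
}

#' Restrict sites to a conserved scaffold set
#'
#' Keeps only sites located on the listed scaffolds (e.g. the conserved
#' subgenome shared between ploidy levels), preserving input order. An empty
#' intersection yields a zero-site matrix with a warning.
#'
#' @param G a [genotype_matrix()].
#' @param conserved non-empty character vector of scaffold ids.
#' @export
subset_scaffolds <- function(G, conserved) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!length(conserved)) stop("conserved scaffold set must be non-empty")
  keep <- G$scaffold %in% conserved
  if (!any(keep))
    warning("no sites fall on the conserved scaffold set; all sites removed")
  subset_genotypes(G, sites = keep)
}

#' Remove invariant sites
#'
#' Drops sites whose minor-allele count over non-missing calls is zero
#' (all-homozygous for a single allele). A site variable only through a
#' single heterozygote is retained.
#'
#' @param G a [genotype_matrix()].
#' @export
remove_invariant <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  alt <- colSums(G$geno, na.rm = TRUE)
  called <- 2 * colSums(!is.na(G$geno))
  mac <- pmin(alt, called - alt)
  subset_genotypes(G, sites = mac > 0)
}

#' Keep one site per scaffold
#'
#' Linkage pruning: retains, for each scaffold, the site with the lowest
#' position (ties broken by input order).
#'
#' @param G a [genotype_matrix()].
#' @export
prune_one_per_scaffold <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  ord <- order(G$scaffold, G$pos, seq_along(G$pos))
  first <- !duplicated(G$scaffold[ord])
  keep <- sort(ord[first])
  subset_genotypes(G, sites = keep)
}

#' Full variant-filtering chain with a stage-by-stage report
#'
#' Applies, in order: site missingness, individual missingness, conserved
#' scaffold subset (if given), invariant-site removal, one-per-scaffold
#' pruning. The report records site and individual counts after every stage.
#'
#' @param G a [genotype_matrix()].
#' @param max_site_missing,max_indiv_missing missingness thresholds (strict
#'   `>` comparisons), defaults 0.5 and 0.75.
#' @param conserved optional scaffold id set; `NULL` skips the stage.
#' @return A list with `G` (the filtered matrix) and `report` (a
#'   `filter_report` data frame with columns `stage`, `n_sites`,
#'   `n_individuals`).
#' @export
filter_chain <- function(G, max_site_missing = 0.5, max_indiv_missing = 0.75,
                         conserved = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  stages <- list(input = function(g) g,
                 site_missingness = function(g)
                   filter_sites_by_missingness(g, max_site_missing),
                 individual_missingness = function(g)
                   filter_individuals_by_missingness(g, max_indiv_missing),
                 conserved_scaffolds = function(g)
                   if (is.null(conserved)) g else subset_scaffolds(g, conserved),
                 invariant_removal = remove_invariant,
                 one_per_scaffold = prune_one_per_scaffold)
  rep <- data.frame(stage = character(0), n_sites = integer(0),
                    n_individuals = integer(0))
  for (nm in names(stages)) {
    G <- stages[[nm]](G)
    rep <- rbind(rep, data.frame(stage = nm, n_sites = ncol(G$geno),
                                 n_individuals = nrow(G$geno)))
  }
  class(rep) <- c("filter_report", "data.frame")
  list(G = G, report = rep)
}

#' Write a filter report as a tab-separated log
#'
#' @param report a `filter_report` from [filter_chain()].
#' @param path output file path.
#' @export
write_filter_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
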