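#' Summarize variation in a grouped marker alignment
#'
#' Classifies every column of an equal-length alignment: \emph{variable} if
#' at least two distinct unambiguous bases occur; \emph{fixed-different} if
#' both groups are monomorphic (ignoring gaps and IUPAC ambiguity codes) for
#' different bases; \emph{singleton} if exactly one sequence carries a
#' minority base (two states, minor count one) and the column is not
#' fixed-different. Gap and ambiguity characters never contribute states; a
#' column in which one group is rendered empty by gaps cannot be classified
#' fixed-different.
#'
#' @param aln a [simulate_marker_alignment()] result or character matrix
#'   (rows = sequences).
#' @param groups factor of group labels, one per sequence; defaults to the
#'   alignment's `groups` attribute.
#' @return An `alignment_summary` list: `length`, `n_variable`, `n_fixed_diff`,
#'   `n_singleton`, `group_sizes`.
#' @export
alignment_summary <- function(aln, groups = NULL) {
  aln <- as_alignment_matrix(aln)
  if (is.null(groups)) groups <- attr(aln, "groups")
  if (is.null(groups)) stop("groups must be supplied")
  groups <- factor(groups)
  if (length(groups) != nrow(aln))
    stop("groups length must match the number of sequences")
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  valid <- c("a", "c", "g", "t")
  g1 <- groups == levels(groups)[1]
  n_variable <- 0L; n_fixed <- 0L; n_single <- 0L
  for (j in seq_len(ncol(aln))) {
    col <- tolower(aln[, j])
    ok <- col %in% valid
    states <- col[ok]
    tab <- table(states)
    if (length(tab) >= 2) {
      n_variable <- n_variable + 1L
      s1 <- unique(col[g1 & ok])
      s2 <- unique(col[!g1 & ok])
      fixed <- length(s1) == 1 && length(s2) == 1 && s1 != s2
      if (fixed) {
        n_fixed <- n_fixed + 1L
      } else if (length(tab) == 2 && min(tab) == 1) {
        n_single <- n_single + 1L
      }
    }
  }
  structure(list(length = ncol(aln), n_variable = n_variable,
                 n_fixed_diff = n_fixed, n_singleton = n_single,
                 group_sizes = setNames(as.integer(table(groups)),
                                        levels(groups))),
            class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat("<alignment_summary>", x$length, "columns;",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "), "\n")
  cat(sprintf("  variable: %d; fixed between groups: %d; singletons: %d\n",
              x$n_variable, x$n_fixed_diff, x$n_singleton))
  invisible(x)
}

#' Pairwise Hamming distances between aligned sequences
#'
#' Proportion of differing comparable columns per sequence pair; a column is
#' comparable for a pair when both sequences carry an unambiguous base.
#' Pairs with no comparable column get `NA`.
#'
#' @param aln alignment as for [alignment_summary()].
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln) {
  aln <- as_alignment_matrix(aln)
  valid <- c("a", "c", "g", "t")
  M <- tolower(aln)
  ok <- matrix(M %in% valid, nrow(M), ncol(M))
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      D[i, j] <- D[j, i] <-
        if (any(comp)) mean(M[i, comp] != M[j, comp]) else NA_real_
    }
  }
  D
}

as_alignment_matrix <- function(aln) {
  if (inherits(aln, "marker_alignment")) return(aln)
  if (is.matrix(aln) && is.character(aln)) {
    if (length(unique(nchar(aln))) > 1)
      stop("alignment cells must be single characters")
    return(aln)
  }
  stop("unsupported alignment input")
}

#' Write / read a grouped alignment as FASTA
#'
#' The group is encoded as the sample-name prefix before the first
#' underscore (e.g. `>D_001`). Reading checks that all sequences have equal
#' length and names the offending sequence otherwise.
#'
#' @param aln a `marker_alignment`.
#' @param path file path.
#' @return `write_fasta_alignment` returns the path invisibly;
#'   `read_fasta_alignment` a `marker_alignment`.
#' @export
write_fasta_alignment <- function(aln, path) {
  aln <- as_alignment_matrix(aln)
  lines <- character(2 * nrow(aln))
  lines[seq(1, by = 2, length.out = nrow(aln))] <- paste0(">", rownames(aln))
  lines[seq(2, by = 2, length.out = nrow(aln))] <-
    apply(aln, 1, paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fasta_alignment
#' @export
read_fasta_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1) {
    bad <- names(seqs)[which(lens != lens[1])[1]]
    stop("ragged alignment: sequence '", bad, "' has length ",
         lens[bad], " but '", names(seqs)[1], "' has ", lens[1])
  }
  M <- do.call(rbind, as.character(seqs))
  rownames(M) <- names(seqs)
  groups <- factor(sub("_.*$", "", names(seqs)))
  structure(M, groups = groups, class = c("marker_alignment", "matrix"))
}
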