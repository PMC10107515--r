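#' Joint site-frequency spectrum container
#'
#' A 2-D array of (expected) segregating-site counts indexed by
#' derived/minor-allele count in population D (rows, `0..n[1]`) and
#' population T (columns, `0..n[2]`), with haploid sample sizes, a folded
#' flag, and a mask excluding the fixed corners (and, for folded spectra, the
#' non-canonical half) from likelihood computations.
#'
#' @param counts numeric matrix of dimension `(n[1]+1) x (n[2]+1)`.
#' @param n integer vector of haploid sample sizes `c(n_D, n_T)`.
#' @param folded logical.
#' @param se optional matrix of per-cell Monte-Carlo standard errors.
#' @return An object of class `joint_sfs`.
#' @export
joint_sfs_obj <- function(counts, n, folded = FALSE, se = NULL) {
  n <- as.integer(n)
  if (!identical(dim(counts), n + 1L))
    stop("counts must be a (n_D + 1) x (n_T + 1) matrix")
  if (any(counts < -1e-9)) stop("spectrum counts must be >= 0")
  structure(list(counts = counts, n = n, folded = folded,
                 mask = sfs_mask(n, folded), se = se),
            class = "joint_sfs")
}

# TRUE = excluded from likelihoods: the fixed corners, plus (folded) the
# non-canonical half of the array
sfs_mask <- function(n, folded) {
  i <- matrix(0:n[1], n[1] + 1, n[2] + 1)
  j <- matrix(0:n[2], n[1] + 1, n[2] + 1, byrow = TRUE)
  m <- (i + j == 0) | (i == n[1] & j == n[2])
  if (folded) m <- m | !sfs_canonical(n)
  m
}

# canonical cells hold the folded mass: minor total count, deterministic
# tie-break on the hinge (i + j == (n_D + n_T) / 2)
sfs_canonical <- function(n) {
  i <- matrix(0:n[1], n[1] + 1, n[2] + 1)
  j <- matrix(0:n[2], n[1] + 1, n[2] + 1, byrow = TRUE)
  tot <- n[1] + n[2]
  lower <- 2 * (i + j) < tot
  hinge <- 2 * (i + j) == tot
  tie <- (i < n[1] - i) | (i == n[1] - i & j <= n[2] - j)
  lower | (hinge & tie)
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("<joint_sfs> n = (", x$n[1], ",", x$n[2], ") haploid;",
      if (x$folded) "folded;" else "unfolded;",
      "total mass", format(sum(x$counts[!x$mask]), digits = 6), "\n")
  invisible(x)
}

#' Fold a joint SFS onto minor-allele orientation
#'
#' Maps each cell `(i, j)` and its complement `(n_D - i, n_T - j)` onto the
#' canonical (minor-total-count) member of the pair; hinge cells paired with
#' themselves are left in place. Folding an already folded spectrum is the
#' identity.
#'
#' @param S a [joint_sfs_obj()].
#' @return The folded `joint_sfs`.
#' @export
fold_sfs <- function(S) {
  stopifnot(inherits(S, "joint_sfs"))
  if (S$folded) return(S)
  n <- S$n
  can <- sfs_canonical(n)
  flip <- function(M) M[(n[1] + 1):1, (n[2] + 1):1, drop = FALSE]
  Ff <- S$counts + flip(S$counts)
  self <- can & flip(can)             # self-complementary hinge cells
  Ff[self] <- S$counts[self]
  Ff[!can] <- 0
  se <- NULL
  if (!is.null(S$se)) {
    se <- sqrt(S$se^2 + flip(S$se)^2)
    se[self] <- S$se[self]
    se[!can] <- 0
  }
  joint_sfs_obj(Ff, n, folded = TRUE, se = se)
}

# symmetric unfolding used internally so that projection and folding commute
unfold_sym <- function(S) {
  n <- S$n
  flip <- function(M) M[(n[1] + 1):1, (n[2] + 1):1, drop = FALSE]
  U <- (S$counts + flip(S$counts)) / 2
  joint_sfs_obj(U, n, folded = FALSE,
                se = if (is.null(S$se)) NULL else sqrt(S$se^2 + flip(S$se)^2) / 2)
}

#' Build the joint SFS from a genotype matrix
#'
#' Per site, alternative-allele counts over non-missing calls in each
#' population increment one cell. Sites with missing data are either
#' projected per-site to a target haploid size via the hypergeometric
#' expectation (`na_action = "project"`, requires `size`) or excluded
#' (`na_action = "exclude"`). When all calls are present and no `size` is
#' given the spectrum is built at the full sample size.
#'
#' @param G a [genotype_matrix()].
#' @param pops the two population labels.
#' @param fold fold to minor-allele orientation (default `TRUE`).
#' @param size optional target haploid sizes `c(n_D, n_T)`; per-site counts
#'   with fewer called copies than the target are dropped.
#' @param na_action `"project"` or `"exclude"`.
#' @return A [joint_sfs_obj()]; attribute `"n_dropped"` counts sites lost.
#' @export
joint_sfs <- function(G, pops = c("D", "T"), fold = TRUE, size = NULL,
                      na_action = c("project", "exclude")) {
  stopifnot(inherits(G, "genotype_matrix"))
  na_action <- match.arg(na_action)
  ac <- allele_counts(G, pops)
  full <- c(2L * sum(G$pop == pops[1]), 2L * sum(G$pop == pops[2]))
  if (is.null(size)) size <- full
  size <- as.integer(size)
  if (any(size > full)) stop("target size exceeds the sample size")
  counts <- matrix(0, size[1] + 1, size[2] + 1)
  dropped <- 0L
  for (s in seq_len(ncol(ac$alt))) {
    mD <- ac$called[1, s]; mT <- ac$called[2, s]
    kD <- ac$alt[1, s]; kT <- ac$alt[2, s]
    incomplete <- mD < full[1] || mT < full[2]
    if (mD < size[1] || mT < size[2] ||
        (na_action == "exclude" && incomplete)) {
      dropped <- dropped + 1L
      next
    }
    if (mD == size[1] && mT == size[2]) {
      counts[kD + 1, kT + 1] <- counts[kD + 1, kT + 1] + 1
    } else {
      # per-site hypergeometric projection from the called copies
      vD <- hyper_kernel_row(kD, mD, size[1])
      vT <- hyper_kernel_row(kT, mT, size[2])
      counts <- counts + outer(vD, vT)
    }
  }
  S <- joint_sfs_obj(counts, size, folded = FALSE)
  if (fold) S <- fold_sfs(S)
  attr(S, "n_dropped") <- dropped
  S
}

# hypergeometric downsampling kernel: P(i derived in a draw of n_to copies |
# k derived among n_from)
hyper_kernel_row <- function(k, n_from, n_to) {
  stats::dhyper(0:n_to, m = k, n = n_from - k, k = n_to)
}

# full projection kernel matrix, rows = source count 0..n_from
hyper_kernel <- function(n_from, n_to) {
  t(vapply(0:n_from, hyper_kernel_row, numeric(n_to + 1), n_from = n_from,
           n_to = n_to))
}

#' Project a joint SFS to smaller haploid sample sizes
#'
#' Expected-value (deterministic) projection: each cell's mass is
#' redistributed by the product of two hypergeometric sampling kernels, one
#' per population. Folded spectra are symmetrically unfolded, projected and
#' refolded, which commutes exactly with folding.
#'
#' @param S a [joint_sfs_obj()].
#' @param target haploid target sizes `c(n_D, n_T)`, each `<=` the current
#'   size.
#' @return The projected `joint_sfs` (same folded state as the input).
#' @export
project_sfs <- function(S, target = c(24L, 24L)) {
  stopifnot(inherits(S, "joint_sfs"))
  target <- as.integer(target)
  if (any(target > S$n))
    stop("projection target (", paste(target, collapse = ", "),
         ") exceeds current size (", paste(S$n, collapse = ", "), ")")
  if (all(target == S$n)) return(S)
  was_folded <- S$folded
  U <- if (was_folded) unfold_sym(S) else S
  K1 <- hyper_kernel(U$n[1], target[1])
  K2 <- hyper_kernel(U$n[2], target[2])
  P <- t(K1) %*% U$counts %*% K2
  se <- if (is.null(U$se)) NULL else sqrt(t(K1^2) %*% U$se^2 %*% K2^2)
  out <- joint_sfs_obj(P, target, folded = FALSE, se = se)
  if (was_folded) out <- fold_sfs(out)
  out
}

#' Write / read a joint SFS as a plain-text matrix
#'
#' The header line records the haploid sample sizes and folded flag; the
#' remaining lines are the count matrix, rows = population D.
#'
#' @param S a [joint_sfs_obj()].
#' @param path file path.
#' @return `write_sfs` returns the path invisibly; `read_sfs` a `joint_sfs`.
#' @export
write_sfs <- function(S, path) {
  stopifnot(inherits(S, "joint_sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# joint_sfs n_D=%d n_T=%d folded=%s",
                     S$n[1], S$n[2], S$folded), con)
  utils::write.table(S$counts, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("n_D=(\\d+) n_T=(\\d+) folded=(TRUE|FALSE)", header))[[1]]
  if (length(m) != 4) stop("not a joint_sfs file: bad header in ", path)
  n <- c(as.integer(m[2]), as.integer(m[3]))
  counts <- as.matrix(utils::read.table(path, skip = 1, sep = "\t"))
  dimnames(counts) <- NULL
  joint_sfs_obj(counts, n, folded = as.logical(m[4]))
}
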