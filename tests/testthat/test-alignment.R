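make_aln <- function(seqs, groups) {
  M <- do.call(rbind, strsplit(seqs, ""))
  rownames(M) <- paste0(groups, "_", seq_along(seqs))
  structure(M, groups = factor(groups),
            class = c("marker_alignment", "matrix"))
}

test_that("column classes: variable, fixed-different, singleton", {
  aln <- make_aln(c("acgta",
                    "acgta",
                    "tcgta",
                    "tcgtc"), c("D", "D", "T", "T"))
  s <- alignment_summary(aln)
  # col 1 fixed-different (a/a vs t/t); col 5 singleton (one c); rest invariant
  expect_identical(s$n_variable, 2L)
  expect_identical(s$n_fixed_diff, 1L)
  expect_identical(s$n_singleton, 1L)
  expect_lte(s$n_fixed_diff + s$n_singleton, s$n_variable)
})

test_that("groups differing at every column give fixed-different = length", {
  aln <- make_aln(c("aaaa", "aaaa", "cccc", "cccc"), c("D", "D", "T", "T"))
  expect_identical(alignment_summary(aln)$n_fixed_diff, 4L)
})

test_that("a single-sequence group still defines fixed differences", {
  aln <- make_aln(c("acg", "tcg", "tcg"), c("D", "T", "T"))
  s <- alignment_summary(aln)
  expect_identical(s$n_fixed_diff, 1L)
  expect_identical(s$n_singleton, 0L)
})

test_that("gaps and ambiguity codes carry no state", {
  aln <- make_aln(c("a-ga", "anga", "c-ga", "cnga"), c("D", "D", "T", "T"))
  s <- alignment_summary(aln)
  expect_identical(s$n_variable, 1L)
  expect_identical(s$n_fixed_diff, 1L)
  # a group entirely gapped in a column cannot be fixed-different
  aln2 <- make_aln(c("--a", "--a", "cca", "cca"), c("D", "D", "T", "T"))
  expect_identical(alignment_summary(aln2)$n_fixed_diff, 0L)
})

test_that("summaries are invariant to sequence order and group relabeling", {
  aln <- simulate_marker_alignment(6, 9, length = 120, n_fixed_diffs = 10,
                                   singleton_rate = 0.05, seed = 3)
  s <- alignment_summary(aln)
  perm <- sample(nrow(aln))
  aln_p <- structure(unclass(aln)[perm, ], groups = attr(aln, "groups")[perm],
                     class = c("marker_alignment", "matrix"))
  s_p <- alignment_summary(aln_p)
  expect_identical(s[c("n_variable", "n_fixed_diff", "n_singleton")],
                   s_p[c("n_variable", "n_fixed_diff", "n_singleton")])
  flipped <- factor(ifelse(attr(aln, "groups") == "D", "T", "D"))
  s_f <- alignment_summary(aln, groups = flipped)
  expect_identical(s$n_fixed_diff, s_f$n_fixed_diff)
})

test_that("generator round-trip recovers the planted column budget", {
  rate <- 0.02
  aln <- simulate_marker_alignment(26, 36, length = 658, n_fixed_diffs = 58,
                                   singleton_rate = rate, seed = 11)
  s <- alignment_summary(aln)
  expect_identical(s$n_fixed_diff, 58L)
  bounds <- qpois(c(0.0005, 0.9995), rate * 658)
  expect_gte(s$n_singleton, bounds[1])
  expect_lte(s$n_singleton, bounds[2])
})

test_that("pairwise distances are Hamming proportions over comparable columns", {
  aln <- make_aln(c("aaaa", "aaat", "cccc"), c("D", "D", "T"))
  D <- pairwise_distance(aln)
  expect_equal(D["D_1", "D_2"], 0.25)
  expect_equal(D["D_1", "T_3"], 1)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  # column-by-column oracle on a random toy alignment
  withr::with_seed(9, {
    M <- matrix(sample(c("a", "c", "g", "t", "-"), 5 * 30, replace = TRUE,
                       prob = c(rep(0.23, 4), 0.08)), 5, 30)
  })
  rownames(M) <- paste0("D_", 1:5)
  aln2 <- structure(M, groups = factor(rep("D", 5)),
                    class = c("marker_alignment", "matrix"))
  D2 <- pairwise_distance(aln2)
  for (i in 1:4) for (j in (i + 1):5) {
    comp <- M[i, ] != "-" & M[j, ] != "-"
    expect_equal(D2[i, j], mean(M[i, comp] != M[j, comp]))
  }
})

test_that("fixed-difference-only variation attributes ~100% to ploidy in AMOVA", {
  aln <- simulate_marker_alignment(10, 12, length = 300, n_fixed_diffs = 30,
                                   singleton_rate = 0, seed = 6)
  res <- amova(aln, n_perm = 99, seed = 2)
  expect_gt(res$pct_among, 99)
  expect_lte(res$p_value, 0.05)
})

test_that("FASTA round-trip and ragged alignments", {
  aln <- simulate_marker_alignment(4, 5, length = 60, n_fixed_diffs = 6,
                                   singleton_rate = 0.02, seed = 8)
  path <- file.path(withr::local_tempdir(), "aln.fasta")
  write_fasta_alignment(aln, path)
  back <- read_fasta_alignment(path)
  expect_identical(unclass(back)[, ], unclass(aln)[, ])
  expect_identical(as.character(attr(back, "groups")),
                   as.character(attr(aln, "groups")))
  ragged <- file.path(withr::local_tempdir(), "ragged.fasta")
  writeLines(c(">D_1", "acgt", ">D_2", "acg"), ragged)
  expect_error(read_fasta_alignment(ragged), "ragged")
})
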