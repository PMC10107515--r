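#' Write a genotype matrix as VCF 4.2 with a population map
#'
#' Emits one biallelic record per site (`CHROM` = scaffold id, 1-based
#' `POS`, placeholder REF/ALT alleles, unphased diploid `GT`), genotype 1
#' serialized as `0/1` and missing as `./.`. The two-population sample map
#' is written alongside as a two-column tab-separated file
#' (`sample<TAB>population`).
#'
#' @param G a [genotype_matrix()].
#' @param path output VCF path (plain text).
#' @param map_path population-map path; default `<path>.popmap`.
#' @return The VCF path, invisibly.
#' @export
write_vcf <- function(G, path, map_path = paste0(path, ".popmap")) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=crossploidy",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", G$samples), collapse = "\t"))
  n_site <- ncol(G$geno)
  body <- vapply(seq_len(n_site), function(j) {
    g <- G$geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(G$scaffold[j], G$pos[j], sprintf("snp_%d", j), "A", "T", ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  write.table(data.frame(sample = G$samples, pop = as.character(G$pop)),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a biallelic VCF and population map into a genotype matrix
#'
#' Multiallelic records are rejected explicitly. Genotype fields other than
#' diploid unphased/phased calls over alleles 0/1 (or `./.`) raise an error
#' naming the offending VCF line.
#'
#' @param path VCF path (plain or gzipped).
#' @param map population map: a two-column data frame (`sample`, `pop`) or
#'   the path of a tab-separated file with those columns.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    first <- which(multi)[1]
    stop("multiallelic record at ", fix[first, "CHROM"], ":",
         fix[first, "POS"], " (record ", first, "); only biallelic SNPs ",
         "are supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # header lines precede the records: locate data lines for error reporting
  n_header <- length(v@meta) + 1L
  geno <- matrix(NA_integer_, ncol(gt), nrow(gt))
  codes <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    miss <- is.na(g) | g %in% c("./.", ".|.", ".")
    known <- codes[g]
    bad <- !miss & is.na(known)
    if (any(bad))
      stop("malformed genotype '", g[which(bad)[1]], "' at VCF line ",
           n_header + i, " (", fix[i, "CHROM"], ":", fix[i, "POS"], ")")
    geno[, i] <- ifelse(miss, NA_integer_, known)
  }
  if (is.character(map) && length(map) == 1) {
    map <- read.table(map, sep = "\t", header = FALSE,
                      col.names = c("sample", "pop"),
                      stringsAsFactors = FALSE)
  }
  samples <- colnames(gt)
  pop <- map$pop[match(samples, map$sample)]
  if (anyNA(pop))
    stop("samples missing from the population map: ",
         paste(samples[is.na(pop)], collapse = ", "))
  genotype_matrix(geno, scaffold = fix[, "CHROM"],
                  pos = as.integer(fix[, "POS"]), pop = pop,
                  samples = samples)
}

#' Write / read a truth record as a plain-text key-value table
#'
#' Serializes the generating model, the simulation configuration, the
#' per-individual true categories, and the realized per-site panel allele
#' frequencies.
#'
#' @param truth a `truth_record`.
#' @param path file path.
#' @return `write_truth` the path invisibly; `read_truth` a `truth_record`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  m <- truth$model
  kv <- c(sprintf("family\t%s", m$family),
          sprintf("nu_D\t%.17g", m$nu_D), sprintf("nu_T\t%.17g", m$nu_T),
          sprintf("T0\t%.17g", m$T0),
          if (!is.null(m$T1)) sprintf("T1\t%.17g", m$T1),
          sprintf("M_DT\t%.17g", m$M_DT), sprintf("M_TD\t%.17g", m$M_TD),
          sprintf("F_D\t%.17g", m$F_D), sprintf("F_T\t%.17g", m$F_T),
          sprintf("seed\t%d", truth$config$seed),
          sprintf("category\t%s\t%s", names(truth$category), truth$category),
          sprintf("freq\t%d\t%.17g\t%.17g", seq_len(ncol(truth$freq)),
                  truth$freq["D", ], truth$freq["T", ]))
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  key <- vapply(lines, `[`, character(1), 1)
  val1 <- vapply(lines, `[`, character(1), 2)
  get1 <- function(k) val1[key == k][1]
  num1 <- function(k) as.numeric(get1(k))
  t1 <- if ("T1" %in% key) num1("T1") else NULL
  fam <- get1("family")
  model <- demographic_model(fam, nu_D = num1("nu_D"), nu_T = num1("nu_T"),
                             T0 = num1("T0"), T1 = t1,
                             M_DT = num1("M_DT"), M_TD = num1("M_TD"),
                             F_D = num1("F_D"), F_T = num1("F_T"))
  cat_rows <- key == "category"
  category <- setNames(vapply(lines[cat_rows], `[`, character(1), 3),
                       val1[cat_rows])
  f_rows <- which(key == "freq")
  freq <- matrix(NA_real_, 2, length(f_rows), dimnames = list(c("D", "T"), NULL))
  freq["D", ] <- as.numeric(vapply(lines[f_rows], `[`, character(1), 3))
  freq["T", ] <- as.numeric(vapply(lines[f_rows], `[`, character(1), 4))
  structure(list(model = model, config = NULL, freq = freq,
                 category = category, seed = as.integer(num1("seed"))),
            class = "truth_record")
}
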