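#' Construct a genotype matrix container
#'
#' Holds an individuals x SNPs dosage matrix (values 0/1/2 or NA for missing)
#' together with ordered individual and SNP identifiers and per-SNP
#' reference-allele frequencies computed from non-missing entries only.
#'
#' @param dosages Numeric or integer matrix, individuals in rows, SNPs in
#'   columns; dimnames, if present, supply `ids` and `snp_ids`.
#' @param ids,snp_ids Optional identifier vectors overriding dimnames.
#' @return A list of class `genotype_matrix` with fields `dosages`, `ids`,
#'   `snp_ids`, `freqs`.
#' @export
genotype_matrix <- function(dosages, ids = NULL, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(ids)) ids <- rownames(dosages)
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(ncol(dosages)))
  if (length(ids) != nrow(dosages) || length(snp_ids) != ncol(dosages)) {
    stop("ids/snp_ids do not match the dosage matrix dimensions", call. = FALSE)
  }
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  dimnames(dosages) <- list(ids, snp_ids)
  structure(list(dosages = dosages, ids = ids, snp_ids = snp_ids,
                 freqs = colMeans(dosages, na.rm = TRUE) / 2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x", length(x$snp_ids),
      "SNPs;", sprintf("%.2f%% missing", 100 * mean(is.na(x$dosages))), "\n")
  invisible(x)
}

#' Hardy-Weinberg chi-square test per SNP
#'
#' One-degree-of-freedom chi-square comparing observed genotype counts with
#' the counts expected at the allele frequency estimated from the same
#' non-missing genotypes. Monomorphic SNPs return p = 1 (the statistic is 0
#' by construction).
#'
#' @param dosages Dosage matrix (individuals x SNPs), NA = missing.
#' @return Tibble with per-SNP genotype counts, chi-square statistic and
#'   p-value.
#' @export
hwe_test <- function(dosages) {
  n0 <- colSums(dosages == 0, na.rm = TRUE)
  n1 <- colSums(dosages == 1, na.rm = TRUE)
  n2 <- colSums(dosages == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- ifelse(n > 0, (n1 + 2 * n2) / (2 * n), NA_real_)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chisq <- term(n0, e0) + term(n1, e1) + term(n2, e2)
  chisq[is.na(chisq)] <- 0
  tibble::tibble(snp_id = colnames(dosages), n_called = unname(n),
                 chisq = unname(chisq),
                 p_value = stats::pchisq(unname(chisq), df = 1,
                                         lower.tail = FALSE))
}

#' SNP quality control
#'
#' Filters SNPs on per-SNP call rate, minor allele frequency and deviation
#' from Hardy-Weinberg equilibrium (chi-square test, see [hwe_test()]),
#' preserving SNP order. All three criteria are evaluated on the input
#' matrix, so a SNP failing several filters is counted under each. The
#' defaults mirror a commercial-array workflow: call rate >= 0.93,
#' MAF >= 0.01, HWE p >= 1e-7.
#'
#' @param genotypes A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency (SNPs strictly below are
#'   removed).
#' @param hwe_p_min Minimum HWE p-value (SNPs strictly below are removed).
#' @param call_rate_min Minimum per-SNP call rate.
#' @return The filtered [genotype_matrix()] with attribute `qc` holding the
#'   per-SNP report and per-filter removal counts.
#' @export
qc_filter <- function(genotypes, maf_min = 0.01, hwe_p_min = 1e-7,
                      call_rate_min = 0.93) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  thr <- c(maf_min, hwe_p_min, call_rate_min)
  if (any(thr < 0) || any(thr > 1)) {
    stop("QC thresholds must lie in [0, 1]", call. = FALSE)
  }
  dos <- genotypes$dosages
  call_rate <- colMeans(!is.na(dos))
  p <- genotypes$freqs
  maf <- pmin(p, 1 - p)
  hwe <- hwe_test(dos)

  fail_call <- call_rate < call_rate_min
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- hwe$p_value < hwe_p_min
  pass <- !(fail_call | fail_maf | fail_hwe)

  report <- tibble::tibble(
    snp_id = genotypes$snp_ids, call_rate = call_rate, maf = maf,
    hwe_p = hwe$p_value, pass = pass
  )
  removed <- c(call_rate = sum(fail_call), maf = sum(fail_maf),
               hwe = sum(fail_hwe))
  if (!any(pass)) stop("no SNPs survive QC", call. = FALSE)

  out <- genotype_matrix(dos[, pass, drop = FALSE],
                         ids = genotypes$ids,
                         snp_ids = genotypes$snp_ids[pass])
  p_true <- attr(genotypes, "p_true")
  if (!is.null(p_true)) attr(out, "p_true") <- p_true[pass]
  attr(out, "qc") <- list(report = report, removed = removed,
                          n_input = ncol(dos), n_retained = sum(pass))
  out
}

#' VanRaden method-1 genomic relationship matrix
#'
#' Computes \eqn{G = Z Z' / (2 \sum_j p_j (1 - p_j))} with
#' \eqn{Z = M - 2P}, where M is the dosage matrix and P the row-replicated
#' allele-frequency vector. Missing dosages are mean-imputed to \eqn{2 p_j}
#' before centring (they contribute zero to Z). A small multiple of the
#' identity ("bending", default 1e-6) is added so downstream REML
#' factorizations succeed; set `bend = 0` to disable.
#'
#' @param genotypes A [genotype_matrix()] with at least 2 individuals.
#' @param freq_source `"observed"` (frequencies from the sample) or
#'   `"supplied"` (use `freqs`).
#' @param freqs Per-SNP allele frequencies when `freq_source = "supplied"`.
#' @param bend Ridge added to the diagonal.
#' @return A list of class `grm` with fields `values` (symmetric matrix) and
#'   `ids`.
#' @export
vanraden_grm <- function(genotypes, freq_source = c("observed", "supplied"),
                         freqs = NULL, bend = 1e-6) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  freq_source <- match.arg(freq_source)
  dos <- genotypes$dosages
  if (nrow(dos) < 2 || ncol(dos) < 1) {
    stop("need at least 2 individuals and 1 SNP", call. = FALSE)
  }
  if (any(colMeans(is.na(dos)) == 1)) {
    stop("all-missing SNP present; run qc_filter first", call. = FALSE)
  }
  p <- switch(freq_source,
              observed = genotypes$freqs,
              supplied = {
                if (is.null(freqs) || length(freqs) != ncol(dos)) {
                  stop("supplied freqs must match the number of SNPs", call. = FALSE)
                }
                freqs
              })
  denom <- 2 * sum(p * (1 - p))
  if (denom <= .Machine$double.eps) {
    stop("degenerate panel: 2*sum(p(1-p)) is zero (all SNPs monomorphic)",
         call. = FALSE)
  }
  Z <- sweep(dos, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  if (bend > 0) G <- G + diag(bend, nrow(G))
  dimnames(G) <- list(genotypes$ids, genotypes$ids)
  structure(list(values = G, ids = genotypes$ids, bend = bend), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$ids), "individuals; mean diagonal",
      sprintf("%.3f", mean(diag(x$values))), "\n")
  invisible(x)
}

#' @export
as.matrix.grm <- function(x, ...) x$values

# ---- file formats ---------------------------------------------------------

#' Write genotype dosages as CSV
#'
#' Rows are individuals (first column `id`), columns are SNP identifiers.
#' @param genotypes A [genotype_matrix()].
#' @param path Output file.
#' @export
write_dosage_csv <- function(genotypes, path) {
  df <- data.frame(id = genotypes$ids, genotypes$dosages,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotype dosages from CSV (as written by [write_dosage_csv()])
#' @param path Input file.
#' @return A [genotype_matrix()].
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  genotype_matrix(m)
}

#' Write genotypes as a minimal diploid VCF
#'
#' Emits VCFv4.2 with unphased GT calls (0 -> 0/0, 1 -> 0/1, 2 -> 1/1,
#' missing -> ./.); SNPs are placed at consecutive positions on one contig.
#' @param genotypes A [genotype_matrix()].
#' @param path Output file.
#' @export
write_vcf_dosages <- function(genotypes, path) {
  dos <- genotypes$dosages
  gt <- matrix("./.", nrow(dos), ncol(dos))
  gt[!is.na(dos) & dos == 0] <- "0/0"
  gt[!is.na(dos) & dos == 1] <- "0/1"
  gt[!is.na(dos) & dos == 2] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=proxyval",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$ids), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(dos)), function(j) {
    paste(c("1", j, genotypes$snp_ids[j], "A", "G", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Uses vcfR to parse the file and converts GT calls to alternate-allele
#' dosages (half-missing calls are treated as missing).
#' @param path VCF file (uncompressed or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- ifelse(a1 %in% c("0", "1") & a2 %in% c("0", "1"),
                as.integer(a1 == "1") + as.integer(a2 == "1"), NA_integer_)
  dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  genotype_matrix(t(dos))
}

#' Write a GRM as a square tab-delimited matrix with ID header and row names
#' @param grm A [vanraden_grm()] result.
#' @param path Output file.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(id = grm$ids, grm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GRM written by [write_grm()]
#' @param path Input file.
#' @return A `grm` object.
#' @export
read_grm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(list(values = m, ids = df[[1]], bend = NA_real_), class = "grm")
}
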