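#' Per-SNP call rate
#'
#' Fraction of animals with a non-missing call at each SNP.
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector in `[0, 1]`, one entry per SNP.
#' @export
compute_call_rate <- function(g) {
  if (n_animals(g) == 0 || n_snps(g) == 0) stop("empty genotype matrix")
  colMeans(!is.na(g$calls))
}

#' Per-SNP minor allele frequency
#'
#' The B-allele frequency is computed over non-missing calls only,
#' `p = sum(calls) / (2 * n_nonmissing)`, and the MAF is `min(p, 1 - p)`.
#' SNPs with no non-missing call get `NA` (MAF undefined; such SNPs fail
#' every frequency filter).
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector in `[0, 0.5]` (or `NA`), one entry per SNP.
#' @export
compute_maf <- function(g) {
  if (n_animals(g) == 0 || n_snps(g) == 0) stop("empty genotype matrix")
  nonmiss <- colSums(!is.na(g$calls))
  p <- colSums(g$calls, na.rm = TRUE) / (2 * nonmiss)
  p[nonmiss == 0] <- NA_real_
  pmin(p, 1 - p)
}

#' SNP quality control: missingness then minor allele frequency
#'
#' Applies the two marker filters in sequence: first remove SNPs whose
#' missing fraction exceeds `max_missing` (call rate below
#' `1 - max_missing`), then remove SNPs whose MAF is not strictly greater
#' than `min_maf`. The kept set is the conjunction of the two conditions,
#' so the result does not depend on the order; the report counts both
#' stages separately.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction per SNP, in
#'   `[0, 1]`; the default 0.10 keeps SNPs with call rate >= 90%.
#' @param min_maf MAF threshold in `[0, 0.5]`; SNPs are kept when
#'   `maf > min_maf` (strict).
#' @return A list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (class `qc_report`: counts per
#'   stage, per-SNP `call_rate` and `maf`, and `kept_snp_ids`).
#' @export
apply_qc <- function(g, max_missing = 0.10, min_maf = 0.01) {
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing > 1) {
    stop("max_missing must lie in [0, 1]")
  }
  if (!is.numeric(min_maf) || min_maf < 0 || min_maf > 0.5) {
    stop("min_maf must lie in [0, 0.5]")
  }
  call_rate <- compute_call_rate(g)
  maf <- compute_maf(g)
  pass_geno <- call_rate >= 1 - max_missing
  pass_maf <- !is.na(maf) & maf > min_maf
  keep <- pass_geno & pass_maf
  report <- structure(
    list(n_input_snps = n_snps(g),
         n_after_geno = sum(pass_geno),
         n_after_maf = sum(keep),
         call_rate = call_rate, maf = maf,
         kept_snp_ids = g$snp_ids[keep],
         max_missing = max_missing, min_maf = min_maf),
    class = "qc_report")
  list(genotypes = subset_snps(g, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC:", x$n_input_snps, "input;",
      x$n_after_geno, sprintf("pass missingness <= %g;", x$max_missing),
      x$n_after_maf, sprintf("also pass MAF > %g\n", x$min_maf))
  invisible(x)
}

#' Write a QC report as tab-delimited text
#'
#' One row per input SNP with its call rate, MAF and kept flag; stage
#' counts go into comment lines at the top.
#'
#' @param report A `qc_report` from [apply_qc()].
#' @param path Output path.
#' @param snp_ids SNP identifiers of the input panel (same order as the
#'   report's per-SNP vectors).
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path, snp_ids = names(report$call_rate)) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# n_input_snps\t", report$n_input_snps),
    paste0("# n_after_geno\t", report$n_after_geno),
    paste0("# n_after_maf\t", report$n_after_maf)), con)
  df <- data.frame(snp_id = snp_ids, call_rate = report$call_rate,
                   maf = report$maf,
                   kept = snp_ids %in% report$kept_snp_ids)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
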