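# Two-locus EM for haplotype frequencies from unphased genotype counts.
# n3x3[i, j] counts animals with i-1 copies of the B allele at locus 1 and
# j-1 at locus 2. Only the double heterozygote class is phase-ambiguous;
# its expected cis/trans split is recomputed from the current frequencies.
.two_locus_em <- function(n3x3, max_iter = 1000, tol = 1e-12) {
  n <- sum(n3x3)
  pB1 <- sum(n3x3 * matrix(0:2, 3, 3)) / (2 * n)
  pB2 <- sum(n3x3 * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  # haplotype order: (B,B), (B,b), (b,B), (b,b)
  h <- c(pB1 * pB2, pB1 * (1 - pB2), (1 - pB1) * pB2, (1 - pB1) * (1 - pB2))
  n_dh <- n3x3[2, 2]
  # unambiguous haplotype counts contributed by the eight other classes
  base <- c(
    2 * n3x3[3, 3] + n3x3[3, 2] + n3x3[2, 3],                    # BB
    2 * n3x3[3, 1] + n3x3[3, 2] + n3x3[2, 1],                    # Bb
    2 * n3x3[1, 3] + n3x3[1, 2] + n3x3[2, 3],                    # bB
    2 * n3x3[1, 1] + n3x3[1, 2] + n3x3[2, 1])                    # bb
  for (it in seq_len(max_iter)) {
    denom <- h[1] * h[4] + h[2] * h[3]
    cis <- if (denom > 0) h[1] * h[4] / denom else 0.5
    cnt <- base + n_dh * c(cis, 1 - cis, 1 - cis, cis)
    h_new <- cnt / (2 * n)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  h
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Estimates the squared allelic correlation between two SNPs from
#' unphased genotypes. Two-locus haplotype frequencies are fitted by an EM
#' algorithm (double heterozygotes split between cis and trans phase in
#' proportion to the current frequency estimates — the estimator PLINK
#' reports for unphased data); then `D = p_AB - p_A p_B` and
#' `r2 = D^2 / (p_A p_a p_B p_b)`. Computed over animals with both calls
#' non-missing. Returns 0 when either locus is monomorphic among those
#' animals, and `NA` when fewer than two complete pairs exist.
#'
#' @param g A [genotype_matrix()].
#' @param snp_a,snp_b SNP indices or ids; must lie on the same chromosome.
#' @return A single value in `[0, 1]`, or `NA` if undefined.
#' @export
pairwise_r2 <- function(g, snp_a, snp_b) {
  if (is.character(snp_a)) snp_a <- match(snp_a, g$snp_ids)
  if (is.character(snp_b)) snp_b <- match(snp_b, g$snp_ids)
  if (g$chromosome[snp_a] != g$chromosome[snp_b]) {
    stop("SNPs lie on different chromosomes; r2 is computed within chromosome")
  }
  .r2_from_calls(g$calls[, snp_a], g$calls[, snp_b])
}

.r2_from_calls <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  g1 <- g1[ok]
  g2 <- g2[ok]
  n3x3 <- matrix(tabulate(3L * g1 + g2 + 1L, 9L), 3, 3, byrow = TRUE)
  pB1 <- mean(g1) / 2
  pB2 <- mean(g2) / 2
  if (pB1 %in% c(0, 1) || pB2 %in% c(0, 1)) return(0)
  h <- .two_locus_em(n3x3)
  pA <- h[1] + h[2]
  pB <- h[1] + h[3]
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) return(0)
  D <- h[1] - pA * pB
  min(1, D^2 / denom)
}

#' Assemble blocks of linked SNPs
#'
#' Within each chromosome, r-squared is computed for every pair of SNPs at
#' most `window_snps` apart in map order; pairs with `r2 >= r2_threshold`
#' become edges of an undirected graph, and blocks are the connected
#' components with at least two SNPs (single-linkage, so blocks need not
#' be contiguous runs; SNP indices are reported sorted by position).
#' Setting `window_snps` to the chromosome's SNP count reproduces the
#' all-pairs computation.
#'
#' @param g A [genotype_matrix()] (normally QC-passed).
#' @param r2_threshold Linkage threshold in `(0, 1]`; pairs at or above it
#'   are linked. The analysis default is 0.8; 0.9 is the stricter setting.
#' @param window_snps Maximum map-order distance (in SNPs) between members
#'   of a computed pair.
#' @param contiguous If `TRUE`, only adjacent-in-map pairs can be linked,
#'   forcing blocks to be contiguous runs (sensitivity mode).
#' @param keep_pairs If `TRUE`, also return the table of computed pairs.
#' @return A list of class `ld_blocks` with elements `blocks` (list of
#'   lists: `block_id`, `chromosome`, `snp_indices` into the panel,
#'   `snp_ids`, `size`), `r2_threshold`, and (optionally) `pairs`.
#' @export
build_blocks <- function(g, r2_threshold = 0.8, window_snps = 50,
                         contiguous = FALSE, keep_pairs = FALSE) {
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must lie in (0, 1]")
  }
  if (window_snps < 1) stop("window_snps must be >= 1")
  pairs <- NULL
  edges <- NULL
  for (chr in unique(g$chromosome)) {
    idx <- which(g$chromosome == chr)
    m <- length(idx)
    if (m < 2) next
    for (i in seq_len(m - 1)) {
      jmax <- if (contiguous) i + 1 else min(m, i + window_snps)
      for (j in seq(i + 1, jmax)) {
        r2 <- .r2_from_calls(g$calls[, idx[i]], g$calls[, idx[j]])
        if (keep_pairs) {
          pairs <- rbind(pairs, data.frame(
            snp_a = idx[i], snp_b = idx[j], r2 = r2))
        }
        if (!is.na(r2) && r2 >= r2_threshold) {
          edges <- rbind(edges, c(idx[i], idx[j]))
        }
      }
    }
  }
  blocks <- list()
  if (!is.null(edges)) {
    verts <- sort(unique(as.vector(edges)))
    gr <- igraph::graph_from_edgelist(
      matrix(match(edges, verts), ncol = 2), directed = FALSE)
    comp <- igraph::components(gr)
    for (k in seq_len(comp$no)) {
      members <- verts[comp$membership == k]
      if (length(members) < 2) next
      members <- members[order(g$position[members])]
      blocks[[length(blocks) + 1L]] <- list(
        chromosome = g$chromosome[members[1]],
        snp_indices = members, snp_ids = g$snp_ids[members],
        size = length(members))
    }
    # deterministic order: chromosome map order, then first position
    ord <- order(match(vapply(blocks, `[[`, character(1), "chromosome"),
                       unique(g$chromosome)),
                 vapply(blocks, function(b) g$position[b$snp_indices[1]],
                        numeric(1)))
    blocks <- blocks[ord]
    for (k in seq_along(blocks)) blocks[[k]]$block_id <- k
  }
  structure(list(blocks = blocks, r2_threshold = r2_threshold,
                 window_snps = window_snps, pairs = pairs),
            class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  sizes <- vapply(x$blocks, `[[`, integer(1), "size")
  cat("ld_blocks:", length(x$blocks), "blocks at r2 >=", x$r2_threshold,
      if (length(sizes)) paste0("(sizes ", min(sizes), "-", max(sizes), ")"),
      "\n")
  invisible(x)
}

#' Write LD blocks as tab-delimited text
#'
#' Columns: block_id, chromosome, n_snps, snp_ids (comma-joined).
#'
#' @param blocks An `ld_blocks` object from [build_blocks()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_blocks <- function(blocks, path) {
  df <- data.frame(
    block_id = vapply(blocks$blocks, `[[`, integer(1), "block_id"),
    chromosome = vapply(blocks$blocks, `[[`, character(1), "chromosome"),
    n_snps = vapply(blocks$blocks, `[[`, integer(1), "size"),
    snp_ids = vapply(blocks$blocks, function(b) paste(b$snp_ids, collapse = ","),
                     character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
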