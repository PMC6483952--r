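# Small in-code fixtures shared across test files.

# genotype matrix from a plain call matrix, one chromosome, unit spacing
gm <- function(calls, chromosome = rep("1", ncol(calls)),
               position = seq_len(ncol(calls))) {
  calls <- as.matrix(calls)
  dimnames(calls) <- NULL
  genotype_matrix(calls, chromosome = chromosome, position = position)
}

# all-homozygous two-SNP panel drawn from a two-haplotype pool:
# `n_cis` animals carry (B,B)/(B,B), `n_trans` carry (b,b)/(b,b)
perfect_ld_panel <- function(n_cis, n_trans) {
  calls <- rbind(matrix(2L, n_cis, 2), matrix(0L, n_trans, 2))
  gm(calls)
}

# three-SNP panel: SNP1 and SNP2 identical (r2 = 1); SNP3 linked to both
# at r2 = 0.818 (haplotype counts AB:9, Ab:1, ab:10 over 20 chromosomes,
# no double heterozygotes, so the EM fixed point is the counting estimate)
three_snp_ld_panel <- function() {
  s12 <- c(rep(2L, 5), rep(0L, 5))
  s3 <- c(rep(2L, 4), 1L, rep(0L, 5))
  gm(cbind(s12, s12, s3))
}
r2_three_snp_hand <- (0.45 - 0.5 * 0.45)^2 / (0.5 * 0.5 * 0.45 * 0.55)

# six-SNP QC fixture over 20 animals: SNP2 is 15% missing (fails
# GENO < 0.10), SNP5 has MAF 0.005 (one het in 100 alleles... here one
# het among 20 animals = 1/40 = 0.025 > 0.01, so use a monomorphic SNP
# made nearly so), the other four are clean
qc_fixture <- function() {
  set.seed(11)
  n <- 20
  clean <- function() sample(0:2, n, replace = TRUE, prob = c(.25, .5, .25))
  calls <- cbind(clean(), clean(), clean(), clean(), clean(), clean())
  calls[1:3, 2] <- NA            # 15% missing -> call rate 0.85
  calls[, 5] <- 0L               # monomorphic -> MAF 0
  storage.mode(calls) <- "integer"
  gm(calls)
}
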