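#!/usr/bin/env Rscript
# Stage 2 — SNP quality control.
#
# Drops SNPs with more than 10% missing genotypes (GENO < 0.1), then
# applies the minor allele frequency filter. Both MAF cuts of the study
# design (> 0.01 and > 0.05) are reported; the MAF > 0.01 panel is
# carried forward.

library(haploblup)

g <- read_ped_map("results/data/genotypes.ped", "results/data/genotypes.map")
message("Input panel: ", length(g$snp_ids), " SNPs, ",
        length(g$animal_ids), " animals.")

for (maf in c(0.01, 0.05)) {
  res <- apply_qc(g, max_missing = 0.10, min_maf = maf)
  message(sprintf("GENO < 0.10 then MAF > %.2f: %d -> %d -> %d SNPs",
                  maf, res$report$n_input_snps, res$report$n_after_geno,
                  res$report$n_after_maf))
}

res <- apply_qc(g, max_missing = 0.10, min_maf = 0.01)
write_qc_report(res$report, "results/qc_report.tsv", snp_ids = g$snp_ids)
write_ped_map(res$genotypes, "results/genotypes_qc.ped",
              "results/genotypes_qc.map")
message("Kept panel written: results/genotypes_qc.{ped,map}")
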