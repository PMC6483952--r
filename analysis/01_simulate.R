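#!/usr/bin/env Rscript
# Stage 1 — simulate the study population.
#
# Generates a desk-scale stand-in for a progeny-tested dairy bull
# population: 1216 bulls born 1987-2003, genotyped on a block-structured
# panel (40 haplotype blocks of 2-6 SNPs spread over 29 autosomes, 4
# haplotype alleles per block), with milk-yield-like trait parameters
# (h2 = 0.33, sigma2_g = 213,490) and proof reliabilities 0.70-0.99.
# Ground truth (true haplotype effects, TBV, diplotypes) is written
# alongside so later stages can be checked against it.

library(haploblup)

out <- "results/data"
cfg <- simulation_config(n_animals = 1216, n_blocks = 40, seed = 20190315)
pop <- simulate_population(cfg)
paths <- write_population(pop, out)

message("Simulated ", cfg$n_animals, " bulls, ", cfg$n_blocks, " blocks, ",
        length(pop$genotypes$snp_ids), " SNPs (",
        sprintf("%.1f%%", 100 * mean(is.na(pop$genotypes$calls))),
        " missing calls).")
message("TBV: mean = ", signif(mean(pop$tbv), 4), ", var = ",
        signif(var(pop$tbv), 6), " (target sigma2_g = ",
        cfg$genetic_variance, ").")
message("Artifacts: ", paste(basename(paths), collapse = ", "),
        " under ", out)
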