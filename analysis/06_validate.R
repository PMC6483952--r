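#!/usr/bin/env Rscript
# Stage 6 — generational cross-validation.
#
# Scores each model's DGV against EBV by Pearson correlation and by the
# regression of EBV on DGV, separately for the training generation
# (in-sample) and the held-out youngest bulls. Slopes above 1 indicate
# underestimated DGV dispersion.

library(haploblup)

proofs <- read_trait_table("results/traits_drp.tsv")
split <- generational_split(proofs, 0.875)

report <- do.call(rbind, lapply(1:4, function(v) {
  dgv <- read.delim(sprintf("results/dgv_model%d.tsv", v),
                    colClasses = c(animal_id = "character"))
  cbind(variant = v, trait = "MY", validation_report(proofs, dgv, split))
}))
write.table(report, "results/validation_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Validation report (train n = ", length(split$train),
        ", validation n = ", length(split$validation), "):")
for (i in seq_len(nrow(report))) {
  message(sprintf("  model %d %-10s r = %5.2f  slope = %6.2f",
                  report$variant[i], report$subset[i],
                  report$pearson_r[i], report$slope[i]))
}
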