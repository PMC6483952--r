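#!/usr/bin/env Rscript
# Stage 5 — deregression and the four model variants.
#
# Proofs are deregressed by the reliability-scaled deviation rule, then
# the random-haplotype-effect model y = mu + Zh + e is solved through the
# mixed model equations for each variant: probability vs indicator Z,
# crossed with equal vs size-weighted partition of the genetic variance.
# Only the oldest 87.5% of bulls (the training generation) enter the
# equations; DGV = Zh is predicted for everyone.

library(haploblup)

proofs <- deregress(read_trait_table("results/data/traits.tsv"))
write_trait_table(proofs, "results/traits_drp.tsv")

posteriors <- read.delim("results/posteriors.tsv",
                         colClasses = c(animal_id = "character"))
selected <- read.delim("results/haplotypes_selected.tsv",
                       colClasses = c(allele_string = "character"))

trait <- trait_spec("MY", heritability = 0.33, genetic_variance = 213490)
split <- generational_split(proofs, 0.875)
idx <- match(split$train, proofs$animal_id)
message("Training on ", length(split$train), " oldest bulls; predicting ",
        nrow(proofs), ".")

for (v in 1:4) {
  vdef <- model_variant(v)
  Z <- build_design_matrix(posteriors, selected, proofs$animal_id,
                           z_kind = vdef$z_kind)
  s2h <- partition_variance(selected, trait$genetic_variance,
                            scheme = vdef$variance_scheme)
  fit <- solve_model(proofs$drp[idx], Z[idx, , drop = FALSE], s2h,
                     trait$error_variance)
  dgv <- predict_dgv(Z, fit)
  write.table(data.frame(haplotype = names(fit$effects),
                         effect = fit$effects, variance = s2h,
                         row.names = NULL),
              sprintf("results/effects_model%d.tsv", v),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dgv, sprintf("results/dgv_model%d.tsv", v), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("Model %d (%s Z, %s variance): %d effects, mu = %.2f",
                  v, vdef$z_kind, vdef$variance_scheme,
                  length(fit$effects), fit$mu_hat))
}
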