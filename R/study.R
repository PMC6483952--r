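#' Phase set from simulation ground truth
#'
#' Converts the true diplotypes of a simulated population into the same
#' structure [phase_blocks()] produces — every posterior is a point mass
#' on the true unordered pair, population frequencies are the drawn
#' Dirichlet frequencies and carrier frequencies are counted directly.
#' Useful for parameter-recovery studies that isolate the model from
#' phasing uncertainty.
#'
#' @param pop A `true_population` from [simulate_population()].
#' @return A `phase_set` (see [phase_blocks()]).
#' @export
true_phase_set <- function(pop) {
  n <- nrow(pop$d1)
  B <- ncol(pop$d1)
  ids <- pop$proofs$animal_id
  hap_rows <- vector("list", B)
  post_rows <- vector("list", B)
  for (b in seq_len(B)) {
    A <- length(pop$allele_freqs[[b]])
    carriers <- vapply(seq_len(A), function(j)
      mean(pop$d1[, b] == j | pop$d2[, b] == j), numeric(1))
    hap_rows[[b]] <- data.frame(
      block_id = b, chromosome = pop$block_chromosome[b],
      block_size = length(pop$block_snps[[b]]),
      allele_index = seq_len(A),
      allele_string = apply(pop$allele_strings[[b]], 1, paste, collapse = ""),
      population_frequency = pop$allele_freqs[[b]],
      carrier_frequency = carriers)
    post_rows[[b]] <- data.frame(
      animal = seq_len(n), animal_id = ids, block_id = b,
      a = pmin(pop$d1[, b], pop$d2[, b]),
      b = pmax(pop$d1[, b], pop$d2[, b]),
      probability = 1)
  }
  structure(list(haplotypes = do.call(rbind, hap_rows),
                 posteriors = do.call(rbind, post_rows),
                 skipped_blocks = integer(0)),
            class = "phase_set")
}

#' Progeny-test reliability implied by heritability
#'
#' Reliability of a sire proof from `n_daughters` effective daughter
#' records: `REL = n t / (1 + (n - 1) t)` with `t = h2 / 4` (the
#' half-sib intraclass correlation). Ties proof reliability to trait
#' heritability so that low-heritability traits carry noisier proofs, as
#' in progeny-tested bull populations.
#'
#' @param h2 Heritability in `(0, 1]`.
#' @param n_daughters Effective daughter count.
#' @return Reliability in `(0, 1)`.
#' @export
progeny_test_reliability <- function(h2, n_daughters = 100) {
  t <- h2 / 4
  n_daughters * t / (1 + (n_daughters - 1) * t)
}

#' One seeded simulation-to-validation replicate
#'
#' Runs a single replicate of the simulation study: simulate a population,
#' phase its blocks by EM (the simulated block layout is used, so LD block
#' discovery is not repeated), keep haplotypes above the carrier-frequency
#' threshold, deregress the proofs, fit one model variant on the
#' generational training set — optionally with the per-haplotype variances
#' multiplied by `shrink` to study deliberate over-shrinkage — and score
#' DGV against EBV on both subsets.
#'
#' @param config A [simulation_config()].
#' @param variant Model variant 1-4 (see [model_variant()]).
#' @param shrink Multiplier applied to the per-haplotype variances
#'   (1 = the variant's own partition; values << 1 over-shrink).
#' @param train_fraction Passed to [generational_split()].
#' @param freq_threshold Carrier-frequency cut for haplotype selection.
#' @param use_true_phase If `TRUE`, use the ground-truth diplotypes
#'   instead of EM phasing.
#' @return The [validation_report()] data.frame, with the number of
#'   selected haplotypes attached as attribute `"n_selected"`.
#' @export
replicate_validation <- function(config, variant = 1, shrink = 1,
                                 train_fraction = 0.875,
                                 freq_threshold = 0.25,
                                 use_true_phase = FALSE) {
  pop <- simulate_population(config)
  phased <- if (use_true_phase) {
    true_phase_set(pop)
  } else {
    phase_blocks(pop$genotypes, pop$block_snps)
  }
  selected <- select_frequent_haplotypes(phased$haplotypes,
                                         threshold = freq_threshold)
  if (nrow(selected) == 0) stop("no haplotype passed the frequency filter")
  vdef <- model_variant(variant)
  proofs <- deregress(pop$proofs)
  split <- generational_split(proofs, train_fraction)
  Z <- build_design_matrix(phased$posteriors, selected,
                           animal_ids = proofs$animal_id,
                           z_kind = vdef$z_kind)
  s2h <- partition_variance(selected, config$genetic_variance,
                            scheme = vdef$variance_scheme) * shrink
  trait <- trait_spec("sim", config$heritability, config$genetic_variance)
  idx <- match(split$train, proofs$animal_id)
  fit <- solve_model(proofs$drp[idx], Z[idx, , drop = FALSE], s2h,
                     trait$error_variance)
  dgv <- predict_dgv(Z, fit)
  rep <- validation_report(proofs, dgv, split)
  attr(rep, "n_selected") <- nrow(selected)
  rep
}
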