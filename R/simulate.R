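#' Configuration for the synthetic population generator
#'
#' Collects and validates every parameter of [simulate_population()]. The
#' defaults describe a desk-scale progeny-tested dairy bull population:
#' block-structured genotypes with a handful of common haplotype alleles
#' per block, milk-yield-like trait parameters, high proof reliabilities
#' and birth years wide enough for a generational split.
#'
#' @param n_animals Number of animals.
#' @param n_blocks Number of independent haplotype blocks.
#' @param block_size_range Integer pair `(min, max)` of SNPs per block
#'   (`min >= 2`).
#' @param alleles_per_block Number of distinct haplotype alleles segregating
#'   in each block (`>= 2`, and at most `2^min(block_size_range)`).
#' @param allele_freq_concentration Positive concentration of the symmetric
#'   Dirichlet from which the haplotype allele frequencies of each block are
#'   drawn; large values give near-equal frequencies.
#' @param heritability Trait heritability, in `(0, 1]`.
#' @param genetic_variance Additive genetic variance of the trait, in
#'   squared trait units (`> 0`).
#' @param reliability_range Pair in `(0, 1]` (min <= max); each animal's
#'   proof reliability is drawn uniformly from this interval.
#' @param birth_year_range Integer pair of first and last birth year.
#' @param missing_rate Probability that any genotype call is set missing,
#'   in `[0, 1)`.
#' @param seed Integer seed; every draw of the generator flows from it.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_animals = 500,
                              n_blocks = 40,
                              block_size_range = c(2L, 6L),
                              alleles_per_block = 4,
                              allele_freq_concentration = 1,
                              heritability = 0.33,
                              genetic_variance = 213490,
                              reliability_range = c(0.70, 0.99),
                              birth_year_range = c(1987L, 2003L),
                              missing_rate = 0.02,
                              seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid '", field, "': ", msg, call. = FALSE)
  }
  chk(is.numeric(n_animals) && n_animals >= 2, "n_animals", "need >= 2 animals")
  chk(is.numeric(n_blocks) && n_blocks >= 1, "n_blocks", "need >= 1 block")
  chk(length(block_size_range) == 2 && block_size_range[1] >= 2 &&
        block_size_range[1] <= block_size_range[2],
      "block_size_range", "need 2 <= min <= max")
  chk(alleles_per_block >= 2, "alleles_per_block", "need >= 2 alleles")
  chk(alleles_per_block <= 2^block_size_range[1], "alleles_per_block",
      "cannot exceed 2^min(block_size_range) distinct haplotypes")
  chk(allele_freq_concentration > 0, "allele_freq_concentration",
      "must be positive")
  chk(heritability > 0 && heritability <= 1, "heritability",
      "must lie in (0, 1]")
  chk(genetic_variance > 0, "genetic_variance", "must be positive")
  chk(length(reliability_range) == 2 && reliability_range[1] > 0 &&
        reliability_range[2] <= 1 &&
        reliability_range[1] <= reliability_range[2],
      "reliability_range", "need values in (0, 1] with min <= max")
  chk(length(birth_year_range) == 2 &&
        birth_year_range[1] <= birth_year_range[2],
      "birth_year_range", "need min <= max")
  chk(missing_rate >= 0 && missing_rate < 1, "missing_rate",
      "must lie in [0, 1)")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be one integer")
  structure(
    list(n_animals = as.integer(n_animals), n_blocks = as.integer(n_blocks),
         block_size_range = as.integer(block_size_range),
         alleles_per_block = as.integer(alleles_per_block),
         allele_freq_concentration = allele_freq_concentration,
         heritability = heritability, genetic_variance = genetic_variance,
         reliability_range = reliability_range,
         birth_year_range = as.integer(birth_year_range),
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# distinct random haplotype strings of length L, as a (A x L) 0/1 matrix
.draw_allele_strings <- function(n_alleles, block_size) {
  codes <- sample.int(2^block_size, n_alleles) - 1L
  t(vapply(codes, function(x) as.integer(intToBits(x)[1:block_size]),
           integer(block_size)))
}

#' Simulate a block-structured population with known haplotype effects
#'
#' Generates genotypes, true diplotypes, per-haplotype effects, true
#' breeding values and proof records under the structure the haplotype
#' model assumes. Per block, haplotype allele frequencies are drawn from a
#' symmetric Dirichlet; diplotypes are drawn independently per animal under
#' Hardy-Weinberg; haplotype effects are drawn from the equal-partition
#' prior `N(0, sigma2_g / H)` (H = total haplotype count), centred within
#' block on the frequency-weighted mean, and rescaled once so that the
#' analytic variance of the sum of the two transmitted effects equals
#' `genetic_variance` exactly. EBV = TBV + noise with noise variance
#' `sigma2_g * (1 - REL) / REL` (the prediction-error-variance relation)
#' and REL uniform on `reliability_range`; birth years are uniform on
#' `birth_year_range`. Missing calls are then injected at `missing_rate`.
#'
#' Blocks are mutually independent (no between-block linkage
#' disequilibrium) and are laid out across cattle autosomes 1-29 with wide
#' gaps so that LD-based block discovery cannot bridge them.
#'
#' @param config A [simulation_config()].
#' @return An object of class `true_population`: list with elements
#'   `genotypes` (after missingness), `genotypes_complete`,
#'   `block_snps` (list of SNP column indices per block), `allele_strings`
#'   (list of A x L 0/1 matrices), `allele_freqs`, `effects` (list of
#'   per-allele effects), `diplotypes` (two n x B matrices `d1`, `d2` of
#'   allele indices, ordered internally but unordered in meaning), `tbv`,
#'   and `proofs` (data.frame: animal_id, birth_year, ebv, reliability).
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "simulation_config")) config <- do.call(simulation_config, config)
  set.seed(config$seed)
  n <- config$n_animals
  B <- config$n_blocks
  A <- config$alleles_per_block

  sizes <- sample(seq(config$block_size_range[1], config$block_size_range[2]),
                  B, replace = TRUE)
  block_chr <- as.character(rep_len(1:29, B))

  allele_strings <- vector("list", B)
  allele_freqs <- vector("list", B)
  d1 <- matrix(0L, n, B)
  d2 <- matrix(0L, n, B)
  for (b in seq_len(B)) {
    allele_strings[[b]] <- .draw_allele_strings(A, sizes[b])
    f <- stats::rgamma(A, shape = config$allele_freq_concentration)
    allele_freqs[[b]] <- f / sum(f)
    d1[, b] <- sample.int(A, n, replace = TRUE, prob = allele_freqs[[b]])
    d2[, b] <- sample.int(A, n, replace = TRUE, prob = allele_freqs[[b]])
  }

  # effects: equal-partition prior, centred per block, scaled so that the
  # analytic var(TBV) given the drawn frequencies is exactly sigma2_g
  H <- B * A
  effects <- lapply(seq_len(B), function(b) {
    e <- stats::rnorm(A, 0, sqrt(config$genetic_variance / H))
    e - sum(allele_freqs[[b]] * e)
  })
  v_block <- vapply(seq_len(B), function(b) {
    sum(allele_freqs[[b]] * effects[[b]]^2)
  }, numeric(1))
  total_var <- 2 * sum(v_block)
  if (total_var > 0) {
    s <- sqrt(config$genetic_variance / total_var)
    effects <- lapply(effects, function(e) e * s)
  }

  tbv <- rowSums(vapply(seq_len(B), function(b) {
    effects[[b]][d1[, b]] + effects[[b]][d2[, b]]
  }, numeric(n)))

  # genotype matrix: per block, per SNP, sum of the two alleles' bits
  n_snp <- sum(sizes)
  calls <- matrix(0L, n, n_snp)
  chromosome <- character(n_snp)
  position <- integer(n_snp)
  block_snps <- vector("list", B)
  col <- 0L
  chr_pos <- setNames(rep(0L, 29), as.character(1:29))
  for (b in seq_len(B)) {
    bits <- allele_strings[[b]]
    idx <- col + seq_len(sizes[b])
    block_snps[[b]] <- idx
    calls[, idx] <- bits[d1[, b], , drop = FALSE] + bits[d2[, b], , drop = FALSE]
    chromosome[idx] <- block_chr[b]
    start <- chr_pos[block_chr[b]] + 1000000L
    position[idx] <- start + 10000L * (seq_len(sizes[b]) - 1L)
    chr_pos[block_chr[b]] <- position[idx[sizes[b]]]
    col <- col + sizes[b]
  }
  animal_ids <- sprintf("ID%04d", seq_len(n))
  snp_ids <- sprintf("SNP%05d", seq_len(n_snp))
  complete <- genotype_matrix(calls, chromosome = chromosome,
                              position = position,
                              animal_ids = animal_ids, snp_ids = snp_ids)

  rel <- stats::runif(n, config$reliability_range[1], config$reliability_range[2])
  noise_sd <- sqrt(config$genetic_variance * (1 - rel) / rel)
  ebv <- tbv + stats::rnorm(n, 0, noise_sd)
  birth_year <- sample(seq(config$birth_year_range[1], config$birth_year_range[2]),
                       n, replace = TRUE)
  proofs <- data.frame(animal_id = animal_ids, birth_year = birth_year,
                       ebv = ebv, reliability = rel,
                       stringsAsFactors = FALSE)

  genotypes <- if (config$missing_rate > 0) {
    inject_missingness(complete, config$missing_rate,
                       seed = config$seed + 1L)
  } else {
    complete
  }

  structure(
    list(genotypes = genotypes, genotypes_complete = complete,
         block_snps = block_snps, block_chromosome = block_chr,
         allele_strings = allele_strings, allele_freqs = allele_freqs,
         effects = effects, d1 = d1, d2 = d2, tbv = tbv, proofs = proofs,
         config = config),
    class = "true_population"
  )
}

#' @export
print.true_population <- function(x, ...) {
  cat("true_population:", x$config$n_animals, "animals,",
      x$config$n_blocks, "blocks,", n_snps(x$genotypes), "SNPs\n")
  invisible(x)
}

#' Set genotype calls missing at random
#'
#' Each call is independently replaced by `NA` with probability `rate`.
#'
#' @param g A [genotype_matrix()] or a `true_population` (its complete
#'   genotypes are used).
#' @param rate Missing probability in `[0, 1)`.
#' @param seed Integer seed for the Bernoulli draws.
#' @return A `genotype_matrix` with calls knocked out.
#' @export
inject_missingness <- function(g, rate, seed) {
  if (inherits(g, "true_population")) g <- g$genotypes_complete
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("invalid 'rate': must lie in [0, 1)")
  }
  set.seed(as.integer(seed))
  calls <- g$calls
  if (rate > 0) calls[stats::runif(length(calls)) < rate] <- NA_integer_
  genotype_matrix(calls, chromosome = g$chromosome, position = g$position,
                  animal_ids = g$animal_ids, snp_ids = g$snp_ids)
}

#' Write a simulated population to plain-text files
#'
#' Writes the genotypes as PLINK PED/MAP, the proof records as a
#' tab-delimited trait table (animal_id, birth_year, ebv, reliability) and
#' the ground truth (haplotype effects, true breeding values, diplotypes)
#' as tab-delimited tables for test harnesses.
#'
#' @param pop A `true_population`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, "genotypes.ped"),
             map = file.path(dir, "genotypes.map"),
             traits = file.path(dir, "traits.tsv"),
             effects = file.path(dir, "true_effects.tsv"),
             tbv = file.path(dir, "true_tbv.tsv"),
             diplotypes = file.path(dir, "true_diplotypes.tsv"))
  write_ped_map(pop$genotypes, paths["ped"], paths["map"])
  write_trait_table(pop$proofs, paths["traits"])
  eff <- do.call(rbind, lapply(seq_along(pop$effects), function(b) {
    data.frame(block_id = b,
               allele_index = seq_along(pop$effects[[b]]),
               allele_string = apply(pop$allele_strings[[b]], 1, paste,
                                     collapse = ""),
               frequency = pop$allele_freqs[[b]],
               effect = pop$effects[[b]])
  }))
  utils::write.table(eff, paths["effects"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(animal_id = pop$proofs$animal_id, tbv = pop$tbv),
    paths["tbv"], sep = "\t", quote = FALSE, row.names = FALSE)
  dip <- data.frame(
    animal_id = rep(pop$proofs$animal_id, times = ncol(pop$d1)),
    block_id = rep(seq_len(ncol(pop$d1)), each = nrow(pop$d1)),
    allele_1 = as.vector(pop$d1), allele_2 = as.vector(pop$d2))
  utils::write.table(dip, paths["diplotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
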