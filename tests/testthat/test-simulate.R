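test_that("config validation names the offending field", {
  expect_error(simulation_config(heritability = 0), "heritability")
  expect_error(simulation_config(genetic_variance = -1), "genetic_variance")
  expect_error(simulation_config(block_size_range = c(1, 4)), "block_size_range")
  expect_error(simulation_config(alleles_per_block = 1), "alleles_per_block")
  expect_error(simulation_config(reliability_range = c(0, 0.9)),
               "reliability_range")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
})

test_that("diplotypes collapse to the complete genotype matrix and tbv is the sum of carried effects", {
  pop <- simulate_population(simulation_config(n_animals = 120, n_blocks = 8,
                                               seed = 3))
  for (b in seq_along(pop$block_snps)) {
    bits <- pop$allele_strings[[b]]
    rebuilt <- bits[pop$d1[, b], , drop = FALSE] +
      bits[pop$d2[, b], , drop = FALSE]
    expect_identical(unname(pop$genotypes_complete$calls[, pop$block_snps[[b]]]),
                     rebuilt)
  }
  tbv2 <- rowSums(vapply(seq_along(pop$effects), function(b)
    pop$effects[[b]][pop$d1[, b]] + pop$effects[[b]][pop$d2[, b]],
    numeric(nrow(pop$d1))))
  expect_equal(pop$tbv, tbv2)
})

test_that("zero missing rate leaves no missing codes and seeded runs are bit-identical", {
  cfg <- simulation_config(n_animals = 80, n_blocks = 5, missing_rate = 0,
                           seed = 9)
  pop <- simulate_population(cfg)
  expect_false(anyNA(pop$genotypes$calls))
  pop2 <- simulate_population(cfg)
  expect_identical(pop$genotypes$calls, pop2$genotypes$calls)
  expect_identical(pop$tbv, pop2$tbv)
  expect_identical(pop$proofs, pop2$proofs)
})

test_that("a huge Dirichlet concentration with two alleles pushes SNP frequencies toward 0.5", {
  cfg <- simulation_config(n_animals = 400, n_blocks = 10,
                           alleles_per_block = 2,
                           allele_freq_concentration = 1e6,
                           missing_rate = 0, seed = 5)
  pop <- simulate_population(cfg)
  # only SNPs that differ between the two haplotype strings segregate;
  # those have allele frequency ~0.5
  maf <- compute_maf(pop$genotypes)
  seg <- maf > 0
  expect_true(any(seg))
  expect_true(all(abs(maf[seg] - 0.5) < 0.12))
})

test_that("tbv is centred and its variance is calibrated to the genetic variance", {
  cfg <- simulation_config(n_animals = 200, n_blocks = 50, seed = 17)
  pop <- simulate_population(cfg)
  se <- stats::sd(pop$tbv) / sqrt(length(pop$tbv))
  expect_lt(abs(mean(pop$tbv)), 3 * se)
  expect_lt(abs(stats::var(pop$tbv) - cfg$genetic_variance),
            0.2 * cfg$genetic_variance)
  # analytic oracle: variance of the sum of two independent allele draws
  # given the drawn frequencies and effects
  v_analytic <- 2 * sum(vapply(seq_along(pop$effects), function(b) {
    f <- pop$allele_freqs[[b]]
    e <- pop$effects[[b]]
    sum(f * e^2) - sum(f * e)^2
  }, numeric(1)))
  expect_equal(v_analytic, cfg$genetic_variance, tolerance = 1e-10)
})

test_that("ebv noise about tbv follows the prediction-error-variance relation", {
  rel <- 0.6
  cfg <- simulation_config(n_animals = 2000, n_blocks = 20,
                           reliability_range = c(rel, rel), seed = 21)
  pop <- simulate_population(cfg)
  v_obs <- stats::var(pop$proofs$ebv - pop$tbv)
  v_exp <- cfg$genetic_variance * (1 - rel) / rel
  expect_lt(abs(v_obs - v_exp), 0.2 * v_exp)
})

test_that("missingness injection is a no-op at rate 0 and binomial at rate 0.5", {
  pop <- simulate_population(simulation_config(n_animals = 100, n_blocks = 10,
                                               missing_rate = 0, seed = 2))
  g0 <- inject_missingness(pop, 0, seed = 1)
  expect_identical(g0$calls, pop$genotypes_complete$calls)
  # ~10,000 calls at rate 0.5: 3-sigma band
  n_calls <- length(pop$genotypes_complete$calls)
  expect_gte(n_calls, 2000)
  g5 <- inject_missingness(pop, 0.5, seed = 1)
  frac <- mean(is.na(g5$calls))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_calls))
  expect_error(inject_missingness(pop, 1, seed = 1), "rate")
})

test_that("population files round-trip as plain text", {
  pop <- simulate_population(simulation_config(n_animals = 30, n_blocks = 4,
                                               seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_population(pop, dir)
  expect_true(all(file.exists(paths)))
  g <- read_ped_map(paths["ped"], paths["map"])
  expect_identical(g$calls, pop$genotypes$calls)
  tr <- read_trait_table(paths["traits"])
  expect_equal(tr$ebv, pop$proofs$ebv, tolerance = 1e-10)
})
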