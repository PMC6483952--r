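test_that("phase is certain for animals with at most one heterozygous site", {
  calls <- rbind(c(0L, 2L, 0L),    # fully homozygous
                 c(0L, 1L, 0L),    # one het: unordered pair still unique
                 c(2L, 2L, 2L))
  res <- em_phase_block(calls)
  for (an in 1:3) {
    p <- res$posteriors[res$posteriors$animal == an, ]
    expect_equal(nrow(p), 1)
    expect_equal(p$probability, 1)
  }
  hom <- res$posteriors[res$posteriors$animal == 1, ]
  expect_equal(hom$a, hom$b)
  a1 <- res$alleles$allele_string[hom$a]
  expect_equal(a1, "010")
})

test_that("posteriors sum to one and every pair reproduces the observed genotype", {
  set.seed(14)
  pool <- rbind(c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  d1 <- sample(1:3, 60, TRUE, prob = c(.5, .3, .2))
  d2 <- sample(1:3, 60, TRUE, prob = c(.5, .3, .2))
  calls <- pool[d1, ] + pool[d2, ]
  calls[sample(length(calls), 20)] <- NA            # some missing calls
  res <- em_phase_block(calls)
  sums <- tapply(res$posteriors$probability, res$posteriors$animal, sum)
  expect_true(all(abs(sums - 1) < 1e-10))
  strings <- res$alleles$allele_string
  split_bits <- function(s) as.integer(strsplit(s, "")[[1]])
  for (r in sample(nrow(res$posteriors), 50)) {
    row <- res$posteriors[r, ]
    geno <- split_bits(strings[row$a]) + split_bits(strings[row$b])
    obs <- calls[row$animal, ]
    expect_true(all(geno[!is.na(obs)] == obs[!is.na(obs)]))
  }
})

test_that("EM log-likelihood is non-decreasing and converges in one sweep on unambiguous data", {
  set.seed(15)
  pool <- rbind(c(0L, 0L), c(1L, 1L))
  d1 <- sample(1:2, 40, TRUE)
  calls <- pool[d1, ] + pool[d1, ]                  # all homozygous
  res <- em_phase_block(calls)
  expect_true(all(diff(res$loglik) >= -1e-8))
  counting <- table(factor(res$alleles$allele_string[
    c(res$posteriors$a, res$posteriors$b)], levels = res$alleles$allele_string))
  expect_equal(unname(res$alleles$population_frequency),
               as.vector(counting / sum(counting)), tolerance = 1e-12)
})

test_that("EM recovers the generating frequencies within 3 binomial SE", {
  set.seed(16)
  n <- 200
  pool <- rbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  f_true <- c(0.5, 0.3, 0.2)
  d1 <- sample(1:3, n, TRUE, prob = f_true)
  d2 <- sample(1:3, n, TRUE, prob = f_true)
  calls <- pool[d1, ] + pool[d2, ]
  res <- em_phase_block(calls, max_iter = 2000, tol = 1e-12)
  strings <- apply(pool, 1, paste, collapse = "")
  f_hat <- res$alleles$population_frequency[
    match(strings, res$alleles$allele_string)]
  se <- sqrt(f_true * (1 - f_true) / (2 * n))
  expect_true(all(abs(f_hat - f_true) < 3 * se))
  expect_true(all(diff(res$loglik) >= -1e-8))
})

test_that("phasing refuses oversized blocks and degenerate input", {
  expect_error(em_phase_block(matrix(0L, 3, 25), enum_cap = 2^20),
               "exceeds cap")
  expect_error(em_phase_block(matrix(NA_integer_, 3, 3)), "non-missing")
  expect_error(em_phase_block(matrix(0L, 3, 1)), "at least 2 SNPs")
})

test_that("an all-missing animal receives the Hardy-Weinberg prior", {
  calls <- rbind(c(2L, 2L), c(0L, 0L), c(2L, 2L), c(NA, NA))
  res <- em_phase_block(calls)
  p4 <- res$posteriors[res$posteriors$animal == 4, ]
  f <- res$alleles$population_frequency
  expect_equal(sum(p4$probability), 1, tolerance = 1e-12)
  hom <- p4[p4$a == p4$b, ]
  expect_equal(sort(hom$probability), sort(f^2), tolerance = 1e-9)
})

test_that("carrier frequency counts probable carriers", {
  post <- data.frame(animal = 1:100,
                     a = c(rep(1L, 30), rep(2L, 70)),
                     b = c(rep(2L, 30), rep(2L, 70)),
                     probability = 1)
  expect_equal(carrier_frequency(post, 1L), 0.30)
  expect_equal(carrier_frequency(post, 3L), 0)
})

test_that("carrier frequency under Hardy-Weinberg approaches 2p - p^2", {
  set.seed(18)
  n <- 2000
  p <- 0.25
  d1 <- sample(1:2, n, TRUE, prob = c(p, 1 - p))
  d2 <- sample(1:2, n, TRUE, prob = c(p, 1 - p))
  post <- data.frame(animal = seq_len(n), a = pmin(d1, d2), b = pmax(d1, d2),
                     probability = 1)
  expected <- 2 * p - p^2
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(carrier_frequency(post, 1L) - expected), 3 * se)
})

test_that("haplotype selection uses a strict threshold and a deterministic order", {
  haps <- data.frame(block_id = c(1, 1, 1, 2, 2),
                     allele_index = c(1, 2, 3, 1, 2),
                     allele_string = c("00", "11", "01", "10", "01"),
                     population_frequency = c(.5, .3, .2, .25, .75),
                     carrier_frequency = c(.6, .3, .1, .25, .8))
  sel <- select_frequent_haplotypes(haps, 0.25)
  expect_equal(nrow(sel), 3)
  expect_equal(sel$carrier_frequency, c(.6, .3, .8))  # block order, desc freq
  # exactly-at-threshold alleles are excluded (strict >)
  expect_false(any(sel$carrier_frequency == 0.25))
  # threshold 0: everything with positive frequency kept
  expect_equal(nrow(select_frequent_haplotypes(haps, 0)), 5)
  # population basis switch
  sel_pop <- select_frequent_haplotypes(haps, 0.25, basis = "population")
  expect_equal(sel_pop$population_frequency, c(.5, .3, .75))
})

test_that("selected alleles per block stay within the sanity bound", {
  pop <- simulate_population(simulation_config(n_animals = 250, n_blocks = 12,
                                               seed = 19))
  phased <- phase_blocks(pop$genotypes, pop$block_snps)
  sel <- select_frequent_haplotypes(phased$haplotypes)
  per_block <- table(sel$block_id)
  expect_true(all(per_block <= 7))
})
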