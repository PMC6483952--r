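# random small MME instance for oracle comparisons
random_instance <- function(n_max = 30, H_max = 10) {
  n <- sample(5:n_max, 1)
  H <- sample(2:min(H_max, n - 2), 1)
  Z <- matrix(round(runif(n * H), 2), n, H,
              dimnames = list(sprintf("A%02d", 1:n), sprintf("h%02d", 1:H)))
  list(n = n, H = H, Z = Z, y = rnorm(n),
       s2h = runif(H, 0.1, 5), s2e = runif(1, 0.5, 2))
}

# independent oracle: assemble the full mixed model equations with
# explicit loops over [1 Z] and solve by plain dense inversion
mme_dense_oracle <- function(y, Z, s2h, s2e, w = rep(1, length(y))) {
  W <- cbind(1, Z)
  q <- ncol(W)
  C <- matrix(0, q, q)
  rhs <- numeric(q)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) C[i, j] <- sum(W[, i] * W[, j] * w / s2e)
    rhs[i] <- sum(W[, i] * y * w / s2e)
  }
  diag(C)[-1] <- diag(C)[-1] + 1 / s2h
  drop(solve(C) %*% rhs)
}

test_that("model variants map to their design kind and variance scheme", {
  expect_equal(model_variant(1)[c("z_kind", "variance_scheme")],
               list(z_kind = "probability", variance_scheme = "equal"))
  expect_equal(model_variant(2)$z_kind, "indicator")
  expect_equal(model_variant(3)$variance_scheme, "size_weighted")
  expect_equal(model_variant(4)[c("z_kind", "variance_scheme")],
               list(z_kind = "indicator", variance_scheme = "size_weighted"))
  expect_error(model_variant(5), "variant")
})

test_that("design matrix entries follow the diplotype posterior", {
  selected <- data.frame(block_id = 1L, allele_index = 1L,
                         allele_string = "01", population_frequency = 0.4,
                         block_size = 2L)
  post <- data.frame(animal_id = c("a1", "a2", "a3", "a3"),
                     block_id = 1L,
                     a = c(1L, 1L, 1L, 2L), b = c(1L, 2L, 2L, 2L),
                     probability = c(1, 1, 0.6, 0.4))
  ids <- c("a1", "a2", "a3")
  Zp <- build_design_matrix(post, selected, ids, "probability")
  # homozygous carrier: 1; certain heterozygote: 0.5;
  # posterior 0.6 on (1,2) and 0.4 on (2,2): (0.6 * 1) / 2 = 0.3
  expect_equal(unname(Zp[, 1]), c(1, 0.5, 0.3))
  Zi <- build_design_matrix(post, selected, ids, "indicator")
  expect_equal(unname(Zi[, 1]), c(1, 1, 1))  # modal pair of a3 is (1,2)
  expect_true(all(Zp >= 0 & Zp <= 1))
  expect_true(all(Zi %in% c(0, 1)))
  # expected-dosage scale doubles the probability entries
  Zd <- build_design_matrix(post, selected, ids, "probability",
                            scale = "dosage")
  expect_equal(unname(Zd[, 1]), c(2, 1, 0.6))
})

test_that("animals without a posterior fall back to the population prior", {
  selected <- data.frame(block_id = 1L, allele_index = 1L,
                         allele_string = "01", population_frequency = 0.6,
                         block_size = 2L)
  post <- data.frame(animal_id = "a1", block_id = 1L, a = 1L, b = 1L,
                     probability = 1)
  ids <- c("a1", "a2")
  expect_warning(Zp <- build_design_matrix(post, selected, ids, "probability"),
                 "population prior")
  expect_equal(unname(Zp["a2", 1]), 0.6)   # transmission prob = frequency
  expect_warning(Zi <- build_design_matrix(post, selected, ids, "indicator"),
                 "prior modal")
  expect_equal(unname(Zi["a2", 1]), 1)     # modal HW pair at f=0.6 carries it
})

test_that("variance partitions match the stated arithmetic and sum exactly", {
  sel4 <- data.frame(block_id = 1:4, allele_index = 1L,
                     allele_string = c("00", "01", "10", "11"),
                     block_size = c(2L, 2L, 2L, 2L))
  v <- partition_variance(sel4, 213490, "equal")
  expect_equal(unname(v), rep(53372.5, 4))
  sel2 <- data.frame(block_id = 1:2, allele_index = 1L,
                     allele_string = c("0", "1"), block_size = c(6L, 2L))
  expect_equal(unname(partition_variance(sel2, 8, "size_weighted")), c(6, 2))
  # equal sizes collapse the two schemes
  sel_eq <- data.frame(block_id = 1:2, allele_index = 1L,
                       allele_string = c("0", "1"), block_size = c(2L, 2L))
  expect_equal(partition_variance(sel_eq, 10, "size_weighted"),
               partition_variance(sel_eq, 10, "equal"))
  # exact conservation under fuzz
  set.seed(31)
  for (k in 1:50) {
    H <- sample(1:40, 1)
    sel <- data.frame(block_id = seq_len(H), allele_index = 1L,
                      allele_string = as.character(seq_len(H)),
                      block_size = sample(2:12, H, TRUE))
    s2g <- runif(1, 1e-4, 1e6)
    for (scheme in c("equal", "size_weighted")) {
      v <- partition_variance(sel, s2g, scheme)
      expect_identical(sum(v), s2g)
    }
  }
  expect_error(partition_variance(sel4[0, ], 1, "equal"), "no selected")
})

test_that("the solver matches dense inversion on random instances", {
  set.seed(33)
  for (k in 1:25) {
    inst <- random_instance()
    fit <- solve_model(inst$y, inst$Z, inst$s2h, inst$s2e)
    oracle <- mme_dense_oracle(inst$y, inst$Z, inst$s2h, inst$s2e)
    got <- c(fit$mu_hat, fit$effects)
    expect_lt(max(abs(got - oracle)) / max(1, max(abs(oracle))), 1e-8)
  }
})

test_that("the solver honours residual weights", {
  set.seed(34)
  inst <- random_instance()
  w <- runif(inst$n, 0.3, 3)
  fit <- solve_model(inst$y, inst$Z, inst$s2h, inst$s2e, weights = w)
  oracle <- mme_dense_oracle(inst$y, inst$Z, inst$s2h, inst$s2e, w)
  expect_equal(unname(c(fit$mu_hat, fit$effects)), oracle, tolerance = 1e-8)
})

test_that("solutions equal the generalized-ridge closed form with the mean absorbed", {
  set.seed(35)
  for (k in 1:10) {
    inst <- random_instance()
    fit <- solve_model(inst$y, inst$Z, inst$s2h, inst$s2e)
    M <- diag(inst$n) - matrix(1 / inst$n, inst$n, inst$n)
    D <- diag(inst$s2e / inst$s2h, inst$H)
    h <- drop(solve(crossprod(inst$Z, M %*% inst$Z) + D,
                    crossprod(inst$Z, M %*% inst$y)))
    expect_equal(unname(fit$effects), unname(h), tolerance = 1e-8)
    expect_equal(fit$mu_hat, mean(inst$y - drop(inst$Z %*% h)),
                 tolerance = 1e-8)
  }
})

test_that("the ridge limits recover OLS and complete shrinkage", {
  set.seed(36)
  inst <- random_instance()
  # sigma2_h huge: BLUP tends to ordinary least squares
  fit_ols <- solve_model(inst$y, inst$Z, rep(1e8 * inst$s2e, inst$H),
                         inst$s2e)
  ls <- unname(stats::coef(stats::lm(inst$y ~ inst$Z)))
  expect_lt(max(abs(c(fit_ols$mu_hat, fit_ols$effects) - ls)), 1e-6 * max(1, max(abs(ls))))
  # sigma2_h tiny: effects vanish, mu tends to mean(y)
  fit_null <- solve_model(inst$y, inst$Z, rep(1e-8 * inst$s2e, inst$H),
                          inst$s2e)
  expect_lt(max(abs(fit_null$effects)), 1e-6)
  expect_equal(fit_null$mu_hat, mean(inst$y), tolerance = 1e-6)
})

test_that("each effect shrinks monotonically as its own variance decreases", {
  set.seed(37)
  inst <- random_instance()
  j <- sample(inst$H, 1)
  grid <- 10^seq(2, -4, by = -0.5)
  mag <- vapply(grid, function(v) {
    s2h <- inst$s2h
    s2h[j] <- v
    abs(solve_model(inst$y, inst$Z, s2h, inst$s2e)$effects[j])
  }, numeric(1))
  expect_true(all(diff(mag) <= 1e-12))
})

test_that("an all-zero design column triggers the minimum-norm path only when singular", {
  set.seed(38)
  inst <- random_instance()
  Z <- inst$Z
  Z[, 2] <- 0
  # finite variances keep the MME nonsingular; the zero column's BLUP is 0
  fit <- solve_model(inst$y, Z, inst$s2h, inst$s2e)
  expect_equal(unname(fit$effects[2]), 0, tolerance = 1e-12)
})

test_that("dgv is the design-weighted sum of effects, excluding the mean", {
  set.seed(39)
  Z <- matrix(runif(12), 4, 3, dimnames = list(paste0("a", 1:4),
                                               paste0("h", 1:3)))
  fit <- structure(list(mu_hat = 99, effects = setNames(rnorm(3),
                                                        colnames(Z))),
                   class = "haplotype_fit")
  dgv <- predict_dgv(Z, fit)
  # summation-loop oracle
  manual <- vapply(1:4, function(i) sum(Z[i, ] * fit$effects), numeric(1))
  expect_equal(dgv$dgv, manual)
  # null effects -> null dgv
  fit0 <- structure(list(mu_hat = 1, effects = setNames(rep(0, 3),
                                                        colnames(Z))),
                    class = "haplotype_fit")
  expect_equal(predict_dgv(Z, fit0)$dgv, rep(0, 4))
  # one-hot rows select single effects
  Z1 <- diag(3)
  dimnames(Z1) <- list(paste0("b", 1:3), colnames(Z))
  expect_equal(predict_dgv(Z1, fit)$dgv, unname(fit$effects))
  # column mismatch rejected
  Zbad <- Z
  colnames(Zbad) <- c("h1", "h2", "x")
  expect_error(predict_dgv(Zbad, fit), "do not match")
})

test_that("haplotype effects are recovered better from larger training sets", {
  corr_at <- function(n, seed) {
    cfg <- simulation_config(n_animals = n, n_blocks = 15, missing_rate = 0,
                             seed = seed)
    pop <- simulate_population(cfg)
    phased <- true_phase_set(pop)
    sel <- select_frequent_haplotypes(phased$haplotypes, 0.25)
    Z <- build_design_matrix(phased$posteriors, sel, pop$proofs$animal_id,
                             "probability")
    s2h <- partition_variance(sel, cfg$genetic_variance, "equal")
    tr <- trait_spec("sim", cfg$heritability, cfg$genetic_variance)
    proofs <- deregress(pop$proofs)
    fit <- solve_model(proofs$drp, Z, s2h, tr$error_variance)
    truth <- vapply(seq_len(nrow(sel)), function(k)
      pop$effects[[sel$block_id[k]]][sel$allele_index[k]], numeric(1))
    cor(fit$effects, truth)
  }
  wins <- 0
  for (s in 1:10) {
    c_small <- corr_at(100, 700 + s)
    c_large <- corr_at(1000, 700 + s)
    expect_gt(c_large, 0)
    wins <- wins + (c_large > c_small)
  }
  expect_gte(wins, 6)
})

test_that("probability and indicator designs coincide for certain homozygous carriers", {
  selected <- data.frame(block_id = 1L, allele_index = 1:2,
                         allele_string = c("00", "11"),
                         population_frequency = c(0.5, 0.5),
                         block_size = 2L)
  post <- data.frame(animal_id = c("a1", "a2"), block_id = 1L,
                     a = c(1L, 2L), b = c(1L, 2L), probability = 1)
  Zp <- build_design_matrix(post, selected, c("a1", "a2"), "probability")
  Zi <- build_design_matrix(post, selected, c("a1", "a2"), "indicator")
  expect_equal(Zp, Zi, ignore_attr = TRUE)
})
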