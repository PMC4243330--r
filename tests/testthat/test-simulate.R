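test_that("genotype simulation follows Hardy-Weinberg class frequencies", {
  # fixed q = 0.2: class-3 (dosage 2) probability is q^2 = 0.04
  G <- simulate_genotypes(50000, 1, maf_low = 0.2, maf_high = 0.2, seed = 42)
  p3 <- mean(G$values[, 1] == 2L)
  se <- sqrt(0.04 * 0.96 / 50000)
  expect_lt(abs(p3 - 0.04), 3 * se)
  p2 <- mean(G$values[, 1] == 1L)
  expect_lt(abs(p2 - 2 * 0.2 * 0.8), 3 * sqrt(0.32 * 0.68 / 50000))
  # degenerate q = 0.5: class frequencies (0.25, 0.5, 0.25)
  G5 <- simulate_genotypes(50000, 1, maf_low = 0.499999, maf_high = 0.499999,
                           seed = 1)
  expect_lt(abs(mean(G5$values == 1L) - 0.5), 0.01)
})

test_that("genotype simulation is deterministic and bounds MAF", {
  G1 <- simulate_genotypes(100, 50, seed = 9)
  G2 <- simulate_genotypes(100, 50, seed = 9)
  expect_identical(G1$values, G2$values)
  expect_identical(G1$coding_origin, "simulated123")
  # empirical MAF within 4 SE of the configured range
  emp <- apply(G1$values, 2, maf)
  se <- sqrt(0.4 * 0.6 / (2 * 100))
  expect_true(all(emp > 0.10 - 4 * se & emp < 0.40 + 4 * se))
})

test_that("additive phenotype matches its indicator model exactly at sd 0", {
  spec <- sim_spec_additive(n_subjects = 200, n_snps = 80, seed = 5,
                            error_sd = 0)
  G <- simulate_genotypes(200, 80, seed = 5)
  y <- simulate_phenotype_additive(G, spec)
  classes <- G$values + 1L
  # subject-level oracle straight from the architecture definition
  expected <- 200 * (classes[, 1] == 2) + 200 * (classes[, 10] == 1) +
    200 * (classes[, 20] == 3) + 900 * (classes[, 30] == 3) +
    200 * (classes[, 40] == 3) + 200 * (classes[, 50] == 2) +
    200 * (classes[, 60] == 2)
  expect_equal(unname(y), unname(expected))
  # spot expectations: only the major effect fires -> 900; none fire -> 0
  only4 <- classes[, 30] == 3 & classes[, 1] != 2 & classes[, 10] != 1 &
    classes[, 20] != 3 & classes[, 40] != 3 & classes[, 50] != 2 &
    classes[, 60] != 2
  if (any(only4)) expect_true(all(y[only4] == 900))
  none <- expected == 0
  expect_true(any(none) && all(y[none] == 0))
})

test_that("epistatic phenotype applies conjunction and negation semantics", {
  spec <- sim_spec_epistatic(n_subjects = 400, n_snps = 30, seed = 8,
                             error_sd = 0)
  G <- simulate_genotypes(400, 30, seed = 8)
  y <- simulate_phenotype_epistatic(G, spec)
  cl <- G$values + 1L
  L1 <- (cl[, 4] != 3) & (cl[, 3] == 2)
  L2 <- cl[, 5] == 3
  L3 <- (cl[, 12] != 1) & (cl[, 9] == 3)
  expect_equal(unname(y), unname(150 * L1 + 150 * L2 + 40 * L3))
  # the three worked cases: L2 alone -> 150; L1 and L3 -> 190; none -> 0
  c150 <- L2 & !L1 & !L3
  c190 <- L1 & L3 & !L2
  c0 <- !L1 & !L2 & !L3
  expect_true(any(c150) && all(y[c150] == 150))
  if (any(c190)) expect_true(all(y[c190] == 190))
  expect_true(any(c0) && all(y[c0] == 0))
})

test_that("indicator terms validate SNP indices", {
  spec <- sim_spec_additive(n_subjects = 20, n_snps = 10, seed = 1)
  G <- simulate_genotypes(20, 10, seed = 1)
  expect_error(simulate_phenotype_additive(G, spec), "outside")
})

test_that("phenotype simulation is deterministic given seeds, genotypes reusable", {
  spec <- sim_spec_additive(n_subjects = 100, n_snps = 70, seed = 3)
  G <- simulate_genotypes(100, 70, seed = 3)
  y1 <- simulate_phenotype_additive(G, spec)
  y2 <- simulate_phenotype_additive(G, spec)
  expect_identical(y1, y2)
  y3 <- simulate_phenotype_additive(G, spec, error_seed = 99)
  expect_false(identical(y1, y3))   # new noise draw, same genotypes
})

test_that("true-indicator regression explains almost all additive variance", {
  spec <- sim_spec_additive(seed = 21)
  st <- simulate_study(spec)
  cl <- st$genotypes$values + 1L
  L <- 1 * cbind((cl[, 1] == 2), (cl[, 10] == 1), (cl[, 20] == 3),
                 (cl[, 30] == 3), (cl[, 40] == 3), (cl[, 50] == 2),
                 (cl[, 60] == 2))
  fit <- lm(st$phenotype ~ L)
  expect_gt(summary(fit)$r.squared, 0.99)
})
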