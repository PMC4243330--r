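test_that("spearman rho matches hand and brute-force oracles", {
  G <- genotype_matrix(matrix(c(1L, 2L, 2L, 0L, 1L, 2L), ncol = 2))
  y <- c(3, 1, 2)
  s <- spearman_stats(impute_missing_as_het(G)$genotypes, y)
  # hand case x = (1,2,3)-like ranks vs y = (3,1,2)
  expect_equal(spearman_oracle(c(1, 2, 3), y), -0.5)
  # column 2 is strictly increasing with ranks of (0,1,2)
  expect_equal(s$rho[2], spearman_oracle(c(0, 1, 2), y), tolerance = 1e-12)
})

test_that("spearman agrees with rank-Pearson oracle and cor.test, ties included", {
  set.seed(31)
  n <- 40
  G <- simulate_genotypes(n, 25, seed = 31)
  y <- rnorm(n) + G$values[, 1]          # some signal, plenty of dosage ties
  y[3] <- y[5]                           # tie in the phenotype too
  s <- spearman_stats(G, y)
  for (j in seq_len(25)) {
    expect_equal(s$rho[j], spearman_oracle(G$values[, j], y),
                 tolerance = 1e-12)
    ct <- suppressWarnings(
      cor.test(G$values[, j], y, method = "spearman", exact = FALSE))
    expect_equal(s$rho[j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(s$p_raw[j], ct$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate columns and identity cases behave as documented", {
  n <- 30
  vals <- cbind(rep(1L, n), rep(c(0L, 1L, 2L), 10))
  G <- genotype_matrix(vals)
  y <- as.numeric(vals[, 2]) + seq_len(n) * 1e-9  # strictly monotone in col 2
  s <- spearman_stats(G, y)
  expect_equal(s$rho[1], 0)   # constant column: rho defined as 0
  expect_equal(s$p_raw[1], 1)
  expect_equal(s$rho[2], spearman_oracle(vals[, 2], y), tolerance = 1e-12)
  # a column against itself as pseudo-phenotype
  s2 <- spearman_stats(G, as.numeric(vals[, 2]))
  expect_equal(s2$rho[2], 1)
  expect_error(spearman_stats(G, rep(2, n)), "constant phenotype")
})

test_that("Bonferroni adjustment multiplies and caps at one", {
  # worked rows of the additive-design reference table (m = 1000 markers)
  expect_equal(bonferroni_adjust(1.658460e-13, 1000), 1.658460e-10)
  expect_equal(bonferroni_adjust(5.737988e-10, 1000), 5.737988e-07)
  expect_equal(bonferroni_adjust(5.366227e-01, 1000), 1.0)
  expect_equal(bonferroni_adjust(3.520811e-04, 1000), 3.520811e-01)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
  # agrees with p.adjust on whole vectors
  p <- c(1e-6, 0.01, 0.4, 0.9)
  expect_equal(vapply(p, bonferroni_adjust, numeric(1), m = length(p)),
               p.adjust(p, "bonferroni"))
})

test_that("group ladders are strict, nested and sized as expected", {
  expect_length(ladder_real(), 8)
  expect_length(ladder_simulated(), 17)
  stats <- data.frame(snp_id = c("a", "b", "c"),
                      p_raw = c(1e-10, 5e-9, 2e-3),
                      p_adj = pmin(1, c(1e-10, 5e-9, 2e-3) * 3))
  g <- build_groups(stats, thresholds = c(1e-9, 1e-2))
  expect_identical(g$sizes, c(1L, 3L))
  expect_identical(g$members[[1]], "a")
  # strict inequality at the boundary
  gb <- build_groups(data.frame(snp_id = "x", p_raw = 1e-2, p_adj = 1e-2),
                     thresholds = c(1e-2, 1e-1))
  expect_identical(gb$sizes, c(0L, 1L))
  # all p = 1: every group empty
  ge <- build_groups(data.frame(snp_id = letters[1:4], p_raw = rep(1, 4),
                                p_adj = rep(1, 4)),
                     thresholds = c(0.1, 0.5))
  expect_identical(ge$sizes, c(0L, 0L))
})

test_that("nestedness and adjusted-subset properties hold on random p-vectors", {
  set.seed(77)
  for (i in 1:20) {
    m <- 50
    p <- runif(m)^3
    stats <- data.frame(snp_id = paste0("s", 1:m), p_raw = p,
                        p_adj = pmin(1, m * p))
    th <- sort(runif(5))
    g_raw <- build_groups(stats, th, use_adjusted = FALSE)
    g_adj <- build_groups(stats, th, use_adjusted = TRUE)
    for (k in seq_len(4)) {
      expect_true(all(g_raw$members[[k]] %in% g_raw$members[[k + 1]]))
    }
    # p_adj >= p_raw, so adjusted groups are subsets of raw groups
    for (k in seq_len(5)) {
      expect_true(all(g_adj$members[[k]] %in% g_raw$members[[k]]))
    }
  }
})
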