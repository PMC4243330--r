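test_that("noise-free linear relation is fit inside the epsilon tube", {
  set.seed(20)
  x <- matrix(seq(-2, 2, length.out = 40), ncol = 1)
  y <- 2 * x[, 1] + 1
  m <- fit_svr(x, y, svr_hyper(1e3, 0.01, kernel_spec("linear")))
  expect_lt(max(abs(m$fitted - y)), 0.01 + 1e-6)
  expect_lt(max(abs(predict(m, x) - y)), 0.01 + 1e-6)
})

test_that("constant target gives a constant model with null dual coefficients", {
  set.seed(21)
  x <- matrix(rnorm(30 * 2), ncol = 2)
  y <- rep(3.5, 30)
  m <- fit_svr(x, y, svr_hyper(10, 0.1, kernel_spec("rbf", gamma = 0.5)))
  expect_equal(unname(predict(m, x)), y, tolerance = 0.1 + 1e-6)
  expect_lt(max(abs(m$beta)), 1e-6)
})

test_that("dual solution satisfies the KKT-style model invariants", {
  set.seed(22)
  x <- matrix(rnorm(50 * 3), ncol = 3)
  y <- x[, 1]^2 - x[, 2] + rnorm(50, 0, 0.3)
  C <- 5; eps <- 0.2
  m <- fit_svr(x, y, svr_hyper(C, eps, kernel_spec("puk", omega = 2,
                                                   sigma = 2)),
               tol = 1e-8)
  expect_true(all(m$beta >= -C - 1e-8 & m$beta <= C + 1e-8))
  expect_lt(abs(sum(m$beta)), 1e-6)
  # points strictly inside the tube carry no dual weight
  inside <- abs(m$fitted - y) < eps - 1e-6
  expect_true(all(abs(m$beta[inside]) < 1e-6))
})

test_that("fit_svr agrees with an independent dual QP oracle", {
  set.seed(23)
  for (case in 1:3) {
    n <- 20
    x <- matrix(rnorm(n * 2), ncol = 2)
    y <- sin(x[, 1]) + 0.5 * x[, 2] + rnorm(n, 0, 0.2)
    spec <- switch(case,
                   kernel_spec("linear"),
                   kernel_spec("rbf", gamma = 0.5),
                   kernel_spec("puk", omega = 1, sigma = 2))
    C <- 2; eps <- 0.1
    m <- fit_svr(x, y, svr_hyper(C, eps, spec), standardize = FALSE,
                 tol = 1e-8)
    K <- kernel_matrix(x, x, spec)
    oracle <- svr_qp_oracle(K, y, C, eps)
    expect_lt(max(abs(m$fitted - oracle$fitted)), 1e-4)
  }
})

test_that("repeated CV pools out-of-fold predictions once per repeat", {
  set.seed(24)
  n <- 60
  x <- matrix(rnorm(n * 2), ncol = 2)
  y <- x[, 1] + rnorm(n, 0, 0.05)
  hy <- svr_hyper(10, 0.05, kernel_spec("linear"))
  cv <- repeated_cv_correlation(x, y, hy, k = 5, r = 4, seed = 7)
  expect_length(cv$values, 4)
  expect_equal(cv$mean, mean(cv$values))
  expect_equal(cv$sd, sd(cv$values))
  expect_true(all(cv$values >= -1 & cv$values <= 1))
  # strong signal: near-perfect correlation
  expect_gt(cv$mean, 0.99)
  # determinism
  cv2 <- repeated_cv_correlation(x, y, hy, k = 5, r = 4, seed = 7)
  expect_identical(cv$values, cv2$values)
  # per-fold mode returns k correlations per repeat
  cv3 <- repeated_cv_correlation(x, y, hy, k = 5, r = 2, seed = 7,
                                 per_fold = TRUE)
  expect_length(cv3$per_fold, 2)
  expect_length(cv3$per_fold[[1]], 5)
})

test_that("null predictors give near-zero mean CV correlation", {
  set.seed(25)
  G <- simulate_genotypes(250, 10, seed = 25)
  y <- rnorm(250)                      # independent of every SNP
  hy <- svr_hyper(1, 0.1 * sd(y), kernel_spec("rbf", gamma = 0.1))
  cv <- repeated_cv_correlation(G$values, y, hy, k = 10, r = 10, seed = 5)
  expect_lt(abs(cv$mean), 0.15)
})

test_that("grid search returns the best point with documented tie-breaking", {
  set.seed(26)
  x <- matrix(rnorm(50), ncol = 1)
  y <- 3 * x[, 1] + rnorm(50, 0, 0.1)
  grids <- list(C = c(0.001, 10), epsilon_frac = c(0.05), gamma = 1)
  gs <- grid_search(x, y, "linear", grids = grids, k = 5, r = 2, seed = 2)
  expect_equal(gs$best$C, 10)          # C = 0.001 underfits badly
  expect_identical(nrow(gs$table), 2L)
  # single-point grid returns that point
  gs1 <- grid_search(x, y, "rbf",
                     grids = list(C = 1, epsilon_frac = 0.1, gamma = 0.5),
                     k = 5, r = 2, seed = 2)
  expect_equal(gs1$best$C, 1)
  expect_equal(gs1$best$kernel$gamma, 0.5)
})

test_that("best-group choice prefers parsimony within the tie tolerance", {
  mk_groups <- function(sizes) {
    structure(list(thresholds = seq_along(sizes),
                   use_adjusted = FALSE,
                   members = lapply(sizes, function(s)
                     if (s == 0) character(0) else paste0("s", seq_len(s))),
                   sizes = as.integer(sizes)),
              class = "group_series")
  }
  mk_cv <- function(mean, sd = 0.1) {
    structure(list(mean = mean, sd = sd), class = "cv_result")
  }
  g <- mk_groups(c(2, 4, 40))
  ev <- list(mk_cv(0.5), mk_cv(0.7), mk_cv(0.7))
  expect_identical(select_best_group(g, ev, tie_tolerance = 0)$index, 2L)
  # within tolerance 0.01 the smaller group wins
  g2 <- mk_groups(c(10, 3))
  ev2 <- list(mk_cv(0.700), mk_cv(0.695))
  expect_identical(select_best_group(g2, ev2, tie_tolerance = 0.01)$index, 2L)
  expect_identical(select_best_group(g2, ev2, tie_tolerance = 0)$index, 1L)
  # single group: itself; all empty: error
  g3 <- mk_groups(1)
  expect_identical(select_best_group(g3, list(mk_cv(0.2)))$index, 1L)
  g4 <- mk_groups(c(0, 0))
  expect_error(select_best_group(g4, list(NULL, NULL)), "no evaluated")
})

test_that("tuned PUK beats tuned linear on the additive causal design", {
  spec <- sim_spec_additive(seed = 41)
  st <- simulate_study(spec)
  X <- st$genotypes$values[, causal_snp_indices(spec)]
  cv_puk <- tuned_cv(X, st$phenotype, "puk", seed = 6)
  cv_lin <- tuned_cv(X, st$phenotype, "linear", seed = 6)
  expect_gte(cv_puk$mean, cv_lin$mean)
  expect_gt(cv_puk$mean, 0.9)
})
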