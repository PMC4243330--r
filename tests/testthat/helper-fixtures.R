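# Small in-code fixtures shared across tests.

toy_genotypes <- function() {
  vals <- rbind(c(0L, 1L, 2L, NA, 0L),
                c(1L, 0L, 0L, 2L, 0L),
                c(2L, NA, 1L, 1L, 0L),
                c(0L, 1L, 2L, 0L, 0L))
  genotype_matrix(vals,
                  snp_ids = paste0("rs", 1:5),
                  sample_ids = paste0("ind", 1:4))
}

# brute-force Spearman oracle: explicit mean ranks, then the plain
# product-moment formula
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# independent dual QP oracle for epsilon-SVR: the textbook 2n-variable dual
# (z = (alpha, alpha*), box [0, C], equality sum(alpha - alpha*) = 0) is
# written out explicitly and handed to a generic interior-point QP solver --
# a different algorithm and code path from the SMO used by the implementation
svr_qp_oracle <- function(K, y, C, epsilon) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K))
  d <- c(y - epsilon, -y - epsilon)
  A <- matrix(c(rep(1, n), rep(-1, n)), nrow = 1)
  sol <- kernlab::ipop(c = -d, H = H, A = A, b = 0, l = rep(0, 2 * n),
                       u = rep(C, 2 * n), r = 0, sigf = 10, maxiter = 200)
  z <- kernlab::primal(sol)
  beta <- z[1:n] - z[(n + 1):(2 * n)]
  f0 <- drop(K %*% beta)
  # intercept from KKT points strictly inside the box
  i_free <- which(abs(beta) > 1e-6 & abs(beta) < C - 1e-6)
  b <- if (length(i_free))
    mean(y[i_free] - epsilon * sign(beta[i_free]) - f0[i_free])
  else mean(y - f0)
  list(beta = beta, b = b, fitted = f0 + b)
}

# compact grids for tuning inside tests, chosen for runtime; the package
# defaults remain default_grids()
test_grids <- function() {
  list(C = c(10, 100, 1000),
       epsilon_frac = c(0.01, 0.1),
       gamma = c(0.01, 0.1, 1),
       omega = c(0.5, 1, 4, 16),
       sigma = c(1, 4, 8, 16, 32))
}

tuned_cv <- function(X, y, family, k = 10, r = 10, seed = 1L,
                     grids = test_grids(), tune_k = k) {
  gs <- grid_search(X, y, family, grids = grids, k = tune_k, r = 1,
                    seed = seed)
  repeated_cv_correlation(X, y, gs$best, k = k, r = r, seed = seed)
}
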