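#' Kernel specification
#'
#' The three kernel families used to evaluate marker groups:
#' * `linear`: `K(x, z) = <x, z>` (no parameter);
#' * `rbf`: `K(x, z) = exp(-gamma * ||x - z||^2)`;
#' * `puk`: the Pearson VII universal kernel
#'   `K(x, z) = 1 / (1 + (2 * ||x - z|| * sqrt(2^(1/omega) - 1) / sigma)^2)^omega`,
#'   whose shape parameter `omega` moves it between a Lorentzian
#'   (`omega = 1`) and a Gaussian (`omega -> Inf`) peak of half-width
#'   controlled by `sigma`, letting one kernel mimic the usual families.
#'
#' @param family `"linear"`, `"rbf"` or `"puk"`.
#' @param gamma positive RBF width parameter.
#' @param omega,sigma positive PUK shape and width parameters.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "rbf", "puk"),
                        gamma = NULL, omega = NULL, sigma = NULL) {
  family <- match.arg(family)
  if (family == "rbf") {
    if (is.null(gamma) || gamma <= 0) stop("rbf kernel needs gamma > 0")
  } else if (family == "puk") {
    if (is.null(omega) || omega <= 0 || is.null(sigma) || sigma <= 0)
      stop("puk kernel needs omega > 0 and sigma > 0")
  }
  structure(list(family = family, gamma = gamma, omega = omega, sigma = sigma),
            class = "kernel_spec")
}

sq_distances <- function(X, Z) {
  # pairwise squared Euclidean distances, n x m
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  pmax(d2, 0)
}

#' Kernel matrix between two sets of vectors
#'
#' @param X,Z numeric matrices with the same number of columns (rows are
#'   observations). `Z` defaults to `X` (Gram matrix).
#' @param spec a [kernel_spec()].
#' @return `nrow(X) x nrow(Z)` kernel matrix.
#' @export
kernel_matrix <- function(X, Z = X, spec) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  stopifnot(ncol(X) == ncol(Z), inherits(spec, "kernel_spec"))
  if (!all(is.finite(X)) || !all(is.finite(Z)))
    stop("non-finite values in kernel inputs")
  switch(spec$family,
         linear = tcrossprod(X, Z),
         rbf = exp(-spec$gamma * sq_distances(X, Z)),
         puk = {
           d <- sqrt(sq_distances(X, Z))
           a <- 2 * sqrt(2^(1 / spec$omega) - 1) / spec$sigma
           1 / (1 + (a * d)^2)^spec$omega
         })
}
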