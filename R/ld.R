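#' Pairwise r-squared linkage disequilibrium matrix
#'
#' Composite (genotype-correlation) LD: `r2[j, k]` is the squared Pearson
#' correlation of the dosage columns of SNPs j and k. Phase information is
#' not needed; the diagonal is 1 for polymorphic SNPs and the matrix is
#' symmetric with entries in \[0, 1\].
#'
#' @param G a [genotype_matrix()] with no missing values.
#' @param snp_ids SNPs to include (default: all).
#' @return An `ld_matrix`: the symmetric r^2 matrix with SNP ids as dimnames.
#' @export
ld_r2_matrix <- function(G, snp_ids = G$snp_ids) {
  stopifnot(inherits(G, "genotype_matrix"))
  vals <- subset_snps(G, snp_ids)$values
  if (anyNA(vals)) stop("missing genotypes: impute before computing LD")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop("constant (monomorphic) column: ",
         paste(utils::head(snp_ids[sds == 0], 5), collapse = ", "))
  r2 <- stats::cor(vals)^2
  structure(r2, class = c("ld_matrix", class(r2)))
}

#' Mean off-diagonal r-squared of an LD matrix
#'
#' Summary used to compare the redundancy of a marker set before and after
#' the genetic-algorithm pruning; for a set of mutually independent SNPs its
#' expectation is approximately `1 / (n_samples - 1)`.
#'
#' @param ld an `ld_matrix` (or any square symmetric matrix).
#' @return Mean of the off-diagonal entries (0 for a 1 x 1 matrix).
#' @export
mean_offdiag_r2 <- function(ld) {
  m <- unclass(ld)
  if (nrow(m) < 2) return(0)
  mean(m[upper.tri(m)])
}
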