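#' Per-SNP Spearman correlation with the phenotype
#'
#' For every SNP column, the Spearman rank correlation with the phenotype:
#' Pearson correlation of mean ranks (ties receive their average rank), with
#' a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Dosage columns have heavy ties by construction, so the tie-corrected
#' (mean-rank) form is used throughout. A column that is constant after
#' ranking has no defined correlation and is reported as `rho = 0, p = 1`.
#' Bonferroni-adjusted p-values use `m = ncol(G)` tests.
#'
#' @param G a [genotype_matrix()] with no missing values (impute first).
#' @param y numeric phenotype, one value per sample of `G`.
#' @return A data.frame (`snp_stats`) with columns `snp_id`, `rho`, `p_raw`,
#'   `p_adj`.
#' @export
spearman_stats <- function(G, y) {
  stopifnot(inherits(G, "genotype_matrix"))
  vals <- G$values
  if (anyNA(vals)) stop("missing genotypes: run impute_missing_as_het first")
  n <- nrow(vals)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(y) == 0) stop("constant phenotype: correlation undefined")
  ry <- rank(y)
  rg <- apply(vals, 2, rank)
  sds <- apply(rg, 2, stats::sd)
  rho <- rep(0, ncol(vals))
  ok <- sds > 0
  if (any(ok)) rho[ok] <- drop(stats::cor(rg[, ok, drop = FALSE], ry))
  rho <- pmin(1, pmax(-1, rho))
  p <- rep(1, ncol(vals))
  nd <- ok & abs(rho) < 1
  tt <- rho[nd] * sqrt((n - 2) / (1 - rho[nd]^2))
  p[nd] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[ok & abs(rho) == 1] <- 0
  out <- data.frame(snp_id = G$snp_ids, rho = rho, p_raw = p,
                    p_adj = vapply(p, bonferroni_adjust, numeric(1),
                                   m = ncol(vals)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("snp_stats", "data.frame")
  out
}

#' Bonferroni adjustment of a p-value
#'
#' @param p_raw raw p-value in (0, 1\].
#' @param m number of tests.
#' @return `min(1, m * p_raw)`.
#' @export
bonferroni_adjust <- function(p_raw, m) {
  stopifnot(p_raw >= 0, p_raw <= 1, m >= 1)
  min(1, m * p_raw)
}

#' P-value ladders for the nested group series
#'
#' `ladder_real()` is the 8-rung ladder 1e-9, 1e-8, ..., 1e-2 used for dense
#' real chips, where larger thresholds only add markers without changing
#' performance. `ladder_simulated()` extends it to 17 rungs
#' (1e-9...1e-1, then 0.2...0.9) so that the rise-then-fall of accuracy with
#' group size is visible on simulated designs.
#'
#' @return Strictly increasing numeric vector of thresholds.
#' @export
ladder_real <- function() 10^seq(-9, -2)

#' @rdname ladder_real
#' @export
ladder_simulated <- function() c(10^seq(-9, -1), seq(0.2, 0.9, by = 0.1))

#' Build the nested group series from p-value thresholds
#'
#' For each threshold tau the group is \{snp : p < tau\} (strict inequality);
#' because the thresholds increase, the groups are nested
#' A1 ⊆ A2 ⊆ ... . Membership may use raw or Bonferroni-adjusted p-values.
#'
#' @param stats a `snp_stats` data.frame from [spearman_stats()].
#' @param thresholds strictly increasing numeric vector.
#' @param use_adjusted if `TRUE`, group on `p_adj` instead of `p_raw`.
#' @return An object of class `group_series`: list with `thresholds`,
#'   `use_adjusted`, `members` (list of SNP id vectors in original order)
#'   and `sizes`.
#' @export
build_groups <- function(stats, thresholds = ladder_real(),
                         use_adjusted = FALSE) {
  stopifnot(inherits(stats, "data.frame"),
            all(diff(thresholds) > 0))
  p <- if (use_adjusted) stats$p_adj else stats$p_raw
  members <- lapply(thresholds, function(tau) stats$snp_id[p < tau])
  structure(list(thresholds = thresholds, use_adjusted = use_adjusted,
                 members = members, sizes = lengths(members)),
            class = "group_series")
}

#' @export
print.group_series <- function(x, ...) {
  cat("group_series (", if (x$use_adjusted) "adjusted" else "raw",
      " p-values):\n", sep = "")
  for (i in seq_along(x$thresholds))
    cat(sprintf("  A%-2d p < %-8.3g %d SNPs%s\n", i, x$thresholds[i],
                x$sizes[i], if (x$sizes[i] == 0) "  (empty)" else ""))
  invisible(x)
}
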