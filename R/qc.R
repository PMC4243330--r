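#' Quality-control thresholds
#'
#' Thresholds for the three marker-level filters: minimum call rate, minimum
#' minor allele frequency and the Hardy-Weinberg significance level
#' `hwe_alpha`, which is Bonferroni-divided by `n_snps_for_bonferroni`
#' (defaulting to the number of SNPs in the matrix being filtered, i.e. the
#' pre-QC chip count). In `"simultaneous"` mode all statistics are computed
#' on the input matrix and a SNP is removed if it fails any filter; in
#' `"sequential"` mode removals are attributed in the order call rate, MAF,
#' HWE (the retained set is identical, since the statistics are per-SNP).
#'
#' @param min_call_rate minimum fraction of non-missing calls, in \[0,1\].
#' @param min_maf minimum minor allele frequency, in \[0,0.5\].
#' @param hwe_alpha family-wise HWE significance level before division.
#' @param n_snps_for_bonferroni divisor for `hwe_alpha`; `NULL` means the
#'   SNP count of the input matrix.
#' @param apply_mode `"simultaneous"` or `"sequential"`.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.05,
                          hwe_alpha = 0.05, n_snps_for_bonferroni = NULL,
                          apply_mode = c("simultaneous", "sequential")) {
  apply_mode <- match.arg(apply_mode)
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5, hwe_alpha >= 0, hwe_alpha <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha,
                 n_snps_for_bonferroni = n_snps_for_bonferroni,
                 apply_mode = apply_mode),
            class = "qc_thresholds")
}

#' Call rate of a genotype column
#'
#' @param column dosage vector with `NA` for missing calls.
#' @return Fraction of non-missing entries, in \[0,1\].
#' @export
call_rate <- function(column) {
  stopifnot(length(column) > 0)
  mean(!is.na(column))
}

#' Minor allele frequency of a genotype column
#'
#' Allele-B frequency is `sum(dosage) / (2 * n_nonmissing)`; the minor allele
#' frequency is the smaller of it and its complement.
#'
#' @param column dosage vector (0/1/2, `NA` allowed).
#' @return MAF in \[0, 0.5\].
#' @export
maf <- function(column) {
  x <- column[!is.na(column)]
  if (!length(x)) stop("cannot compute MAF of an all-missing column")
  p <- sum(x) / (2 * length(x))
  min(p, 1 - p)
}

#' Hardy-Weinberg equilibrium chi-square p-value
#'
#' One-degree-of-freedom Pearson goodness-of-fit test of the genotype counts
#' (n_AA, n_AB, n_BB) against the Hardy-Weinberg expectations computed from
#' the estimated allele frequency. Monomorphic counts (allele frequency 0
#' or 1) give no evidence of disequilibrium; p is defined as 1.
#'
#' @param counts integer vector (n_AA, n_AB, n_BB).
#' @return Upper-tail chi-square p-value in \[0,1\].
#' @export
hwe_pvalue <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype counts")
  p <- (2 * counts[3] + counts[2]) / (2 * n)  # allele-B frequency
  if (p == 0 || p == 1) return(1.0)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

qc_stats <- function(G) {
  vals <- G$values
  data.frame(
    snp_id = G$snp_ids,
    call_rate = apply(vals, 2, call_rate),
    maf = apply(vals, 2, function(col)
      if (all(is.na(col))) NA_real_ else maf(col)),
    hwe_p = apply(vals, 2, function(col) {
      x <- col[!is.na(col)]
      if (!length(x)) return(NA_real_)
      hwe_pvalue(c(sum(x == 0), sum(x == 1), sum(x == 2)))
    }),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply marker quality control
#'
#' Computes per-SNP call rate, MAF and HWE p-value on the raw (pre-imputation)
#' matrix and removes SNPs failing `call_rate >= min_call_rate`,
#' `maf >= min_maf` or `hwe_p >= hwe_alpha / n_snps_for_bonferroni`. All-missing
#' columns fail call rate and are excluded from the MAF/HWE flags.
#'
#' @param G a [genotype_matrix()], ideally before imputation.
#' @param thresholds a [qc_thresholds()].
#' @return list(genotypes, report) where `report` is a `qc_report`: per-SNP
#'   statistics and pass flags, per-filter removal counts (each filter
#'   evaluated on the full input in simultaneous mode; attributed in order in
#'   sequential mode), the joint removal count and the HWE threshold used.
#' @export
apply_qc <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  m_bonf <- thresholds$n_snps_for_bonferroni
  if (is.null(m_bonf)) m_bonf <- length(G$snp_ids)
  hwe_cut <- thresholds$hwe_alpha / m_bonf
  st <- qc_stats(G)
  st$pass_call_rate <- st$call_rate >= thresholds$min_call_rate
  st$pass_maf <- !is.na(st$maf) & st$maf >= thresholds$min_maf
  st$pass_hwe <- !is.na(st$hwe_p) & st$hwe_p >= hwe_cut
  st$pass <- st$pass_call_rate & st$pass_maf & st$pass_hwe

  if (thresholds$apply_mode == "simultaneous") {
    removed_by <- c(call_rate = sum(!st$pass_call_rate),
                    maf = sum(!st$pass_maf),
                    hwe = sum(!st$pass_hwe))
  } else {
    fail1 <- !st$pass_call_rate
    fail2 <- !fail1 & !st$pass_maf
    fail3 <- !fail1 & !fail2 & !st$pass_hwe
    removed_by <- c(call_rate = sum(fail1), maf = sum(fail2), hwe = sum(fail3))
  }
  report <- structure(list(stats = st, removed_by = removed_by,
                           n_removed = sum(!st$pass),
                           n_retained = sum(st$pass),
                           hwe_threshold = hwe_cut,
                           thresholds = thresholds),
                      class = "qc_report")
  if (!any(st$pass)) {
    e <- simpleError("all SNPs removed by quality control")
    e$report <- report
    stop(e)
  }
  G$values <- G$values[, st$pass, drop = FALSE]
  G$snp_ids <- G$snp_ids[st$pass]
  list(genotypes = G, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d retained, %d removed ",
                     "(call rate %d, MAF %d, HWE %d; HWE threshold %.3g)\n"),
              x$n_retained, x$n_removed, x$removed_by["call_rate"],
              x$removed_by["maf"], x$removed_by["hwe"], x$hwe_threshold))
  invisible(x)
}
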