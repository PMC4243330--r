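#' Indicator term over genotype classes
#'
#' One term of a simulated genetic architecture: a conjunction of atomic
#' conditions on genotype classes. Each condition tests one SNP against one
#' class label (1 = homozygous reference, 2 = heterozygous, 3 = homozygous
#' variant), optionally negated; the term evaluates to 1 for a subject only
#' if every condition holds.
#'
#' @param snp integer vector of SNP column indices (1-based).
#' @param class integer vector of class labels in \{1,2,3\}, same length.
#' @param negated logical vector, same length; `TRUE` means "is not of this
#'   class".
#' @return An object of class `indicator_term`.
#' @export
indicator_term <- function(snp, class, negated = rep(FALSE, length(snp))) {
  stopifnot(length(snp) >= 1, length(class) == length(snp),
            length(negated) == length(snp), all(class %in% 1:3))
  structure(list(snp = as.integer(snp), class = as.integer(class),
                 negated = as.logical(negated)),
            class = "indicator_term")
}

eval_indicator <- function(term, classes) {
  # classes: n_subjects x n_snps matrix of labels 1/2/3
  if (max(term$snp) > ncol(classes))
    stop("indicator term references SNP index ", max(term$snp),
         " outside the genotype matrix (", ncol(classes), " SNPs)")
  hit <- rep(TRUE, nrow(classes))
  for (j in seq_along(term$snp)) {
    ok <- classes[, term$snp[j]] == term$class[j]
    if (term$negated[j]) ok <- !ok
    hit <- hit & ok
  }
  as.numeric(hit)
}

#' Simulation specification
#'
#' Bundles the generative model for a synthetic genotype-phenotype study:
#' cohort size, marker count, the uniform minor-allele-frequency (MAF) range,
#' the phenotype model (`"additive"` or `"epistatic"`), its coefficients
#' (`betas[1]` is the intercept, then one coefficient per causal term), the
#' residual standard deviation and the RNG seed. Two constructors,
#' [sim_spec_additive()] and [sim_spec_epistatic()], give the two reference
#' designs: 1,000 SNPs x 250 subjects with seven additive indicator effects
#' (intercept 0; effects 200, 200, 200, 900, 200, 200, 200; noise sd 5) and
#' 10,000 SNPs x 600 subjects with two epistatic and one moderate effect
#' (150, 150, 40; noise sd 1), both with MAF ~ Uniform(0.10, 0.40).
#'
#' @param n_subjects,n_snps positive integers.
#' @param maf_low,maf_high MAF bounds in (0, 0.5), `maf_low <= maf_high`.
#' @param model `"additive"` or `"epistatic"`.
#' @param betas numeric, intercept followed by one coefficient per term.
#' @param error_sd non-negative residual standard deviation.
#' @param causal_terms list of [indicator_term()]s.
#' @param seed integer RNG seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects, n_snps, maf_low = 0.10, maf_high = 0.40,
                     model = c("additive", "epistatic"), betas, error_sd,
                     causal_terms, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_subjects >= 1, n_snps >= 1,
            maf_low > 0, maf_high < 0.5, maf_low <= maf_high,
            error_sd >= 0,
            length(betas) == length(causal_terms) + 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_snps = as.integer(n_snps),
                 maf_low = maf_low, maf_high = maf_high, model = model,
                 betas = as.numeric(betas), error_sd = error_sd,
                 causal_terms = causal_terms, seed = as.integer(seed)),
            class = "sim_spec")
}

#' @rdname sim_spec
#' @export
sim_spec_additive <- function(n_subjects = 250L, n_snps = 1000L, seed = 1L,
                              error_sd = 5) {
  terms <- list(
    indicator_term(1L, 2L),    # SNP1  heterozygous
    indicator_term(10L, 1L),   # SNP10 homozygous reference
    indicator_term(20L, 3L),   # SNP20 homozygous variant
    indicator_term(30L, 3L),   # SNP30 homozygous variant (major effect)
    indicator_term(40L, 3L),
    indicator_term(50L, 2L),
    indicator_term(60L, 2L))
  sim_spec(n_subjects, n_snps, model = "additive",
           betas = c(0, 200, 200, 200, 900, 200, 200, 200),
           error_sd = error_sd, causal_terms = terms, seed = seed)
}

#' @rdname sim_spec
#' @export
sim_spec_epistatic <- function(n_subjects = 600L, n_snps = 10000L, seed = 1L,
                               error_sd = 1) {
  # L1: SNP4 not homozygous-variant AND SNP3 heterozygous. The epistatic
  # masking term is the one whose conditional mean over SNP3 is non-monotone
  # in dosage, which is what makes the single-marker relationship non-linear.
  terms <- list(
    indicator_term(c(4L, 3L), c(3L, 2L), c(TRUE, FALSE)),
    indicator_term(5L, 3L),                               # SNP5==3
    indicator_term(c(12L, 9L), c(1L, 3L), c(TRUE, FALSE)))# SNP12!=1 & SNP9==3
  sim_spec(n_subjects, n_snps, model = "epistatic",
           betas = c(0, 150, 150, 40),
           error_sd = error_sd, causal_terms = terms, seed = seed)
}

#' Indices of the causal SNPs of a simulation spec
#' @param spec a [sim_spec()].
#' @return sorted unique integer vector of SNP column indices.
#' @export
causal_snp_indices <- function(spec) {
  sort(unique(unlist(lapply(spec$causal_terms, `[[`, "snp"))))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP, a minor allele frequency q is drawn from
#' Uniform(`maf_low`, `maf_high`); subjects then receive genotype classes
#' (1, 2, 3) independently with Hardy-Weinberg probabilities
#' ((1-q)^2, 2q(1-q), q^2). Classes are stored as allele-B dosages
#' (class - 1) with `coding_origin = "simulated123"`. Linkage disequilibrium
#' between markers arises only through finite sampling; no block structure is
#' imposed.
#'
#' @param n_subjects,n_snps positive integers.
#' @param maf_low,maf_high MAF bounds in (0, 0.5); equal bounds (a fixed q)
#'   are permitted for controlled experiments.
#' @param seed integer seed; the same seed always reproduces the same matrix.
#' @return A [genotype_matrix()] with SNP ids `SNP1..SNPm`, sample ids
#'   `S1..Sn` and attribute `maf` holding the drawn frequencies.
#' @export
simulate_genotypes <- function(n_subjects, n_snps, maf_low = 0.10,
                               maf_high = 0.40, seed = 1L) {
  stopifnot(maf_low > 0, maf_high < 0.5, maf_low <= maf_high)
  withr::with_seed(as.integer(seed), {
    q <- stats::runif(n_snps, maf_low, maf_high)
    u <- matrix(stats::runif(n_subjects * n_snps), nrow = n_subjects)
    p_ref <- matrix((1 - q)^2, nrow = n_subjects, ncol = n_snps, byrow = TRUE)
    p_het <- matrix(2 * q * (1 - q), nrow = n_subjects, ncol = n_snps,
                    byrow = TRUE)
    dos <- (u > p_ref) + (u > p_ref + p_het)
  })
  G <- genotype_matrix(dos,
                       snp_ids = paste0("SNP", seq_len(n_snps)),
                       sample_ids = paste0("S", seq_len(n_subjects)),
                       coding_origin = "simulated123")
  attr(G, "maf") <- q
  G
}

simulated_classes <- function(G) {
  if (G$coding_origin != "simulated123")
    stop("phenotype simulation requires genotypes with simulated 1/2/3 labels")
  G$values + 1L
}

sim_design_matrix <- function(G, spec) {
  classes <- simulated_classes(G)
  vapply(spec$causal_terms, eval_indicator, numeric(nrow(classes)),
         classes = classes)
}

simulate_phenotype <- function(G, spec, error_seed) {
  L <- sim_design_matrix(G, spec)
  signal <- spec$betas[1] + drop(L %*% spec$betas[-1])
  eps <- if (spec$error_sd > 0)
    withr::with_seed(as.integer(error_seed),
                     stats::rnorm(nrow(L), 0, spec$error_sd))
  else rep(0, nrow(L))
  y <- signal + eps
  names(y) <- G$sample_ids
  y
}

#' Simulate a continuous phenotype from additive indicator effects
#'
#' Y_i = beta0 + sum_k beta_k L_k(i) + eps_i with eps_i ~ N(0, error_sd^2),
#' where each L_k is an [indicator_term()] on the subject's genotype classes.
#' The error stream is seeded separately from the genotypes (default
#' `spec$seed + 1`) so the same genotype matrix can be reused across
#' phenotype redraws.
#'
#' @param G a [genotype_matrix()] with `coding_origin = "simulated123"`.
#' @param spec a [sim_spec()] with `model = "additive"`.
#' @param error_seed seed for the noise draw.
#' @return Named numeric phenotype vector aligned to `G$sample_ids`.
#' @export
simulate_phenotype_additive <- function(G, spec, error_seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "sim_spec"), spec$model == "additive")
  simulate_phenotype(G, spec, error_seed)
}

#' Simulate a continuous phenotype with epistasis
#'
#' Same linear-in-indicators form as [simulate_phenotype_additive()], but the
#' terms are conjunctions over several SNPs (gene-gene interactions), so no
#' single marker carries the full effect.
#'
#' @inheritParams simulate_phenotype_additive
#' @param spec a [sim_spec()] with `model = "epistatic"`.
#' @return Named numeric phenotype vector aligned to `G$sample_ids`.
#' @export
simulate_phenotype_epistatic <- function(G, spec, error_seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "sim_spec"), spec$model == "epistatic")
  simulate_phenotype(G, spec, error_seed)
}

#' Generate a complete simulated study
#'
#' Convenience wrapper drawing genotypes and phenotype from one `sim_spec`.
#'
#' @param spec a [sim_spec()].
#' @return list(genotypes, phenotype, spec).
#' @export
simulate_study <- function(spec) {
  G <- simulate_genotypes(spec$n_subjects, spec$n_snps, spec$maf_low,
                          spec$maf_high, seed = spec$seed)
  y <- if (spec$model == "additive") simulate_phenotype_additive(G, spec)
  else simulate_phenotype_epistatic(G, spec)
  list(genotypes = G, phenotype = y, spec = spec)
}
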