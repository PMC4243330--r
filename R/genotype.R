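#' Genotype matrix in allele-B dosage coding
#'
#' The internal container for genotype data: an `n_samples x n_snps` integer
#' matrix of allele-B dosages (0 = AA, 1 = AB, 2 = BB) with `NA` marking
#' missing calls. Row names are sample identifiers, column names SNP
#' identifiers; both must be unique. `coding_origin` records the coding the
#' data arrived in (`"dosage012"`, `"simulated123"`, `"vcf_gt"` or
#' `"plink_raw"`). Simulated data use the class labels 1/2/3 (homozygous
#' reference / heterozygous / homozygous variant); they are stored as
#' dosage = class - 1 and the original class of any cell is recoverable as
#' dosage + 1.
#'
#' @param values integer matrix, samples in rows, SNPs in columns; entries
#'   0/1/2 or `NA`.
#' @param snp_ids,sample_ids character vectors of unique identifiers; default
#'   to the dimnames of `values`.
#' @param coding_origin one of `"dosage012"`, `"simulated123"`, `"vcf_gt"`,
#'   `"plink_raw"`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values,
                            snp_ids = colnames(values),
                            sample_ids = rownames(values),
                            coding_origin = c("dosage012", "simulated123",
                                              "vcf_gt", "plink_raw")) {
  coding_origin <- match.arg(coding_origin)
  values <- as.matrix(values)
  if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(snp_ids)) stop("duplicate SNP identifiers")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (length(snp_ids) != ncol(values) || length(sample_ids) != nrow(values))
    stop("identifier lengths do not match matrix dimensions")
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("dosage outside {0,1,2} at sample '%s', SNP '%s'",
                 sample_ids[idx[1]], snp_ids[idx[2]]))
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(list(values = values, snp_ids = snp_ids, sample_ids = sample_ids,
                 coding_origin = coding_origin),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%s), %d missing cells\n",
              length(x$sample_ids), length(x$snp_ids), x$coding_origin,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

n_missing <- function(G) sum(is.na(G$values))

#' Read genotypes from CSV, PLINK .raw or VCF
#'
#' Normalizes any supported dialect to the internal 0/1/2 allele-B dosage
#' coding. CSV: first column is the sample id, header row carries SNP ids,
#' missing cells are empty or `NA`; a `coding` argument accepts either the
#' canonical `0/1/2` dosages or the simulated `1/2/3` class labels, which are
#' mapped 1->0, 2->1, 3->2. PLINK `.raw` files (header
#' `FID IID PAT MAT SEX PHENOTYPE SNP1_A ...`) already hold counted-allele
#' dosages. VCF genotypes are taken from the GT field of biallelic diploid
#' records: `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`
#' (phased separators `|` are accepted).
#'
#' @param path file path.
#' @param dialect `"csv"`, `"plink_raw"` or `"vcf"`.
#' @param coding for `dialect = "csv"`: `"dosage012"` (default) or
#'   `"simulated123"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("csv", "plink_raw", "vcf"),
                           coding = c("dosage012", "simulated123")) {
  dialect <- match.arg(dialect)
  coding <- match.arg(coding)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         csv = read_genotypes_csv(path, coding),
         plink_raw = read_genotypes_plink_raw(path),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_csv <- function(path, coding) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("", "NA"),
                          data.table = FALSE)
  sample_ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(vals) <- "integer"
  if (coding == "simulated123") {
    bad <- !is.na(vals) & !(vals %in% 1:3)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("genotype class outside {1,2,3} at row %d, column '%s'",
                   idx[1], colnames(vals)[idx[2]]))
    }
    vals <- vals - 1L
  }
  genotype_matrix(vals, snp_ids = colnames(vals), sample_ids = sample_ids,
                  coding_origin = if (coding == "simulated123")
                    "simulated123" else "dosage012")
}

read_genotypes_plink_raw <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("", "NA"),
                          data.table = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(dt)[seq_along(meta)]))
    stop("not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE ...)")
  vals <- as.matrix(dt[, setdiff(names(dt), meta), drop = FALSE])
  storage.mode(vals) <- "integer"
  genotype_matrix(vals, snp_ids = colnames(vals),
                  sample_ids = as.character(dt$IID),
                  coding_origin = "plink_raw")
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multi-allelic VCF record at ", fix[which(multi)[1], "CHROM"], ":",
         fix[which(multi)[1], "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")  # SNPs x samples
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids))
    ids <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  gtn <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = nrow(gtn), ncol = ncol(gtn))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  flat <- gtn
  miss <- is.na(flat) | flat == "./." | flat == "."
  bad <- !miss & !(flat %in% names(known))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-diploid or unsupported GT '%s' in record '%s'",
                 flat[idx[1], idx[2]], ids[idx[1]]))
  }
  dos[!miss] <- known[flat[!miss]]
  genotype_matrix(t(dos), snp_ids = ids, sample_ids = colnames(gt),
                  coding_origin = "vcf_gt")
}

#' Write a genotype matrix as dosage CSV
#'
#' Inverse of `read_genotypes(..., dialect = "csv")`: first column `sample_id`,
#' one column per SNP, missing cells written as `NA`.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(sample_id = G$sample_ids, G$values, check.names = FALSE)
  data.table::fwrite(df, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Impute missing genotypes as heterozygous
#'
#' Every missing call is set to the heterozygote dosage 1, the convention for
#' chip read errors in the pipeline this package implements.
#'
#' @param G a [genotype_matrix()].
#' @return A list with elements `genotypes` (the imputed matrix, mask
#'   all-false) and `n_imputed` (number of cells that were missing).
#' @export
impute_missing_as_het <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  miss <- is.na(G$values)
  G$values[miss] <- 1L
  list(genotypes = G, n_imputed = sum(miss))
}

#' Drop monomorphic SNPs
#'
#' Removes SNP columns with no allelic variation (fewer than two distinct
#' non-missing dosage values), as such markers carry no association signal.
#'
#' @param G a [genotype_matrix()].
#' @return A list with elements `genotypes` (polymorphic columns only, input
#'   order preserved) and `removed` (character vector of removed SNP ids).
#' @export
drop_monomorphic <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  n_distinct <- apply(G$values, 2, function(col) length(unique(col[!is.na(col)])))
  keep <- n_distinct >= 2
  if (!any(keep)) stop("all SNPs are monomorphic: empty design matrix")
  removed <- G$snp_ids[!keep]
  G$values <- G$values[, keep, drop = FALSE]
  G$snp_ids <- G$snp_ids[keep]
  list(genotypes = G, removed = removed)
}

#' Subset a genotype matrix by SNP ids
#'
#' @param G a [genotype_matrix()].
#' @param snp_ids SNP identifiers to keep, in the order given.
#' @return A [genotype_matrix()] restricted to `snp_ids`.
#' @export
subset_snps <- function(G, snp_ids) {
  stopifnot(inherits(G, "genotype_matrix"))
  missing_ids <- setdiff(snp_ids, G$snp_ids)
  if (length(missing_ids))
    stop("unknown SNP ids: ", paste(utils::head(missing_ids, 5), collapse = ", "))
  G$values <- G$values[, snp_ids, drop = FALSE]
  G$snp_ids <- as.character(snp_ids)
  G
}

#' Load a phenotype vector aligned to a genotype matrix
#'
#' Reads a two-column CSV (`sample_id`, `phenotype`), drops samples with a
#' missing phenotype (with a message giving the count), and returns the values
#' aligned to the sample order of `G`. Samples present in only one of the two
#' sources are an error: identifiers must match explicitly.
#'
#' @param path CSV path with columns `sample_id` and `phenotype`.
#' @param G a [genotype_matrix()] to align against.
#' @return A named numeric vector ordered as `G$sample_ids` (restricted to
#'   samples with a phenotype), plus the possibly-subset `G` in attribute
#'   handling left to the caller via [align_phenotype()].
#' @export
read_phenotype <- function(path, G = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("", "NA"))
  if (ncol(dt) < 2) stop("phenotype CSV needs columns sample_id, phenotype")
  y <- as.numeric(dt[[2]])
  names(y) <- as.character(dt[[1]])
  n_miss <- sum(is.na(y))
  if (n_miss > 0) {
    message(n_miss, " sample(s) dropped for missing phenotype")
    y <- y[!is.na(y)]
  }
  if (!is.null(G)) y <- align_phenotype(y, G)$phenotype
  y
}

#' Align a phenotype vector with a genotype matrix
#'
#' Restricts both to their common samples (genotype order); errors if no
#' samples are shared.
#'
#' @param y named numeric phenotype vector.
#' @param G a [genotype_matrix()].
#' @return list(genotypes, phenotype) with identical sample order.
#' @export
align_phenotype <- function(y, G) {
  stopifnot(inherits(G, "genotype_matrix"), !is.null(names(y)))
  common <- intersect(G$sample_ids, names(y))
  if (!length(common)) stop("no samples shared between genotypes and phenotype")
  G$values <- G$values[common, , drop = FALSE]
  G$sample_ids <- common
  list(genotypes = G, phenotype = y[common])
}
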