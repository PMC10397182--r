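#' In-memory genotype dataset
#'
#' The central container of the package: an ordered set of biallelic SNPs
#' with per-sample alternate-allele dosage calls. Dosage counts copies of the
#' alternate allele, so entries are 0, 1 or 2; a missing call is `NA` (the
#' single missingness sentinel used throughout the package).
#'
#' @param variants data.frame with columns `chrom` (character, no "chr"
#'   prefix), `pos` (1-based integer), `ref`, `alt` (single bases A/C/G/T)
#'   and `id` (may be ".").
#' @param samples character vector of unique sample identifiers.
#' @param dosage integer matrix, samples x variants, entries in
#'   \{0, 1, 2, NA\}.
#' @param skip_summary optional named integer vector of records skipped while
#'   reading (see [read_vcf()]).
#' @return An object of class `GenotypeDataset` (a list with elements
#'   `variants`, `samples`, `dosage`, `skip_summary`).
#' @export
genotype_dataset <- function(variants, samples, dosage, skip_summary = NULL) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "id") %in% names(variants)))
  samples <- as.character(samples)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(variants)) {
    stop("dosage must be length(samples) x nrow(variants)")
  }
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("non-missing dosage entries must be in {0,1,2}")
  }
  variants$chrom <- normalize_chrom(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  rownames(dosage) <- samples
  colnames(dosage) <- variant_key(variants)
  structure(
    list(variants = variants, samples = samples, dosage = dosage,
         skip_summary = skip_summary),
    class = "GenotypeDataset"
  )
}

#' @export
print.GenotypeDataset <- function(x, ...) {
  cat(sprintf("GenotypeDataset: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing call fraction: %.4f\n", miss))
  if (!is.null(x$skip_summary) && any(x$skip_summary > 0)) {
    cat("  records skipped at read: ",
        paste(names(x$skip_summary), x$skip_summary, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of variants / samples in a dataset
#' @param data a `GenotypeDataset`.
#' @return integer count.
#' @export
n_variants <- function(data) nrow(data$variants)

#' @rdname n_variants
#' @export
n_samples <- function(data) length(data$samples)

#' Subset a genotype dataset
#'
#' @param data a `GenotypeDataset`.
#' @param idx integer indices of variants (resp. samples) to keep, in the
#'   order they should appear.
#' @return a new `GenotypeDataset`.
#' @export
subset_variants <- function(data, idx) {
  genotype_dataset(data$variants[idx, , drop = FALSE], data$samples,
                   data$dosage[, idx, drop = FALSE], data$skip_summary)
}

#' @rdname subset_variants
#' @export
subset_samples <- function(data, idx) {
  if (is.character(idx)) {
    unknown <- setdiff(idx, data$samples)
    if (length(unknown)) {
      stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    }
    idx <- match(idx, data$samples)
  }
  genotype_dataset(data$variants, data$samples[idx],
                   data$dosage[idx, , drop = FALSE], data$skip_summary)
}

# "1:100:A:G"-style key, unique after QC
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

# strip a leading "chr"; chromosome labels are bare ("1".."22","X",...)
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

# deterministic genomic order: numeric chromosomes first, then lexicographic
chrom_order <- function(chrom, pos) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom, pos)
}

#' Watson-Crick complement of allele characters
#' @param x character vector of single bases A/C/G/T.
#' @return complemented bases.
#' @export
complement_alleles <- function(x) {
  chartr("ACGT", "TGCA", toupper(x))
}

#' Is a variant palindromic (A/T or C/G)?
#'
#' Palindromic (ambiguous-strand) SNPs cannot be oriented from their alleles
#' alone, so they are removed in QC and excluded from cross-dataset matching.
#'
#' @param ref,alt allele character vectors.
#' @return logical vector.
#' @export
is_palindromic <- function(ref, alt) {
  toupper(alt) == complement_alleles(ref)
}
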