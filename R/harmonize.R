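#' Match variants between two datasets with strand-flip awareness
#'
#' Matching is by (chrom, pos) only; the allele logic then decides the
#' orientation of B relative to A: `direct` (same ref/alt), `swap`
#' (ref/alt exchanged; dosage recodes d -> 2 - d), `flip` (B on the opposite
#' strand; alleles complement, dosages unchanged), `flip_swap` (both), or
#' `unmatched` when the allele pairs are irreconcilable. Palindromic (A/T,
#' C/G) variants in either set are classed `ambiguous_palindromic` — flip
#' versus swap is undecidable for them — and never enter concordance or
#' intersection outputs.
#'
#' @param a,b variant data.frames (columns `chrom`, `pos`, `ref`, `alt`),
#'   each deduplicated on (chrom, pos), or `GenotypeDataset`s.
#' @return data.frame with columns `chrom`, `pos`, `action`, `index_a`,
#'   `index_b` — one row per shared (chrom, pos).
#' @export
match_variants <- function(a, b) {
  if (inherits(a, "GenotypeDataset")) a <- a$variants
  if (inherits(b, "GenotypeDataset")) b <- b$variants
  key_a <- paste(a$chrom, a$pos)
  key_b <- paste(b$chrom, b$pos)
  if (anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stop("variant lists must be deduplicated on (chrom, pos)")
  }
  ia <- which(key_a %in% key_b)
  ib <- match(key_a[ia], key_b)
  refA <- toupper(a$ref[ia]); altA <- toupper(a$alt[ia])
  refB <- toupper(b$ref[ib]); altB <- toupper(b$alt[ib])
  action <- rep("unmatched", length(ia))
  action[refA == refB & altA == altB] <- "direct"
  action[refA == altB & altA == refB] <- "swap"
  cB <- complement_alleles(refB); cBa <- complement_alleles(altB)
  action[action == "unmatched" & refA == cB & altA == cBa] <- "flip"
  action[action == "unmatched" & refA == cBa & altA == cB] <- "flip_swap"
  pal <- is_palindromic(refA, altA) | is_palindromic(refB, altB)
  action[pal] <- "ambiguous_palindromic"
  data.frame(chrom = a$chrom[ia], pos = a$pos[ia], action = action,
             index_a = ia, index_b = ib, stringsAsFactors = FALSE)
}

# the actions that make a usable match
matched_actions <- c("direct", "swap", "flip", "flip_swap")

#' Align a dataset to its match partner's orientation
#'
#' Restricts B to the matched variants (in match order), recodes dosages
#' d -> 2 - d for `swap`/`flip_swap` records, and rewrites ref/alt to A's
#' orientation. Missing calls stay missing.
#'
#' @param b a `GenotypeDataset` (the B side of [match_variants()]).
#' @param matches output of [match_variants()].
#' @return a `GenotypeDataset` aligned to A.
#' @export
align_genotypes <- function(b, matches) {
  m <- matches[matches$action %in% matched_actions, , drop = FALSE]
  if (nrow(m) && (max(m$index_b) > n_variants(b) || min(m$index_b) < 1L)) {
    stop("match records reference variant indices outside the dataset")
  }
  out <- subset_variants(b, m$index_b)
  recode <- m$action %in% c("swap", "flip_swap")
  if (any(recode)) {
    out$dosage[, recode] <- 2L - out$dosage[, recode, drop = FALSE]
    tmp <- out$variants$ref[recode]
    out$variants$ref[recode] <- out$variants$alt[recode]
    out$variants$alt[recode] <- tmp
  }
  comp <- m$action %in% c("flip", "flip_swap")
  if (any(comp)) {
    out$variants$ref[comp] <- complement_alleles(out$variants$ref[comp])
    out$variants$alt[comp] <- complement_alleles(out$variants$alt[comp])
  }
  colnames(out$dosage) <- variant_key(out$variants)
  out
}

#' Per-sample genotype concordance between paired datasets
#'
#' For each (sample in A, sample in B) pair, concordance is the fraction of
#' harmonized variants, non-missing in both datasets, whose dosages are
#' identical (genotype-level comparison: a het matches a het regardless of
#' phase). Pairs with no comparable variant are flagged and excluded from
#' the cohort mean.
#'
#' @param a a `GenotypeDataset` restricted to the matched variants.
#' @param b_aligned the output of [align_genotypes()] on the same matches.
#' @param sample_pairs data.frame with columns `sample_a`, `sample_b`; by
#'   default samples shared by name are self-paired.
#' @return list of class `ConcordanceReport`: `pairs` (data.frame with
#'   `sample_a`, `sample_b`, `n_compared`, `n_identical`, `concordance`)
#'   and `mean_concordance`.
#' @export
sample_concordance <- function(a, b_aligned, sample_pairs = NULL) {
  if (n_variants(a) != n_variants(b_aligned)) {
    stop("datasets must share the matched variant set in identical order")
  }
  if (is.null(sample_pairs)) {
    shared <- intersect(a$samples, b_aligned$samples)
    sample_pairs <- data.frame(sample_a = shared, sample_b = shared,
                               stringsAsFactors = FALSE)
  }
  bad_a <- setdiff(sample_pairs$sample_a, a$samples)
  bad_b <- setdiff(sample_pairs$sample_b, b_aligned$samples)
  if (length(bad_a) || length(bad_b)) {
    stop("unknown sample id(s): ", paste(c(bad_a, bad_b), collapse = ", "))
  }
  ia <- match(sample_pairs$sample_a, a$samples)
  ib <- match(sample_pairs$sample_b, b_aligned$samples)
  ga <- a$dosage[ia, , drop = FALSE]
  gb <- b_aligned$dosage[ib, , drop = FALSE]
  both <- !is.na(ga) & !is.na(gb)
  n_compared <- rowSums(both)
  n_identical <- rowSums(both & (ga == gb), na.rm = TRUE)
  conc <- ifelse(n_compared > 0, n_identical / n_compared, NA_real_)
  pairs <- data.frame(sample_a = sample_pairs$sample_a,
                      sample_b = sample_pairs$sample_b,
                      n_compared = n_compared, n_identical = n_identical,
                      concordance = conc, stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 mean_concordance = mean(conc, na.rm = TRUE)),
            class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf("ConcordanceReport: %d sample pairs, mean concordance %.4f\n",
              nrow(x$pairs), x$mean_concordance))
  invisible(x)
}

#' Intersect a dataset with a reference SNP panel
#'
#' Keeps variants whose (chrom, pos) occurs in the panel and whose allele
#' pair matches the panel entry under direct, swap, strand-flip or
#' flip-and-swap orientation. Alleles are not reoriented (orientation is
#' irrelevant for downstream PCA); variant order is preserved. Palindromic
#' variants never match (upstream QC removes them; any survivor is dropped
#' here for the same ambiguity reason).
#'
#' @param data a `GenotypeDataset`.
#' @param panel a `VariantPanel` from [read_panel()].
#' @return the restricted `GenotypeDataset`.
#' @export
intersect_with_panel <- function(data, panel) {
  v <- data$variants
  hit <- match(paste(v$chrom, v$pos), paste(panel$chrom, panel$pos))
  keep <- !is.na(hit)
  if (any(keep)) {
    r <- toupper(v$ref[keep]); a <- toupper(v$alt[keep])
    p1 <- toupper(panel$a1[hit[keep]]); p2 <- toupper(panel$a2[hit[keep]])
    cp1 <- complement_alleles(p1); cp2 <- complement_alleles(p2)
    ok <- (r == p1 & a == p2) | (r == p2 & a == p1) |
      (r == cp1 & a == cp2) | (r == cp2 & a == cp1)
    ok <- ok & !is_palindromic(r, a)
    keep[keep] <- ok
  }
  subset_variants(data, which(keep))
}
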