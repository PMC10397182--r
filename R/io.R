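#' Read a multi-sample VCF of biallelic SNP genotypes
#'
#' Parses a VCF v4.2 (via vcfR) into a [genotype_dataset()]. Only biallelic
#' SNP records are kept; multi-allelic records, indels/non-ACGT alleles and
#' records whose FILTER field is neither `PASS` nor `.` are skipped and
#' counted in the returned `skip_summary`. Genotypes are decoded from the GT
#' field: phased and unphased calls are equivalent (`0|1` and `0/1` both give
#' dosage 1) and any call containing `.` (no-calls and half-calls such as
#' `./1`) is treated as missing. Records are sorted by (chrom, pos);
#' chromosome labels lose any leading "chr".
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param keep_samples optional character vector of sample ids to retain (in
#'   the given order); unknown ids raise an error listing them.
#' @return a `GenotypeDataset` whose `skip_summary` has elements
#'   `filtered`, `multiallelic`, `non_snp`.
#' @export
read_vcf <- function(path, keep_samples = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L) {
    stop("VCF has no genotype (FORMAT/sample) columns: ", path)
  }
  fmt <- gt[, 1L]
  has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (nrow(fix) > 0L && !all(has_gt)) {
    bad <- which(!has_gt)[1L]
    stop(sprintf("record %s:%s has no GT in its FORMAT field",
                 fix[bad, "CHROM"], fix[bad, "POS"]))
  }
  samples <- colnames(gt)[-1L]
  if (!is.null(keep_samples)) {
    unknown <- setdiff(keep_samples, samples)
    if (length(unknown)) {
      stop("keep_samples not present in VCF: ", paste(unknown, collapse = ", "))
    }
  }

  filt <- fix[, "FILTER"]
  ok_filter <- is.na(filt) | filt == "PASS" | filt == "."
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

  keep <- ok_filter & !multi & snp
  skip_summary <- c(
    filtered = sum(!ok_filter),
    multiallelic = sum(ok_filter & multi),
    non_snp = sum(ok_filter & !multi & !snp)
  )

  variants <- data.frame(
    chrom = normalize_chrom(fix[keep, "CHROM"]),
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    id = ifelse(is.na(fix[keep, "ID"]), ".", fix[keep, "ID"]),
    stringsAsFactors = FALSE
  )

  gtm <- gt[keep, -1L, drop = FALSE]
  # GT is the first colon-separated field by VCF convention
  gtm[] <- sub(":.*$", "", gtm)
  dos <- matrix(NA_integer_, nrow = nrow(gtm), ncol = ncol(gtm))
  dos[gtm %in% c("0/0", "0|0")] <- 0L
  dos[gtm %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gtm %in% c("1/1", "1|1")] <- 2L

  ord <- chrom_order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dos <- t(dos[ord, , drop = FALSE])
  rownames(dos) <- samples

  data <- genotype_dataset(variants, samples, dos, skip_summary)
  if (!is.null(keep_samples)) data <- subset_samples(data, keep_samples)
  data
}

#' Write a genotype dataset as a minimal VCF v4.2
#'
#' Emits unphased GT-only records (`0/0`, `0/1`, `1/1`, `./.`) with FILTER
#' `PASS`. [read_vcf()] of the written file reproduces the dataset.
#'
#' @param data a `GenotypeDataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(data, path) {
  v <- data$variants
  gt_code <- c("0/0", "0/1", "1/1")
  gm <- matrix("./.", nrow = n_variants(data), ncol = n_samples(data))
  d <- t(data$dosage)
  ok <- !is.na(d)
  gm[ok] <- gt_code[d[ok] + 1L]
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gm, 1L, paste, collapse = "\t"), sep = "\t")
  if (n_variants(data) == 0L) body <- character(0)
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", data$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a reference SNP panel
#'
#' A panel is a TSV with columns chrom, pos, allele1, allele2 and optionally
#' an id (rsID). A header row is auto-detected (non-numeric `pos` in the
#' first row). Rows duplicating an earlier (chrom, pos) are dropped with a
#' warning giving the count. Palindromic entries are retained: excluding
#' them is a QC decision taken downstream, not a read decision.
#'
#' @param path path to the TSV.
#' @return data.frame of class `VariantPanel` with columns `chrom`, `pos`,
#'   `a1`, `a2`, `id` and attribute `n_duplicates`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      a1 = character(), a2 = character(), id = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_duplicates") <- 0L
    class(out) <- c("VariantPanel", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "[ \t]+")
  first <- fields[[1L]]
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2L])))
  offset <- if (has_header) 1L else 0L
  fields <- fields[(offset + 1L):length(fields)]
  if (!length(fields)) {
    return(read_panel_empty())
  }
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("panel line ", which(nf < 4L)[1L] + offset, ": fewer than 4 columns")
  }
  chrom <- normalize_chrom(vapply(fields, `[`, "", 1L))
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  a1 <- toupper(vapply(fields, `[`, "", 3L))
  a2 <- toupper(vapply(fields, `[`, "", 4L))
  id <- vapply(fields, function(f) if (length(f) >= 5L) f[5L] else ".", "")
  bad <- which(!(a1 %in% c("A", "C", "G", "T")) | !(a2 %in% c("A", "C", "G", "T")))
  if (length(bad)) {
    stop("panel line ", bad[1L] + offset, ": non-ACGT allele")
  }
  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    warning(sum(dup), " duplicated (chrom,pos) panel row(s) dropped")
  }
  out <- data.frame(chrom = chrom[!dup], pos = pos[!dup], a1 = a1[!dup],
                    a2 = a2[!dup], id = id[!dup], stringsAsFactors = FALSE)
  attr(out, "n_duplicates") <- sum(dup)
  class(out) <- c("VariantPanel", "data.frame")
  out
}

read_panel_empty <- function() {
  out <- data.frame(chrom = character(), pos = integer(), a1 = character(),
                    a2 = character(), id = character(), stringsAsFactors = FALSE)
  attr(out, "n_duplicates") <- 0L
  class(out) <- c("VariantPanel", "data.frame")
  out
}

#' Write / read principal component scores (eigenvec layout)
#'
#' The on-disk layout is the whitespace-delimited table downstream tools
#' expect: header `FID IID PC1..PCk`, FID duplicated from IID, values at six
#' significant digits, rows in sample order.
#'
#' @param result a `PCResult` from [compute_pcs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pcs <- function(result, path) {
  k <- result$k
  stopifnot(k >= 1L)
  scores <- signif(result$scores, 6L)
  df <- data.frame(FID = result$samples, IID = result$samples, scores,
                   stringsAsFactors = FALSE)
  names(df) <- c("FID", "IID", paste0("PC", seq_len(k)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pcs
#' @return for `read_pcs`: a list with `samples` and `scores`.
#' @export
read_pcs <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  scores <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(scores) <- df$IID
  list(samples = df$IID, scores = scores)
}
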