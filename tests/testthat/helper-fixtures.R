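# fixtures are built in code: small VCF writers and dataset constructors

vcf_header <- function(samples = c("S1", "S2", "S3")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_test_vcf <- function(records, samples = c("S1", "S2", "S3"),
                           path = tempfile(fileext = ".vcf")) {
  writeLines(c(vcf_header(samples), records), path)
  path
}

vrec <- function(chrom, pos, ref, alt, gts, id = ".", filter = "PASS") {
  paste(c(chrom, pos, id, ref, alt, ".", filter, ".", "GT", gts),
        collapse = "\t")
}

# quick dataset: dosage given as samples x variants matrix
make_dataset <- function(dosage, chrom = NULL, pos = NULL,
                         ref = NULL, alt = NULL,
                         samples = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  genotype_dataset(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               id = rep(".", m), stringsAsFactors = FALSE),
    samples, dosage)
}

# plain mean silhouette on euclidean distances
cluster_silhouette <- function(x, labels) {
  dmat <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(dmat[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(dmat[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# independent enumeration oracle for the HWE exact test
hwe_enum_oracle <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  rare <- min(2 * n_ref_hom + n_het, 2 * n_alt_hom + n_het)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hs, function(h) {
    choose(n, h) * choose(n - h, (rare - h) / 2) * 2^h / choose(2 * n, rare)
  }, numeric(1))
  pr <- pr / sum(pr)
  po <- pr[match(n_het, hs)]
  sum(pr[pr <= po * (1 + 1e-12)])
}
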