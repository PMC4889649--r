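# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no binary fixtures.

ANC <- c("African", "Amerindian", "European")

# A tiny panel: H haplotype rows (haploid "samples" unless meta given).
tiny_panel <- function(alleles, sample_id = NULL, copy = NULL,
                       sex = "female", group = NA, chrom = "1") {
  alleles <- as.matrix(alleles)
  H <- nrow(alleles); M <- ncol(alleles)
  if (is.null(sample_id)) sample_id <- paste0("h", seq_len(H))
  if (is.null(copy)) copy <- rep(1L, H)
  hap_panel(alleles, hap_meta(sample_id, copy, sex, group),
            site_map(rep(chrom, M), seq_len(M)))
}

# Diploid panel: H/2 samples of two rows each.
diploid_panel <- function(alleles, sex = "female", group = NA,
                          chrom = "1") {
  alleles <- as.matrix(alleles)
  H <- nrow(alleles)
  stopifnot(H %% 2 == 0)
  s <- rep(paste0("s", seq_len(H / 2)), each = 2)
  hap_panel(alleles, hap_meta(s, rep(1:2, H / 2), sex, group),
            site_map(rep(chrom, ncol(alleles)), seq_len(ncol(alleles))))
}

diploid_calls <- function(calls, labels = ANC, sex = "female") {
  calls <- as.matrix(calls)
  H <- nrow(calls)
  stopifnot(H %% 2 == 0)
  s <- rep(paste0("s", seq_len(H / 2)), each = 2)
  la_calls(calls, labels, hap_meta(s, rep(1:2, H / 2), sex, NA),
           site_map(rep("1", ncol(calls)), seq_len(ncol(calls))))
}

# Write a small phased VCF from genotype-string rows.
write_test_vcf <- function(path, samples, records) {
  # records: list of list(chrom, pos, id, ref, alt, gts = character)
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT",
            r$gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# ---- independent Mendelian transmission oracles (enumeration) --------

# All unordered diploid calls over K ancestries.
unordered_pairs <- function(K = 3) {
  out <- list()
  for (i in seq_len(K)) for (j in i:K) out[[length(out) + 1]] <- c(i, j)
  out
}

# Pair oracle: enumerate transmitted allele from the observed parent and
# any allele from the unobserved parent; consistent iff some combination
# reproduces the child's multiset.
oracle_pair <- function(parent, child, K = 3) {
  for (p in parent) for (o in seq_len(K)) {
    if (identical(sort(c(p, o)), sort(child))) return(TRUE)
  }
  FALSE
}

# Trio oracle: one allele from each parent.
oracle_trio <- function(mother, father, child) {
  for (pm in mother) for (pf in father) {
    if (identical(sort(c(pm, pf)), sort(child))) return(TRUE)
  }
  FALSE
}

# X oracles: son's X is maternal; daughter's is paternal + maternal.
oracle_x_ms <- function(mother, son) son %in% mother
oracle_x_md <- function(mother, daughter, K = 3) {
  for (pm in mother) for (o in seq_len(K)) {
    if (identical(sort(c(pm, o)), sort(daughter))) return(TRUE)
  }
  FALSE
}
oracle_x_mfd <- function(mother, father, daughter) {
  for (pm in mother) {
    if (identical(sort(c(pm, father)), sort(daughter))) return(TRUE)
  }
  FALSE
}

# 2-means label recovery accuracy (best of the two label matchings).
kmeans_accuracy <- function(x, truth) {
  km <- stats::kmeans(x, centers = 2, nstart = 10)
  cl <- km$cluster
  t2 <- as.integer(factor(truth))
  max(mean(cl == t2), mean(3L - cl == t2))
}
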