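# small in-code fixtures shared across test files

# genotype matrix from a bare matrix with auto ids
gm_of <- function(calls) genotype_matrix(calls)

# popmap data frame for a genotype matrix, labels recycled over samples
popmap_of <- function(gm, labels) {
  data.frame(sample = gm$sample_ids,
             population = rep_len(labels, n_samples(gm)),
             stringsAsFactors = FALSE)
}

# a small literal VCF with the four GT states, one triallelic record and
# one indel record (both of which must be dropped on read)
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("ctg1", "10", ".", "A", "T", ".", "PASS", ".", "GT",
            "0/0", "0|1", "1/1", "./."), collapse = "\t"),
    paste(c("ctg1", "20", ".", "A", "T,G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "0/2", "1/2"), collapse = "\t"),
    paste(c("ctg1", "30", ".", "AT", "A", ".", "PASS", ".", "GT",
            "0/0", "0/1", "0/0", "0/0"), collapse = "\t"))
  writeLines(lines, path)
  path
}

# block distance matrix: within-cluster distance 0.01, between 0.2
two_cluster_dist <- function(sizes) {
  grp <- rep(seq_along(sizes), sizes)
  d <- ifelse(outer(grp, grp, "=="), 0.01, 0.2)
  diag(d) <- 0
  n <- length(grp)
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}

# adjusted Rand index between two labelings (independent of label names)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
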