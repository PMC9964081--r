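#' Read diploid genotypes from a VCF file
#'
#' Parses a VCF (v4.2) with GT fields into a [genotype_matrix()]. Only
#' biallelic SNP records are retained: multiallelic records and indels
#' are dropped (with a message reporting the count). Phased (`|`) and
#' unphased (`/`) separators are treated identically; `./.` becomes a
#' missing call. Locus ids are taken from the ID column when present,
#' otherwise `CHROM:POS`.
#'
#' @param path Path to a VCF file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0L) {
    stop("no variant records in VCF file: ", path)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  n_drop <- sum(!snp)
  if (n_drop > 0L) {
    message(sprintf("read_vcf: dropped %d multiallelic/non-SNP record(s)", n_drop))
  }
  if (!any(snp)) {
    stop("no biallelic SNP records in VCF file: ", path)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  ids <- fix[snp, "ID"]
  pos_ids <- paste(fix[snp, "CHROM"], fix[snp, "POS"], sep = ":")
  ids <- ifelse(is.na(ids) | ids == ".", pos_ids, ids)
  m <- nrow(gt)
  calls <- t(matrix(vapply(seq_len(ncol(gt)),
                           function(j) decode_gt(gt[, j]),
                           integer(m)),
                    nrow = m))  # samples x loci
  genotype_matrix(calls, sample_ids = colnames(gt),
                  locus_ids = make.unique(ids, sep = "_"))
}

# internal: "0/1", "0|1", "./." ... -> 0/1/2/NA alt-allele counts
decode_gt <- function(g) {
  g <- gsub("|", "/", g, fixed = TRUE)
  parts <- strsplit(g, "/", fixed = TRUE)
  vapply(parts, function(a) {
    if (length(a) != 2L || any(a == ".") || anyNA(a)) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
}

#' Write a genotype matrix to VCF v4.2
#'
#' Emits a minimal single-ALT VCF readable by [read_vcf()]. Genotype
#' codes do not track the actual alleles, so placeholder REF/ALT bases
#' (`A`/`T`) are written; the original locus id is preserved in the ID
#' column so that a write/read round trip is the identity.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- gm$locus_ids
  has_pos <- grepl("^[^:]+:[0-9]+$", ids)
  chrom <- ifelse(has_pos, sub(":[0-9]+$", "", ids), "ctg1")
  pos <- ifelse(has_pos, sub("^.*:", "", ids), as.character(seq_along(ids)))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L],
                   nrow = n_samples(gm))
  gt_str[is.na(gt_str)] <- "./."
  body <- cbind(chrom, pos, ids, "A", "T", ".", "PASS", ".", "GT",
                t(gt_str))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Expects a headerless two-column TSV: `sample<TAB>population`. Lines
#' starting with `#` are ignored. If `gm` is supplied, every sample in
#' the genotype matrix must appear in the map.
#'
#' @param path Path to the TSV file.
#' @param gm Optional [genotype_matrix()] to validate against.
#' @return A data frame with columns `sample` and `population`.
#' @export
read_popmap <- function(path, gm = NULL) {
  if (!file.exists(path)) stop("popmap file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("sample", "population"),
                           colClasses = "character", comment.char = "#")
  popmap <- validate_popmap(tab)
  if (!is.null(gm)) match_populations(gm, popmap)
  popmap
}

#' Read per-sample geographic coordinates
#'
#' Expects a headerless three-column TSV:
#' `sample<TAB>longitude<TAB>latitude` in decimal degrees.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `sample`, `longitude`, `latitude`.
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop("coordinates file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("sample", "longitude", "latitude"),
                           colClasses = c("character", "numeric", "numeric"),
                           comment.char = "#")
  validate_coords(tab)
}

#' Write a population map / coordinates table as TSV
#'
#' @param x Data frame as returned by [read_popmap()] or [read_coords()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
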