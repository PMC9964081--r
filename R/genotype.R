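#' Construct a genotype matrix
#'
#' The central data container: an `n_samples x n_loci` matrix of diploid
#' genotype codes, where each call counts copies of the alternate allele
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate)
#' and `NA` marks a missing call. Phase is discarded.
#'
#' @param calls Integer (or coercible) matrix, samples in rows, loci in
#'   columns. Values must be 0, 1, 2 or `NA`.
#' @param sample_ids Character vector of unique sample identifiers;
#'   defaults to `rownames(calls)`.
#' @param locus_ids Character vector of unique locus identifiers
#'   (conventionally `CHROM:POS`); defaults to `colnames(calls)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (integer matrix with dimnames), `sample_ids`, `locus_ids`.
#' @examples
#' gm <- genotype_matrix(rbind(s1 = c(0, 1), s2 = c(2, NA)),
#'                       locus_ids = c("ctg1:10", "ctg1:42"))
#' n_samples(gm); n_loci(gm)
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            locus_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(nrow(calls)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- paste0("locus", seq_len(ncol(calls)))
  }
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 1L || ncol(calls) < 1L) {
    stop("genotype matrix must have at least one sample and one locus")
  }
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) {
    stop("genotype calls must be 0, 1, 2 or NA; found: ",
         paste(unique(calls[bad]), collapse = ", "))
  }
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  if (length(sample_ids) != nrow(calls) || length(locus_ids) != ncol(calls)) {
    stop("id vectors must match matrix dimensions")
  }
  dimnames(calls) <- list(sample_ids, locus_ids)
  structure(list(calls = calls, sample_ids = sample_ids,
                 locus_ids = locus_ids),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param gm A `genotype_matrix`.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) ncol(gm$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing calls)\n",
              n_samples(x), n_loci(x), 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix by sample and/or locus
#'
#' @param gm A `genotype_matrix`.
#' @param samples Sample ids or indices to keep (default all).
#' @param loci Locus ids or indices to keep (default all).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(gm, samples = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  if (!is.null(loci)) calls <- calls[, loci, drop = FALSE]
  genotype_matrix(calls)
}

#' Filter loci by genotype presence
#'
#' Keeps exactly those loci whose fraction of non-missing calls is at
#' least `min_presence` (the threshold is inclusive: a locus typed in
#' 60% of samples passes `min_presence = 0.6`). Sample set and locus
#' order are unchanged.
#'
#' @param gm A `genotype_matrix`.
#' @param min_presence Fraction in (0, 1]: minimum share of samples with
#'   a non-missing call at a locus.
#' @return A `genotype_matrix` containing the retained loci.
#' @examples
#' gm <- genotype_matrix(rbind(c(0, NA), c(1, NA), c(2, 0), c(0, 0), c(1, NA)))
#' n_loci(filter_by_presence(gm, 0.6))  # second locus at 2/5 presence drops
#' @export
filter_by_presence <- function(gm, min_presence) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.numeric(min_presence) || length(min_presence) != 1L ||
      min_presence <= 0 || min_presence > 1) {
    stop("min_presence must be a single value in (0, 1]")
  }
  presence <- colMeans(!is.na(gm$calls))
  # small tolerance so exact boundary cases (e.g. 3/5 vs 0.6) are kept;
  # loci with no calls at all never pass
  keep <- presence >= min_presence - 1e-9 & presence > 0
  if (!any(keep)) {
    stop(sprintf("no locus passes the presence filter (min_presence = %g)",
                 min_presence))
  }
  subset_genotypes(gm, loci = which(keep))
}

# internal: validate a popmap against a genotype matrix, return the vector
# of population labels aligned to gm$sample_ids
match_populations <- function(gm, popmap) {
  stopifnot(inherits(gm, "genotype_matrix"))
  popmap <- validate_popmap(popmap)
  idx <- match(gm$sample_ids, popmap$sample)
  if (anyNA(idx)) {
    stop("samples missing from population map: ",
         paste(gm$sample_ids[is.na(idx)], collapse = ", "))
  }
  as.character(popmap$population[idx])
}

# internal: shared popmap structural checks
validate_popmap <- function(popmap) {
  if (!is.data.frame(popmap) ||
      !all(c("sample", "population") %in% names(popmap))) {
    stop("popmap must be a data frame with columns 'sample' and 'population'")
  }
  if (anyDuplicated(popmap$sample)) {
    stop("popmap assigns some sample more than one population: ",
         paste(unique(popmap$sample[duplicated(popmap$sample)]),
               collapse = ", "))
  }
  popmap
}

# internal: coordinate table checks
validate_coords <- function(coords) {
  if (!is.data.frame(coords) ||
      !all(c("sample", "longitude", "latitude") %in% names(coords))) {
    stop("coords must be a data frame with columns 'sample', 'longitude', 'latitude'")
  }
  if (any(abs(coords$latitude) > 90, na.rm = TRUE) ||
      any(abs(coords$longitude) > 180, na.rm = TRUE)) {
    stop("coordinates out of range: latitude in [-90,90], longitude in [-180,180]")
  }
  coords
}
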