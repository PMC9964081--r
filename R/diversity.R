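#' Observed heterozygosity per population
#'
#' For each population and locus, `H_O` is the fraction of heterozygous
#' calls among non-missing calls; the population value is the unweighted
#' mean over loci. Loci with zero non-missing calls in a population are
#' excluded from that population's mean; loci monomorphic within a
#' population contribute 0 (no re-filtering), keeping populations
#' comparable.
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Data frame with columns `sample`, `population` covering
#'   every sample in `gm`.
#' @return A list with `per_locus` (populations x loci matrix, `NA`
#'   where a population has no calls) and `mean` (named vector).
#' @export
observed_het <- function(gm, popmap) {
  pop_locus_stat(gm, popmap, function(x) {
    nn <- sum(!is.na(x))
    if (nn == 0L) return(NA_real_)
    sum(x == 1L, na.rm = TRUE) / nn
  })
}

#' Expected heterozygosity (gene diversity) per population
#'
#' Per locus, with `n_c` non-missing diploids and alternate-allele
#' frequency `q`, the small-sample-corrected gene diversity is
#' `H_E = (2*n_c / (2*n_c - 1)) * (1 - q^2 - (1-q)^2)` (Nei 1987);
#' the population value is the unweighted mean over loci.
#'
#' @inheritParams observed_het
#' @return A list with `per_locus` and `mean`, as [observed_het()].
#' @export
expected_het <- function(gm, popmap) {
  pop_locus_stat(gm, popmap, function(x) {
    nn <- sum(!is.na(x))
    if (nn == 0L) return(NA_real_)
    q <- sum(x, na.rm = TRUE) / (2 * nn)
    (1 - q^2 - (1 - q)^2) * 2 * nn / (2 * nn - 1)
  })
}

# internal: apply a per-locus statistic within each population
pop_locus_stat <- function(gm, popmap, fun) {
  pop <- match_populations(gm, popmap)
  pops <- unique(pop)
  per_locus <- matrix(NA_real_, length(pops), n_loci(gm),
                      dimnames = list(pops, gm$locus_ids))
  for (k in seq_along(pops)) {
    sub <- gm$calls[pop == pops[k], , drop = FALSE]
    per_locus[k, ] <- apply(sub, 2L, fun)
  }
  means <- rowMeans(per_locus, na.rm = TRUE)
  empty <- rowSums(!is.na(per_locus)) == 0L
  if (any(empty)) {
    stop("population(s) with no callable loci: ",
         paste(pops[empty], collapse = ", "))
  }
  list(per_locus = per_locus, mean = means)
}

#' Within-population inbreeding coefficient
#'
#' `F_IS = 1 - mean(H_O) / mean(H_E)` as a ratio of locus averages
#' (robust to low-diversity loci). Undefined (`NA`) where the mean
#' expected heterozygosity is zero; never reported as 0 in that case.
#'
#' @param ho,he Objects returned by [observed_het()] and
#'   [expected_het()] (or their `mean` vectors) over the same
#'   populations.
#' @return Named per-population vector of `F_IS`.
#' @export
inbreeding_fis <- function(ho, he) {
  ho <- if (is.list(ho)) ho$mean else ho
  he <- if (is.list(he)) he$mean else he
  stopifnot(length(ho) == length(he))
  fis <- ifelse(he > 0, 1 - ho / he, NA_real_)
  names(fis) <- names(he)
  fis
}

#' Heterozygosity deficit
#'
#' `delta_H = H_E - H_O`, the excess of expected over observed
#' heterozygosity; large positive values flag inbreeding or clonal
#' substructure.
#'
#' @inheritParams inbreeding_fis
#' @return Named per-population vector.
#' @export
delta_h <- function(he, ho) {
  ho <- if (is.list(ho)) ho$mean else ho
  he <- if (is.list(he)) he$mean else he
  stopifnot(length(ho) == length(he))
  he - ho
}

#' Per-population diversity table
#'
#' One row per population: sample count `N`, mean expected (`H_E`) and
#' observed (`H_O`) heterozygosity, inbreeding coefficient `F_IS`, and
#' heterozygosity deficit `delta_H = H_E - H_O`.
#'
#' @inheritParams observed_het
#' @return A data frame with columns `population`, `N`, `H_E`, `H_O`,
#'   `F_IS`, `delta_H`.
#' @examples
#' sim <- simulate_clonal_snps(sim_config(n_pops = 2, n_loci = 200,
#'                                        fis = 0, seed = 1))
#' diversity_table(sim$genotypes, sim$popmap)
#' @export
diversity_table <- function(gm, popmap) {
  pop <- match_populations(gm, popmap)
  ho <- observed_het(gm, popmap)
  he <- expected_het(gm, popmap)
  pops <- names(he$mean)
  data.frame(population = pops,
             N = as.integer(table(pop)[pops]),
             H_E = unname(he$mean),
             H_O = unname(ho$mean),
             F_IS = unname(inbreeding_fis(ho, he)),
             delta_H = unname(delta_h(he, ho)),
             stringsAsFactors = FALSE)
}
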