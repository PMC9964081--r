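#' Configuration for the clonal SNP simulator
#'
#' Defaults emulate the sampling regime of a range-wide ddRAD survey of
#' a rhizomatous clonal plant: a dozen populations of roughly 10-35
#' stems each, thousands of biallelic loci with substantial missingness,
#' moderate population divergence, within-population inbreeding, and
#' clonal groups (genets) whose sampled stems (ramets) differ only by
#' genotyping error.
#'
#' @param n_pops Number of populations.
#' @param n_loci Number of biallelic loci.
#' @param fst Target between-population divergence theta in [0, 1);
#'   population allele frequencies follow the Balding-Nichols model
#'   `Beta(p(1-theta)/theta, (1-p)(1-theta)/theta)` around ancestral
#'   frequencies `p ~ Uniform(0.05, 0.95)`. `fst = 0` gives panmixia.
#' @param fis Within-population inbreeding coefficient in [-1, 1];
#'   genet genotypes are drawn with heterozygote probability
#'   `2*p*q*(1 - fis)`.
#' @param genets_per_pop Number of genets sampled per population
#'   (recycled across populations).
#' @param ramet_lambda When `ramet_counts` is not given, each genet
#'   contributes `1 + rpois(lambda)` ramets (stems).
#' @param ramet_counts Optional list (one element per population) of
#'   integer vectors giving the exact ramet count of every genet;
#'   overrides `genets_per_pop`/`ramet_lambda`.
#' @param error_rate Per-allele genotyping error: each of the two
#'   alleles of every emitted call flips (ref <-> alt) independently
#'   with this probability.
#' @param missing_rate Per-call missingness: each emitted call is masked
#'   to `NA` independently with this probability.
#' @param layout Spatial arrangement of ramets within a population:
#'   `"guerrilla"` scatters every ramet uniformly over the population
#'   extent so genets intermix; `"phalanx"` clusters each genet's ramets
#'   (Gaussian, sd `phalanx_sd` degrees) around a genet center.
#' @param pop_extent Side (degrees) of the square patch holding one
#'   population's samples.
#' @param phalanx_sd Gaussian scatter (degrees) of ramets around their
#'   genet center under the phalanx layout.
#' @param seed RNG seed; fixing it makes the output fully reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 12, n_loci = 5000, fst = 0.10, fis = 0.15,
                       genets_per_pop = 8, ramet_lambda = 0.7,
                       ramet_counts = NULL, error_rate = 0.005,
                       missing_rate = 0.2,
                       layout = c("guerrilla", "phalanx"),
                       pop_extent = 0.002, phalanx_sd = 1e-4,
                       seed = NULL) {
  layout <- match.arg(layout)
  stopifnot(n_pops >= 1, n_loci >= 1,
            fst >= 0, fst < 1,
            fis >= -1, fis <= 1,
            error_rate >= 0, error_rate < 0.5,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(ramet_counts)) {
    stopifnot(is.list(ramet_counts), length(ramet_counts) == n_pops,
              all(unlist(ramet_counts) >= 1))
  }
  structure(list(n_pops = n_pops, n_loci = n_loci, fst = fst, fis = fis,
                 genets_per_pop = genets_per_pop,
                 ramet_lambda = ramet_lambda, ramet_counts = ramet_counts,
                 error_rate = error_rate, missing_rate = missing_rate,
                 layout = layout, pop_extent = pop_extent,
                 phalanx_sd = phalanx_sd, seed = seed),
            class = "sim_config")
}

#' Simulate a structured, inbred, clonal SNP dataset with known truth
#'
#' Generates genotypes under a Balding-Nichols population model with
#' within-population inbreeding and clonal replication: each genet's
#' multilocus genotype is drawn once from its population's allele
#' frequencies, and every ramet copies that genotype before per-allele
#' genotyping error and per-call missingness are applied. Sample
#' coordinates follow the configured clonal growth architecture.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` ([genotype_matrix()]),
#'   `popmap`, `coords` (data frames as read by [read_popmap()] /
#'   [read_coords()]), and `truth`, a list holding `ancestral_freqs`,
#'   `pop_freqs` (pops x loci), `genet_of` (named vector, sample ->
#'   genet label), `genet_genotypes` (genets x loci, pre-error), and
#'   the generating `config`.
#' @examples
#' sim <- simulate_clonal_snps(sim_config(n_pops = 2, n_loci = 100, seed = 1))
#' sim$genotypes
#' @export
simulate_clonal_snps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- config$n_loci
  theta <- config$fst

  p_anc <- stats::runif(m, 0.05, 0.95)
  pop_freqs <- matrix(NA_real_, config$n_pops, m)
  for (k in seq_len(config$n_pops)) {
    if (theta > 0) {
      pop_freqs[k, ] <- stats::rbeta(m, p_anc * (1 - theta) / theta,
                                     (1 - p_anc) * (1 - theta) / theta)
    } else {
      pop_freqs[k, ] <- p_anc
    }
  }

  # ramet layout per population
  ramets <- config$ramet_counts
  if (is.null(ramets)) {
    ramets <- lapply(seq_len(config$n_pops), function(k) {
      1L + stats::rpois(config$genets_per_pop, config$ramet_lambda)
    })
  }

  pops <- sprintf("pop%02d", seq_len(config$n_pops))
  # population centers spaced along a transect (degrees)
  ctr_lon <- -85.3 + 0.05 * seq_len(config$n_pops)
  ctr_lat <- 30.0 + 0.01 * ((seq_len(config$n_pops) - 1L) %% 3L)

  rows <- list(); sample_pop <- character(0); genet_of <- character(0)
  lon <- numeric(0); lat <- numeric(0)
  genet_rows <- list(); genet_labels <- character(0)

  for (k in seq_len(config$n_pops)) {
    q <- pop_freqs[k, ]  # alt-allele frequency
    n_gen <- length(ramets[[k]])
    # genet genotypes with inbreeding: P(het) = 2pq(1-F), homozygotes
    # split in proportion to q^2 + Fpq and p^2 + Fpq
    p_het <- 2 * q * (1 - q) * (1 - config$fis)
    p_aa <- q^2 + config$fis * q * (1 - q)
    gg <- matrix(NA_integer_, n_gen, m)
    for (g in seq_len(n_gen)) {
      u <- stats::runif(m)
      gg[g, ] <- ifelse(u < p_aa, 2L, ifelse(u < p_aa + p_het, 1L, 0L))
    }
    glab <- sprintf("%s_g%02d", pops[k], seq_len(n_gen))
    genet_rows[[k]] <- gg
    genet_labels <- c(genet_labels, glab)

    # genet centers for the phalanx layout
    gx <- stats::runif(n_gen, -0.5, 0.5) * config$pop_extent + ctr_lon[k]
    gy <- stats::runif(n_gen, -0.5, 0.5) * config$pop_extent + ctr_lat[k]

    for (g in seq_len(n_gen)) {
      for (r in seq_len(ramets[[k]][g])) {
        rows[[length(rows) + 1L]] <- gg[g, ]
        sample_pop <- c(sample_pop, pops[k])
        genet_of <- c(genet_of, glab[g])
        if (config$layout == "guerrilla") {
          lon <- c(lon, ctr_lon[k] + stats::runif(1, -0.5, 0.5) * config$pop_extent)
          lat <- c(lat, ctr_lat[k] + stats::runif(1, -0.5, 0.5) * config$pop_extent)
        } else {
          lon <- c(lon, stats::rnorm(1, gx[g], config$phalanx_sd))
          lat <- c(lat, stats::rnorm(1, gy[g], config$phalanx_sd))
        }
      }
    }
  }

  calls <- do.call(rbind, rows)
  n <- nrow(calls)

  # per-allele genotyping error: flip each of the two alleles with prob eps
  if (config$error_rate > 0) {
    flips <- matrix(stats::rbinom(2L * n * m, 1L, config$error_rate),
                    nrow = n)
    f1 <- flips[, seq_len(m), drop = FALSE]
    f2 <- flips[, m + seq_len(m), drop = FALSE]
    a1 <- as.integer(calls >= 1L)  # allele 1 carries alt iff call >= 1
    a2 <- as.integer(calls == 2L)
    calls <- matrix((a1 + f1) %% 2L + (a2 + f2) %% 2L, nrow = n)
  }
  if (config$missing_rate > 0) {
    calls[matrix(stats::runif(n * m) < config$missing_rate, nrow = n)] <- NA_integer_
  }

  sample_ids <- sprintf("s%03d", seq_len(n))
  locus_ids <- paste0("ctg1:", seq_len(m))
  gm <- genotype_matrix(calls, sample_ids = sample_ids, locus_ids = locus_ids)
  names(genet_of) <- sample_ids

  truth <- list(ancestral_freqs = p_anc,
                pop_freqs = structure(pop_freqs,
                                      dimnames = list(pops, locus_ids)),
                genet_of = genet_of,
                genet_genotypes = structure(do.call(rbind, genet_rows),
                                            dimnames = list(genet_labels,
                                                            locus_ids)),
                config = config)
  list(genotypes = gm,
       popmap = data.frame(sample = sample_ids, population = sample_pop,
                           stringsAsFactors = FALSE),
       coords = data.frame(sample = sample_ids, longitude = lon,
                           latitude = lat, stringsAsFactors = FALSE),
       truth = truth)
}

#' Closed-form expectations for a simulated dataset
#'
#' Analytic per-population expectations derived from the generating
#' allele frequencies, for comparison with downstream estimates:
#' `H_E = mean(2*q*(1-q))`, `H_O = H_E * (1 - F_IS)`, plus the
#' generating `fis` and `fst`.
#'
#' @param truth The `truth` element returned by [simulate_clonal_snps()].
#' @return A list with `h_e` and `h_o` (named per-population vectors),
#'   `fis`, and `fst`.
#' @export
expected_summaries <- function(truth) {
  q <- truth$pop_freqs
  h_e <- rowMeans(2 * q * (1 - q))
  list(h_e = h_e,
       h_o = h_e * (1 - truth$config$fis),
       fis = truth$config$fis,
       fst = truth$config$fst)
}
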