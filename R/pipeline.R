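#' Configuration for the end-to-end analysis pipeline
#'
#' @param vcf Path to the input VCF.
#' @param popmap Path to the sample-to-population TSV.
#' @param coords Optional path to the per-sample coordinates TSV; when
#'   `NULL` or missing, the Mantel test and clone maps are skipped.
#' @param out_dir Output directory (created if needed).
#' @param min_presence Locus presence filter threshold (default 0.6).
#' @param k_range Candidate cluster counts for ancestry K selection.
#' @param n_perm Mantel permutations (default 9999).
#' @param seed Master RNG seed for every stochastic stage.
#' @param clone_threshold Optional fixed clone-delimitation threshold
#'   overriding histogram gap detection.
#' @param max_missing Per-sample missingness cap for the clonality stage
#'   (default 0.25).
#' @param dominance,minor Unique-ancestry thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, popmap, coords = NULL, out_dir,
                            min_presence = 0.6, k_range = 1:10,
                            n_perm = 9999, seed = 1,
                            clone_threshold = NULL, max_missing = 0.25,
                            dominance = 0.5, minor = 0.2) {
  structure(list(vcf = vcf, popmap = popmap, coords = coords,
                 out_dir = out_dir, min_presence = min_presence,
                 k_range = k_range, n_perm = n_perm, seed = seed,
                 clone_threshold = clone_threshold,
                 max_missing = max_missing, dominance = dominance,
                 minor = minor),
            class = "pipeline_config")
}

#' Run the full population-genomic and clonality pipeline
#'
#' Chains every stage: locus presence filtering, per-population
#' diversity, pairwise F_ST (with Mantel isolation-by-distance when
#' coordinates are available), ancestry estimation with K selection,
#' DAPC, clone delimitation with clonal-richness summaries, and the
#' conservation genetic-value assessment. Writes one TSV per table, a
#' machine-readable `report.json`, and the resolved configuration to
#' `out_dir`. The run is a pure function of (inputs, config, seed).
#'
#' @param config A [pipeline_config()].
#' @return The report (named list), invisibly; also serialized to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  report <- list(config = unclass(config), skipped = character(0))

  gm <- stage("input", read_vcf(config$vcf))
  popmap <- stage("input", read_popmap(config$popmap, gm))
  coords <- NULL
  if (!is.null(config$coords) && file.exists(config$coords)) {
    coords <- stage("input", read_coords(config$coords))
  } else if (!is.null(config$coords)) {
    report$skipped <- c(report$skipped,
                        "coordinates file missing: Mantel test and clone maps skipped")
  } else {
    report$skipped <- c(report$skipped,
                        "no coordinates supplied: Mantel test and clone maps skipped")
  }

  gm <- stage("filter", filter_by_presence(gm, config$min_presence))
  report$n_samples <- n_samples(gm)
  report$n_loci <- n_loci(gm)

  div <- stage("diversity", diversity_table(gm, popmap))
  fst <- stage("divergence", pairwise_fst(gm, popmap))
  mantel <- NULL
  if (!is.null(coords)) {
    km <- stage("divergence", geo_distance(coords, popmap))
    km <- km[fst$populations, fst$populations]
    mantel <- stage("divergence",
                    mantel_test(fst$theta, km, n_perm = config$n_perm,
                                seed = config$seed))
  }

  ks <- stage("structure",
              select_k(gm, config$k_range, seed = config$seed))
  anc <- stage("structure",
               estimate_ancestry(gm, ks$best_k, seed = config$seed))
  n_pops <- length(unique(popmap$population))
  cand <- unique(pmin(c(5L, 10L, 20L, 40L), n_samples(gm) - n_pops - 1L))
  cand <- cand[cand >= 1L]
  cv <- stage("structure",
              crossvalidate_pcs(gm, popmap, cand, n_rep = 10,
                                seed = config$seed))
  dapc <- stage("structure",
                dapc_fit(gm, popmap, n_pcs = cv$optimal_n_pcs))

  clones <- stage("clonality",
                  population_clonality(gm, popmap,
                                       threshold = config$clone_threshold,
                                       max_missing = config$max_missing))
  maps <- NULL
  if (!is.null(coords)) {
    maps <- stage("clonality",
                  lapply(clones$assignments, clonal_map, coords = coords))
  }

  assessment <- stage("valuation",
                      assess_populations(div, fst, anc, popmap,
                                         dominance = config$dominance,
                                         minor = config$minor))

  report$diversity <- div
  report$fst <- fst$theta
  report$mantel <- if (is.null(mantel)) NULL else unclass(mantel)
  report$best_k <- ks$best_k
  report$cross_entropy <- ks$cross_entropy[, c("K", "mean_ce")]
  report$optimal_n_pcs <- cv$optimal_n_pcs
  report$dapc_axis_variance <- dapc$axis_variance
  report$clonality <- clones$summary
  report$intermixing <- if (is.null(maps)) NULL else
    vapply(maps, function(m) attr(m, "intermixing"), numeric(1))
  report$assessment <- assessment

  # outputs: one TSV per table + machine-readable JSON
  wt <- function(x, f) utils::write.table(
    x, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(div, "diversity.tsv")
  utils::write.table(fst$theta, file.path(config$out_dir, "fst.tsv"),
                     sep = "\t", quote = FALSE)
  wt(data.frame(sample = rownames(anc$Q), round(anc$Q, 6)), "Q.tsv")
  wt(clones$summary, "clonality.tsv")
  wt(assessment, "assessment.tsv")
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
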