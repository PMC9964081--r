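#' Bin a population's mean pairwise divergence into a qualitative level
#'
#' The population's divergence level is the mean of its pairwise
#' Weir-Cockerham theta against all other populations, binned as:
#' `< 0.05` Low, `[0.05, 0.15)` Moderate, `[0.15, 0.20)` High,
#' `>= 0.20` Very High. The bins are total and disjoint over \[0, 1\]
#' (negative means fall in Low).
#'
#' @param fst An `fst_matrix` from [pairwise_fst()] (or bare symmetric
#'   matrix with population dimnames).
#' @param population Population label; default `NULL` returns the level
#'   for every population.
#' @return Character level(s) in
#'   `c("Low", "Moderate", "High", "Very High")`.
#' @export
derive_divergence_level <- function(fst, population = NULL) {
  theta <- if (inherits(fst, "fst_matrix")) fst$theta else as.matrix(fst)
  if (nrow(theta) < 2L) stop("divergence level needs at least two populations")
  pops <- rownames(theta)
  mean_theta <- vapply(seq_len(nrow(theta)),
                       function(i) mean(theta[i, -i]), numeric(1))
  lev <- divergence_bin(mean_theta)
  names(lev) <- pops
  if (is.null(population)) lev else {
    if (!population %in% pops) stop("unknown population: ", population)
    lev[[population]]
  }
}

#' @rdname derive_divergence_level
#' @param mean_theta Numeric mean pairwise theta value(s) to bin
#'   directly.
#' @export
divergence_bin <- function(mean_theta) {
  cut(mean_theta, breaks = c(-Inf, 0.05, 0.15, 0.20, Inf), right = FALSE,
      labels = c("Low", "Moderate", "High", "Very High")) |>
    as.character()
}

#' Flag populations carrying unique ancestry
#'
#' A population shows unique ancestry when some ancestral cluster is
#' both dominant there (mean membership at least `dominance`) and
#' essentially absent everywhere else (mean membership below `minor` in
#' every other population) -- a numeric stand-in for judging private
#' ancestry blocks on a barplot.
#'
#' @param ancestry An `ancestry_result` from [estimate_ancestry()] (or
#'   bare Q matrix with sample rownames).
#' @param popmap Data frame with columns `sample`, `population`.
#' @param dominance Dominant mean-membership threshold (default 0.5).
#' @param minor Maximum mean membership allowed in other populations
#'   (default 0.2).
#' @return Named logical-as-character vector (`"Yes"`/`"No"`) per
#'   population.
#' @export
derive_unique_ancestry <- function(ancestry, popmap, dominance = 0.5,
                                   minor = 0.2) {
  Q <- if (inherits(ancestry, "ancestry_result")) ancestry$Q else as.matrix(ancestry)
  popmap <- validate_popmap(popmap)
  idx <- match(rownames(Q), popmap$sample)
  if (anyNA(idx)) {
    stop("Q samples missing from popmap: ",
         paste(rownames(Q)[is.na(idx)], collapse = ", "))
  }
  pop <- popmap$population[idx]
  pops <- unique(pop)
  mean_q <- t(vapply(pops, function(p) colMeans(Q[pop == p, , drop = FALSE]),
                     numeric(ncol(Q))))  # pops x K
  out <- vapply(seq_along(pops), function(i) {
    others <- mean_q[-i, , drop = FALSE]
    private <- mean_q[i, ] >= dominance &
      apply(others < minor, 2L, all)
    if (any(private)) "Yes" else "No"
  }, character(1))
  stats::setNames(out, pops)
}

#' Conservation genetic-value classification
#'
#' Rule-based reconstruction of a qualitative conservation rubric that
#' weighs observed heterozygosity, inbreeding, divergence, and unique
#' ancestry: populations lacking unique ancestry are Low value;
#' populations with unique ancestry, High or Very High divergence, and
#' `F_IS < 0.05` are High value; every other population is Moderate.
#' Observed heterozygosity is carried along for reporting but does not
#' gate the decision (the rubric is fully determined without it).
#'
#' @param h_o Observed heterozygosity (reported, not used by the rule).
#' @param fis Inbreeding coefficient.
#' @param divergence_level One of `"Low"`, `"Moderate"`, `"High"`,
#'   `"Very High"`.
#' @param unique_ancestry `"Yes"`/`"No"` (or logical).
#' @return Character vector in `c("Low", "Moderate", "High")`.
#' @examples
#' classify_genetic_value(0.127, 0.024, "Very High", "Yes")  # "High"
#' classify_genetic_value(0.04, 0.555, "Moderate", "No")     # "Low"
#' @export
classify_genetic_value <- function(h_o, fis, divergence_level,
                                   unique_ancestry) {
  lev <- as.character(divergence_level)
  ok <- lev %in% c("Low", "Moderate", "High", "Very High")
  if (any(!ok)) stop("unknown divergence level: ",
                     paste(unique(lev[!ok]), collapse = ", "))
  ua <- if (is.logical(unique_ancestry)) unique_ancestry else {
    uav <- as.character(unique_ancestry)
    bad <- !uav %in% c("Yes", "No")
    if (any(bad)) stop("unknown unique-ancestry label: ",
                       paste(unique(uav[bad]), collapse = ", "))
    uav == "Yes"
  }
  n <- max(length(h_o), length(fis), length(lev), length(ua))
  fis <- rep_len(fis, n); lev <- rep_len(lev, n); ua <- rep_len(ua, n)
  ifelse(!ua, "Low",
         ifelse(lev %in% c("High", "Very High") & fis < 0.05,
                "High", "Moderate"))
}

#' Assemble per-population conservation assessments
#'
#' Joins the diversity table, pairwise F_ST, and ancestry result into
#' one assessment row per population (H_O, F_IS, divergence level,
#' unique ancestry, genetic value).
#'
#' @param div Data frame from [diversity_table()].
#' @param fst An `fst_matrix` from [pairwise_fst()].
#' @param ancestry An `ancestry_result` (or Q matrix), passed to
#'   [derive_unique_ancestry()].
#' @param popmap Data frame with columns `sample`, `population`.
#' @param dominance,minor Unique-ancestry thresholds, see
#'   [derive_unique_ancestry()].
#' @return A data frame with columns `population`, `H_O`, `F_IS`,
#'   `divergence_level`, `unique_ancestry`, `genetic_value`.
#' @export
assess_populations <- function(div, fst, ancestry, popmap,
                               dominance = 0.5, minor = 0.2) {
  lev <- derive_divergence_level(fst)
  ua <- derive_unique_ancestry(ancestry, popmap, dominance, minor)
  pops <- div$population
  data.frame(population = pops,
             H_O = div$H_O,
             F_IS = div$F_IS,
             divergence_level = unname(lev[pops]),
             unique_ancestry = unname(ua[pops]),
             genetic_value = classify_genetic_value(div$H_O, div$F_IS,
                                                    lev[pops], ua[pops]),
             stringsAsFactors = FALSE)
}
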