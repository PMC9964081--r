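#' Pairwise Prevosti genetic distance between samples
#'
#' `d(i, j) = sum(|g_i - g_j|) / (2 * L_ij)` over the `L_ij` loci where
#' both samples have non-missing calls (absolute allele-count
#' difference). Identical genotypes give 0; opposite homozygotes give 1
#' per locus. Computed with matrix products, so it scales to thousands
#' of loci.
#'
#' @param gm A [genotype_matrix()] with at least 2 samples.
#' @return A list of class `genetic_dist` with `sample_ids`, `d`
#'   (symmetric matrix in \[0, 1\], zero diagonal) and `comparable_loci`
#'   (per-pair count of mutually non-missing loci).
#' @examples
#' gm <- genotype_matrix(rbind(a = c(0, 1, NA), b = c(0, 2, 2)))
#' genetic_distance(gm)$d["a", "b"]  # (0 + 1) / (2 * 2) = 0.25
#' @export
genetic_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_samples(gm) < 2L) stop("need at least 2 samples")
  g <- gm$calls
  w <- !is.na(g)                       # observed indicator
  g0 <- g; g0[!w] <- 0L
  mode(g0) <- "double"; mode(w) <- "double"
  # sum over both-observed loci of |a - b|, using
  # |a - b| = a + b - 2*min(a, b) and min(a, b) = 1[a>=1]1[b>=1] + 1[a>=2]1[b>=2]
  s_a <- (g0 * w) %*% t(w)             # sum of a over both-observed
  a1 <- (g0 >= 1) * w
  a2 <- (g0 >= 2) * w
  num <- s_a + t(s_a) - 2 * (a1 %*% t(a1) + a2 %*% t(a2))
  comp <- w %*% t(w)
  off <- row(comp) != col(comp)
  if (any(comp[off] == 0)) {
    bad <- which(comp == 0 & off, arr.ind = TRUE)[1L, ]
    stop(sprintf("samples %s and %s share no called locus",
                 gm$sample_ids[bad[1L]], gm$sample_ids[bad[2L]]))
  }
  d <- num / (2 * pmax(comp, 1))
  diag(d) <- 0
  dimnames(d) <- dimnames(comp) <- list(gm$sample_ids, gm$sample_ids)
  structure(list(sample_ids = gm$sample_ids, d = d,
                 comparable_loci = comp),
            class = "genetic_dist")
}

#' Detect a clone-delimitation threshold from the distance histogram
#'
#' Implements the histogram-gap rule used to separate within-genet
#' (genotyping error) from between-genet distances: sort the unique
#' off-diagonal distances below `search_ceiling`, find the largest gap
#' between consecutive values, and place the threshold at its midpoint
#' when the gap is at least `bin_width` and values exist on both sides.
#' Returns `NULL` ("no gap") when no such gap exists or when the
#' smallest pairwise distance already exceeds `min_floor` (all samples
#' then look genetically unique).
#'
#' @param dist A `genetic_dist` (or bare symmetric matrix).
#' @param bin_width Minimum gap size to accept (default 0.005).
#' @param search_ceiling Only distances below this value are examined
#'   (default 0.10); clone thresholds live in the low tail.
#' @param min_floor If the minimum pairwise distance is at least this
#'   (default 0.04), no clones are assumed and `NULL` is returned.
#' @return The threshold `d_star` (numeric) or `NULL` when no gap
#'   qualifies.
#' @export
detect_threshold <- function(dist, bin_width = 0.005, search_ceiling = 0.10,
                             min_floor = 0.04) {
  d <- if (inherits(dist, "genetic_dist")) dist$d else as.matrix(dist)
  vals <- d[upper.tri(d)]
  if (length(vals) < 1L) stop("need at least one off-diagonal pair")
  if (min(vals) >= min_floor) return(NULL)
  u <- sort(unique(vals[vals < search_ceiling]))
  if (length(u) < 2L) return(NULL)
  gaps <- diff(u)
  k <- which.max(gaps)
  if (gaps[k] < bin_width) return(NULL)
  (u[k] + u[k + 1L]) / 2
}

#' UPGMA tree from a genetic distance matrix
#'
#' Average-linkage agglomerative clustering; node height equals the
#' linkage distance, producing a rooted ultrametric dendrogram on which
#' clones appear as subtrees below the delimitation threshold.
#'
#' @param dist A `genetic_dist` (or bare symmetric matrix).
#' @return An object of class `hclust` (convert with `ape::as.phylo()`
#'   if a phylogeny object is needed).
#' @export
upgma <- function(dist) {
  d <- if (inherits(dist, "genetic_dist")) dist$d else as.matrix(dist)
  tr <- stats::hclust(stats::as.dist(d), method = "average")
  # average linkage is monotone, but tied merges can drift below the
  # previous height by ~1e-17; snap so cutree accepts the tree
  tr$height <- round(tr$height, 12)
  tr$height <- cummax(tr$height)
  tr
}

#' Assign samples to clones by cutting the UPGMA tree
#'
#' Cuts the dendrogram at height `d_star`: each resulting subtree's
#' leaves form one genet (clone). With `d_star = NULL` (no histogram
#' gap), every sample is its own genet. Reports the genet count `G`,
#' ramet counts, and clonal richness `CR = (G - 1) / (N - 1)`
#' (`CR = 1` by convention for a single sample).
#'
#' @param tree An `hclust` from [upgma()].
#' @param d_star Threshold height, or `NULL` for "no gap".
#' @return A list of class `clone_assignment` with `genet_of` (named
#'   vector, sample -> genet label), `d_star`, `G`, `N`,
#'   `ramets_per_genet` (named integer vector) and `CR`.
#' @export
assign_clones <- function(tree, d_star = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (is.null(d_star)) {
    grp <- stats::setNames(seq_len(n), tree$labels)
  } else {
    grp <- stats::cutree(tree, h = d_star)
  }
  new_clone_assignment(grp, d_star)
}

# internal: package integer group labels into a clone_assignment
new_clone_assignment <- function(grp, d_star) {
  n <- length(grp)
  labels <- sprintf("genet%02d", grp)
  genet_of <- stats::setNames(labels, names(grp))
  ramets <- table(labels)
  g <- length(ramets)
  cr <- if (n >= 2L) (g - 1) / (n - 1) else 1
  structure(list(genet_of = genet_of, d_star = d_star, G = g, N = n,
                 ramets_per_genet = stats::setNames(as.integer(ramets),
                                                    names(ramets)),
                 CR = cr),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  thr <- if (is.null(x$d_star)) "none (no gap)" else format(x$d_star)
  cat(sprintf("clone assignment: N = %d, G = %d genets, CR = %.3f, threshold = %s\n",
              x$N, x$G, x$CR, thr))
  invisible(x)
}

#' Clonal richness
#'
#' `CR = (G - 1) / (N - 1)` for `G` distinct multilocus genotypes among
#' `N` samples: 0 for a monoclonal stand, 1 when every sample is unique.
#'
#' @param g Number of distinct genotypes (genets).
#' @param n Number of samples analyzed.
#' @return Clonal richness in \[0, 1\] (1 by convention when `n = 1`).
#' @export
clonal_richness <- function(g, n) {
  stopifnot(all(g >= 1), all(n >= g))
  ifelse(n >= 2, (g - 1) / (n - 1), 1)
}

#' Per-population clone delimitation
#'
#' Runs the full delimitation procedure independently within each
#' population: drop samples exceeding the per-sample missingness cap,
#' compute Prevosti distances, find (or accept) a threshold, cut the
#' UPGMA tree, and summarize. A fixed `threshold` overrides histogram
#' gap detection (useful to reproduce manually chosen cutoffs).
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Data frame with columns `sample`, `population`.
#' @param threshold Optional fixed threshold applied to every
#'   population; default `NULL` runs [detect_threshold()] per
#'   population.
#' @param max_missing Per-sample missingness cap (default 0.25; the
#'   delimitation is sensitive to missing data). Samples above the cap
#'   are excluded with a message.
#' @param ... Passed to [detect_threshold()].
#' @return A list with `assignments` (named list of `clone_assignment`
#'   per population) and `summary` (data frame: `population`, `N`,
#'   `threshold`, `G`, `ramets`, `CR`).
#' @export
population_clonality <- function(gm, popmap, threshold = NULL,
                                 max_missing = 0.25, ...) {
  pop <- match_populations(gm, popmap)
  pops <- unique(pop)
  miss <- rowMeans(is.na(gm$calls))
  assignments <- list()
  rows <- list()
  for (p in pops) {
    keep <- pop == p & miss <= max_missing
    n_drop <- sum(pop == p) - sum(keep)
    if (n_drop > 0L) {
      message(sprintf("population %s: excluded %d sample(s) above %.0f%% missingness",
                      p, n_drop, 100 * max_missing))
    }
    if (sum(keep) == 0L) {
      warning("population ", p, " has no sample under the missingness cap; skipped")
      next
    }
    sub <- subset_genotypes(gm, samples = which(keep))
    if (n_samples(sub) == 1L) {
      asg <- new_clone_assignment(stats::setNames(1L, sub$sample_ids), threshold)
    } else {
      dd <- genetic_distance(sub)
      thr <- if (is.null(threshold)) detect_threshold(dd, ...) else threshold
      asg <- assign_clones(upgma(dd), thr)
    }
    assignments[[p]] <- asg
    rows[[p]] <- data.frame(
      population = p, N = asg$N,
      threshold = if (is.null(asg$d_star)) NA_real_ else asg$d_star,
      G = asg$G,
      ramets = paste(sort(asg$ramets_per_genet, decreasing = TRUE),
                     collapse = ","),
      CR = asg$CR, stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(assignments = assignments, summary = summary)
}

#' Plot-ready spatial clone map with intermixing index
#'
#' Joins a clone assignment with sample coordinates into a table of
#' plot records (x = longitude, y = latitude, symbol = genet) and
#' computes an intermixing index: the fraction of samples whose nearest
#' spatial neighbour belongs to a different genet. Intermixed
#' (guerrilla) stands score high; clumped (phalanx) stands score low.
#'
#' @param assignment A `clone_assignment`.
#' @param coords Data frame with columns `sample`, `longitude`,
#'   `latitude`. Samples without coordinates are omitted with a warning.
#' @return A data frame (`sample`, `longitude`, `latitude`, `genet`)
#'   with the intermixing index in `attr(, "intermixing")`.
#' @export
clonal_map <- function(assignment, coords) {
  stopifnot(inherits(assignment, "clone_assignment"))
  coords <- validate_coords(coords)
  ids <- names(assignment$genet_of)
  idx <- match(ids, coords$sample)
  if (anyNA(idx)) {
    warning("samples without coordinates omitted from map: ",
            paste(ids[is.na(idx)], collapse = ", "))
  }
  ok <- !is.na(idx)
  out <- data.frame(sample = ids[ok],
                    longitude = coords$longitude[idx[ok]],
                    latitude = coords$latitude[idx[ok]],
                    genet = unname(assignment$genet_of[ok]),
                    stringsAsFactors = FALSE)
  attr(out, "intermixing") <- intermixing_index(out)
  out
}

#' Intermixing index of a clone map
#'
#' Fraction of samples whose nearest spatial neighbour (Euclidean on
#' the coordinate plane) belongs to a different genet.
#'
#' @param map Data frame with columns `longitude`, `latitude`, `genet`.
#' @return A value in \[0, 1\].
#' @export
intermixing_index <- function(map) {
  n <- nrow(map)
  if (n < 2L) return(NA_real_)
  xy <- cbind(map$longitude, map$latitude)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  nn <- apply(d, 1L, which.min)
  mean(map$genet[nn] != map$genet)
}
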