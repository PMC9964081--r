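#' Pairwise Weir-Cockerham F_ST between populations
#'
#' For every pair of populations, theta is estimated per locus from the
#' two populations' allele counts and observed heterozygote counts using
#' the Weir & Cockerham (1984) variance components, and combined over
#' loci as the ratio of sums `sum(a) / sum(a + b + c)`. Loci where
#' either population has fewer than two non-missing diploids, or where
#' all variance components vanish (uninformative in both populations),
#' are skipped for that pair. Negative estimates (small-sample
#' artifacts) are reported as computed, not clamped.
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Data frame with columns `sample`, `population`; at
#'   least two populations, each with at least two samples.
#' @param keep_components If `TRUE`, also return per-pair per-locus
#'   variance components (for resampling-based standard errors).
#' @return A list of class `fst_matrix` with `populations`, `theta`
#'   (symmetric matrix, zero diagonal) and, optionally, `components`
#'   (named list of data frames with columns `a`, `b`, `c`).
#' @export
pairwise_fst <- function(gm, popmap, keep_components = FALSE) {
  pop <- match_populations(gm, popmap)
  pops <- unique(pop)
  if (length(pops) < 2L) stop("pairwise_fst needs at least two populations")
  sizes <- table(pop)
  if (any(sizes < 2L)) {
    stop("population(s) with fewer than two samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }

  m <- n_loci(gm)
  np <- length(pops)
  nmat <- pmat <- hmat <- matrix(NA_real_, np, m)
  for (k in seq_len(np)) {
    sub <- gm$calls[pop == pops[k], , drop = FALSE]
    nmat[k, ] <- colSums(!is.na(sub))
    pmat[k, ] <- colSums(sub, na.rm = TRUE) / (2 * nmat[k, ])  # alt freq
    hmat[k, ] <- colSums(sub == 1L, na.rm = TRUE) / nmat[k, ]
  }

  theta <- matrix(0, np, np, dimnames = list(pops, pops))
  components <- list()
  for (i in seq_len(np - 1L)) {
    for (j in seq(i + 1L, np)) {
      cmp <- wc_components(nmat[i, ], pmat[i, ], hmat[i, ],
                           nmat[j, ], pmat[j, ], hmat[j, ])
      if (nrow(cmp) == 0L) {
        stop(sprintf("no informative locus for pair %s / %s",
                     pops[i], pops[j]))
      }
      th <- sum(cmp$a) / sum(cmp$a + cmp$b + cmp$c)
      theta[i, j] <- theta[j, i] <- th
      if (keep_components) {
        components[[paste(pops[i], pops[j], sep = "|")]] <- cmp
      }
    }
  }
  out <- list(populations = pops, theta = theta)
  if (keep_components) out$components <- components
  structure(out, class = "fst_matrix")
}

# internal: Weir & Cockerham (1984) per-locus variance components for
# two populations (r = 2), vectorized over loci
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  ok <- n1 >= 2 & n2 >= 2
  n1 <- n1[ok]; p1 <- p1[ok]; h1 <- h1[ok]
  n2 <- n2[ok]; p2 <- p2[ok]; h2 <- h2[ok]
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  inf <- (a + b + cc) != 0 & is.finite(a + b + cc)
  data.frame(a = a[inf], b = b[inf], c = cc[inf])
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise Weir-Cockerham theta:\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Great-circle distances between population centroids
#'
#' Each population's geographic position is the centroid (mean
#' longitude/latitude) of its georeferenced samples; distances are
#' haversine great-circle distances in kilometres (mean Earth radius
#' 6371 km).
#'
#' @param coords Data frame with columns `sample`, `longitude`,
#'   `latitude`.
#' @param popmap Data frame with columns `sample`, `population`.
#' @return Symmetric km matrix with population dimnames.
#' @export
geo_distance <- function(coords, popmap) {
  coords <- validate_coords(coords)
  popmap <- validate_popmap(popmap)
  idx <- match(popmap$sample, coords$sample)
  if (anyNA(idx)) {
    stop("samples without coordinates: ",
         paste(popmap$sample[is.na(idx)], collapse = ", "))
  }
  lon <- coords$longitude[idx]
  lat <- coords$latitude[idx]
  pops <- unique(popmap$population)
  ctr <- t(vapply(pops, function(p) {
    c(mean(lon[popmap$population == p]), mean(lat[popmap$population == p]))
  }, numeric(2)))
  np <- length(pops)
  d <- matrix(0, np, np, dimnames = list(pops, pops))
  for (i in seq_len(np - 1L)) {
    for (j in seq(i + 1L, np)) {
      km <- geosphere::distHaversine(ctr[i, ], ctr[j, ], r = 6371000) / 1000
      d[i, j] <- d[j, i] <- km
    }
  }
  d
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with a one-sided
#' permutation test for positive association (rows and columns of the
#' second matrix are permuted jointly); the p-value uses the add-one
#' convention `p = (1 + #(r_perm >= r_obs)) / (n_perm + 1)`.
#' Typically applied to pairwise F_ST versus geographic distance
#' (isolation by distance).
#'
#' @param m1,m2 Symmetric matrices of identical shape and population
#'   order, at least 3 x 3.
#' @param n_perm Number of permutations (default 9999).
#' @param seed RNG seed (required for reproducibility).
#' @return A list of class `mantel_result` with `r`, `r_squared`, `p`,
#'   `n_perm`, `seed`.
#' @export
mantel_test <- function(m1, m2, n_perm = 9999, seed) {
  if (inherits(m1, "fst_matrix")) m1 <- m1$theta
  if (inherits(m2, "fst_matrix")) m2 <- m2$theta
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must have identical shape")
  if (nrow(m1) < 3L) stop("Mantel test needs at least 3 populations")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                       method = "pearson", permutations = n_perm)
  structure(list(r = unname(fit$statistic),
                 r_squared = unname(fit$statistic)^2,
                 p = unname(fit$signif),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f (r^2 = %.4f), one-sided p = %.4g (%d permutations)\n",
              x$r, x$r_squared, x$p, x$n_perm))
  invisible(x)
}
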