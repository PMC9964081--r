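test_that("Prevosti distance handles identity, opposites and missing loci", {
  gm <- genotype_matrix(rbind(a = c(0L, 0L), b = c(0L, 0L), c = c(2L, 2L)))
  d <- genetic_distance(gm)$d
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)  # (2 + 2) / (2 * 2)

  gm2 <- genotype_matrix(rbind(a = c(0L, 1L, NA), b = c(0L, 2L, 2L)))
  dd <- genetic_distance(gm2)
  expect_equal(dd$d["a", "b"], 0.25)          # (0 + 1) / (2 * 2)
  expect_equal(dd$comparable_loci["a", "b"], 2)

  gm3 <- genotype_matrix(rbind(a = c(0L, NA), b = c(NA, 1L)))
  expect_error(genetic_distance(gm3), "share no called locus")
})

test_that("distance matrix is symmetric, zero-diagonal, within [0, 1]", {
  sim <- simulate_clonal_snps(sim_config(n_pops = 1, n_loci = 200, fst = 0,
                                         fis = 0.2, genets_per_pop = 8,
                                         error_rate = 0.01,
                                         missing_rate = 0.3, seed = 12))
  d <- genetic_distance(sim$genotypes)$d
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("histogram gap detection places the threshold mid-gap", {
  # off-diagonal distances {0.001, 0.002, 0.003, 0.06, 0.07}: the largest
  # gap runs 0.003 -> 0.06, midpoint 0.0315
  v <- c(0.001, 0.002, 0.003, 0.06, 0.07, 0.001, 0.002, 0.003, 0.06, 0.07)
  d <- matrix(0, 5, 5)
  d[upper.tri(d)] <- v
  d <- d + t(d)
  expect_equal(detect_threshold(d), 0.0315)

  # minimum pairwise distance >= 0.04: all samples treated as unique
  d2 <- d; d2[d2 > 0 & d2 < 0.04] <- 0.05
  expect_null(detect_threshold(d2))

  # no gap wider than the bin width
  v3 <- seq(0.001, 0.02, length.out = 10)
  d3 <- matrix(0, 5, 5); d3[upper.tri(d3)] <- v3; d3 <- d3 + t(d3)
  expect_null(detect_threshold(d3))
})

test_that("UPGMA merges the closest pair first and is ultrametric", {
  d <- matrix(c(0, 0.02, 0.10,
                0.02, 0, 0.10,
                0.10, 0.10, 0), 3, 3,
              dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  tr <- upgma(d)
  expect_equal(tr$height[1], 0.02)
  expect_setequal(tr$labels[-tr$merge[1, ]], c("s1", "s2"))
  expect_true(all(diff(tr$height) >= 0))          # monotone heights
  expect_equal(max(tr$height), tr$height[length(tr$height)])

  # identical samples merge at height zero
  gm <- gm_of(rbind(c(0L, 1L), c(0L, 1L), c(2L, 2L)))
  tr2 <- upgma(genetic_distance(gm))
  expect_equal(tr2$height[1], 0)
})

test_that("clone assignment reproduces the clonal-richness arithmetic", {
  # 28 samples in clusters of 5 and 23 -> G = 2, CR = 1/27
  d <- two_cluster_dist(c(5, 23))
  asg <- assign_clones(upgma(d), 0.03)
  expect_equal(asg$G, 2L)
  expect_equal(asg$CR, 1 / 27)
  expect_equal(sum(asg$ramets_per_genet), asg$N)

  # 21 samples in clusters {1, 1, 19} -> G = 3, CR = 0.10
  d2 <- two_cluster_dist(c(1, 1, 19))
  asg2 <- assign_clones(upgma(d2), 0.03)
  expect_equal(asg2$G, 3L)
  expect_equal(asg2$CR, 0.10)

  # monoclonal stand: G = 1, CR = 0
  d3 <- two_cluster_dist(11)
  asg3 <- assign_clones(upgma(d3), 0.03)
  expect_equal(asg3$G, 1L)
  expect_equal(asg3$CR, 0)

  # no threshold: every sample its own genet, CR = 1
  asg4 <- assign_clones(upgma(d), NULL)
  expect_equal(asg4$G, asg4$N)
  expect_equal(asg4$CR, 1)
})

test_that("genet count is non-increasing in the cut height", {
  sim <- simulate_clonal_snps(sim_config(n_pops = 1, n_loci = 300, fst = 0,
                                         fis = 0.1,
                                         ramet_counts = list(c(3L, 5L, 2L, 7L)),
                                         error_rate = 0.005,
                                         missing_rate = 0.1, seed = 44))
  tr <- upgma(genetic_distance(sim$genotypes))
  g_seq <- vapply(seq(0.001, 0.4, by = 0.01),
                  function(h) assign_clones(tr, h)$G, integer(1))
  expect_true(all(diff(g_seq) <= 0L))
})

test_that("noise-free clone structure is recovered exactly at any cut in the gap", {
  sim <- simulate_clonal_snps(sim_config(n_pops = 1, n_loci = 400, fst = 0,
                                         fis = 0,
                                         ramet_counts = list(c(5L, 3L, 6L, 2L)),
                                         error_rate = 0, missing_rate = 0,
                                         seed = 27))
  dd <- genetic_distance(sim$genotypes)
  genet <- sim$truth$genet_of[sim$genotypes$sample_ids]
  inter_min <- min(dd$d[outer(genet, genet, "!=")])
  tr <- upgma(dd)
  for (h in c(inter_min / 10, inter_min / 2, inter_min * 0.99)) {
    asg <- assign_clones(tr, h)
    expect_equal(ari(asg$genet_of, genet), 1)
  }
})

test_that("per-population delimitation filters high-missingness samples", {
  sim <- simulate_clonal_snps(sim_config(n_pops = 2, n_loci = 200, fst = 0.1,
                                         fis = 0,
                                         ramet_counts = list(c(4L, 4L),
                                                             c(3L, 5L)),
                                         error_rate = 0, missing_rate = 0,
                                         seed = 52))
  gm <- sim$genotypes
  gm$calls[1, seq_len(150)] <- NA_integer_  # 75% missing for sample 1
  gm <- genotype_matrix(gm$calls)
  res <- suppressMessages(
    population_clonality(gm, sim$popmap, search_ceiling = 0.5))
  expect_equal(res$summary$N[1], 7L)        # one sample excluded
  expect_equal(sum(res$summary$N), 15L)
  expect_equal(res$summary$CR,
               clonal_richness(res$summary$G, res$summary$N))
})

test_that("clone maps quantify spatial intermixing of genets", {
  map <- data.frame(longitude = 1:8, latitude = 0,
                    genet = rep(c("a", "b"), 4))
  expect_equal(intermixing_index(map), 1)   # perfectly interleaved
  map2 <- data.frame(longitude = c(1:4, 101:104), latitude = 0,
                     genet = rep(c("a", "b"), each = 4))
  expect_equal(intermixing_index(map2), 0)  # disjoint clusters

  cfg <- function(layout) sim_config(n_pops = 1, n_loci = 150, fst = 0,
                                     fis = 0,
                                     ramet_counts = list(rep(6L, 4)),
                                     error_rate = 0, missing_rate = 0,
                                     layout = layout, seed = 5)
  sG <- simulate_clonal_snps(cfg("guerrilla"))
  sP <- simulate_clonal_snps(cfg("phalanx"))
  asgG <- assign_clones(upgma(genetic_distance(sG$genotypes)), 0.01)
  asgP <- assign_clones(upgma(genetic_distance(sP$genotypes)), 0.01)
  iG <- attr(clonal_map(asgG, sG$coords), "intermixing")
  iP <- attr(clonal_map(asgP, sP$coords), "intermixing")
  expect_gt(iG, iP)

  # samples without coordinates are dropped with a warning
  co <- sG$coords[-1, ]
  expect_warning(clonal_map(asgG, co), "omitted")
})
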