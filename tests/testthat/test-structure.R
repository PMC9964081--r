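# a well-separated two-population dataset reused across blocks
sep_sim <- function(seed = 3, n_per = 20, m = 600, fst = 0.25) {
  simulate_clonal_snps(sim_config(n_pops = 2, n_loci = m, fst = fst, fis = 0,
                                  ramet_counts = list(rep(1L, n_per),
                                                      rep(1L, n_per)),
                                  error_rate = 0, missing_rate = 0.1,
                                  seed = seed))
}

test_that("K = 1 forces the all-ones membership column", {
  sim <- sep_sim(m = 100, n_per = 8)
  a <- estimate_ancestry(sim$genotypes, K = 1, seed = 2)
  expect_equal(unname(a$Q[, 1]), rep(1, 16))
})

test_that("Q rows are simplex points and the EM loss descends monotonically", {
  sim <- sep_sim()
  a <- estimate_ancestry(sim$genotypes, K = 3, seed = 5)
  expect_true(all(a$Q >= 0))
  expect_equal(unname(rowSums(a$Q)), rep(1, nrow(a$Q)), tolerance = 1e-6)
  # penalized loss non-increasing, checked at every recorded iteration
  expect_true(all(diff(a$loss_trace) <= 1e-8))
  # genotype-frequency factors are proper per-locus distributions
  sums <- apply(a$G_freq, c(1, 3), sum)
  expect_equal(unname(as.vector(sums)), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("two divergent populations resolve into their own clusters", {
  sim <- sep_sim()
  a <- estimate_ancestry(sim$genotypes, K = 2, seed = 11)
  pop <- sim$popmap$population
  own1 <- which.max(colMeans(a$Q[pop == "pop01", ]))
  own <- ifelse(pop == "pop01", a$Q[, own1], a$Q[, 3 - own1])
  expect_gte(mean(own >= 0.8), 0.9)
})

test_that("Q is stable under sample reordering, up to cluster relabeling", {
  sim <- sep_sim()
  a1 <- estimate_ancestry(sim$genotypes, 2, seed = 11)
  set.seed(99)
  perm <- sample(n_samples(sim$genotypes))
  a2 <- estimate_ancestry(subset_genotypes(sim$genotypes, samples = perm),
                          2, seed = 11)
  Q2 <- a2$Q[sim$genotypes$sample_ids, ]
  err <- min(max(abs(Q2 - a1$Q)), max(abs(Q2[, 2:1] - a1$Q)))
  expect_lt(err, 0.1)
})

test_that("masked cross-entropy selects the generating number of clusters", {
  sim <- simulate_clonal_snps(sim_config(n_pops = 3, n_loci = 400, fst = 0.25,
                                         fis = 0,
                                         ramet_counts = list(rep(1L, 15),
                                                             rep(1L, 15),
                                                             rep(1L, 15)),
                                         error_rate = 0, missing_rate = 0.1,
                                         seed = 13))
  ks <- select_k(sim$genotypes, 1:5, seed = 21)
  expect_equal(ks$best_k, 3L)
  expect_equal(nrow(ks$cross_entropy), 5L)  # one row per candidate K
})

test_that("panmictic data select K = 1 with non-decreasing cross-entropy", {
  sim <- simulate_clonal_snps(sim_config(n_pops = 1, n_loci = 400, fst = 0,
                                         fis = 0,
                                         ramet_counts = list(rep(1L, 40)),
                                         error_rate = 0, missing_rate = 0.1,
                                         seed = 9))
  ks <- select_k(sim$genotypes, 1:4, seed = 21)
  expect_equal(ks$best_k, 1L)
  expect_true(all(diff(ks$cross_entropy$mean_ce) > -1e-3))
})

test_that("DAPC separates fixed-difference populations with zero overlap", {
  gm <- gm_of(rbind(matrix(0L, 6, 40), matrix(2L, 6, 40)))
  pm <- popmap_of(gm, rep(c("A", "B"), each = 6))
  dp <- dapc_fit(gm, pm, n_pcs = 3)
  s <- dp$discriminants[, 1]
  expect_true(max(s[1:6]) < min(s[7:12]) || min(s[1:6]) > max(s[7:12]))
  expect_true(all(diff(dp$axis_variance) <= 0))
  expect_lte(sum(dp$axis_variance), 1 + 1e-9)
})

test_that("discriminant axes agree with the classical LDA solution", {
  skip_if_not_installed("MASS")
  sim <- sep_sim()
  X <- sim$genotypes$calls
  X[is.na(X)] <- 1L
  gm <- genotype_matrix(X)
  dp <- dapc_fit(gm, sim$popmap, n_pcs = 6)
  pca <- stats::prcomp(scale(X, scale = FALSE), center = FALSE, rank. = 6)
  fit <- MASS::lda(pca$x, grouping = factor(sim$popmap$population))
  oracle <- pca$x %*% fit$scaling
  expect_gt(abs(stats::cor(dp$discriminants[, 1], oracle[, 1])), 0.999)
  expect_gte(mean(dp$assignments == sim$popmap$population), 0.95)
})

test_that("DAPC scores are invariant to locus order and reject singletons", {
  sim <- sep_sim()
  dp1 <- dapc_fit(sim$genotypes, sim$popmap, n_pcs = 5)
  set.seed(1)
  lperm <- sample(n_loci(sim$genotypes))
  dp2 <- dapc_fit(subset_genotypes(sim$genotypes, loci = lperm),
                  sim$popmap, n_pcs = 5)
  expect_equal(dp1$discriminants, dp2$discriminants, tolerance = 1e-8)

  gm <- gm_of(rbind(matrix(0L, 3, 20), matrix(2L, 1, 20)))
  pm <- popmap_of(gm, c("A", "A", "A", "B"))
  expect_error(dapc_fit(gm, pm, n_pcs = 2), "single sample")
})

test_that("PC cross-validation is deterministic and ties go to fewer PCs", {
  sim <- sep_sim(n_per = 15, m = 200)
  cv1 <- crossvalidate_pcs(sim$genotypes, sim$popmap, c(2, 5, 10),
                           n_rep = 8, seed = 4)
  cv2 <- crossvalidate_pcs(sim$genotypes, sim$popmap, c(2, 5, 10),
                           n_rep = 8, seed = 4)
  expect_identical(cv1$optimal_n_pcs, cv2$optimal_n_pcs)
  expect_identical(cv1$scores, cv2$scores)
  # strongly separated data: reassignment is near-perfect and the tie
  # between equally good candidates resolves to the smallest
  expect_gte(max(cv1$scores$mean_correct), 0.95)
  top <- cv1$scores$n_pcs[cv1$scores$mean_correct ==
                            max(cv1$scores$mean_correct)]
  expect_equal(cv1$optimal_n_pcs, min(top))

  expect_error(crossvalidate_pcs(sim$genotypes, sim$popmap, 100,
                                 n_rep = 2, seed = 1), "training-set")
})
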