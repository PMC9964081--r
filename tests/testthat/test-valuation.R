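test_that("genetic-value rules classify the canonical profiles", {
  expect_equal(classify_genetic_value(0.04, 0.555, "Moderate", "No"), "Low")
  expect_equal(classify_genetic_value(0.127, 0.024, "Very High", "Yes"), "High")
  expect_equal(classify_genetic_value(0.125, 0.113, "Moderate", "Yes"),
               "Moderate")
  expect_error(classify_genetic_value(0.1, 0.1, "Medium", "Yes"),
               "unknown divergence level")
  expect_error(classify_genetic_value(0.1, 0.1, "High", "maybe"),
               "unknown unique-ancestry")
})

test_that("the rubric reproduces every row of the reference survey table", {
  tab <- sfloridana_summary("population")
  got <- classify_genetic_value(tab$H_O, tab$F_IS, tab$divergence,
                                tab$unique_ancestry)
  expect_equal(got, tab$genetic_value)
})

test_that("divergence bins are total, disjoint, and match the anchors", {
  expect_equal(divergence_bin(0.03), "Low")
  expect_equal(divergence_bin(0.17), "High")
  expect_equal(divergence_bin(0.22), "Very High")
  expect_equal(divergence_bin(0.05), "Moderate")  # left-closed bins
  expect_equal(divergence_bin(0.15), "High")
  expect_equal(divergence_bin(0.20), "Very High")
  grid <- seq(0, 1, by = 0.001)
  lev <- divergence_bin(grid)
  expect_false(anyNA(lev))  # total over [0, 1]

  theta <- matrix(c(0, 0.03, 0.03, 0), 2,
                  dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(derive_divergence_level(theta, "A"), "Low")
  expect_error(derive_divergence_level(theta, "C"), "unknown population")
})

test_that("unique ancestry requires a private dominant cluster", {
  pm <- data.frame(sample = paste0("s", 1:6),
                   population = rep(c("A", "B"), each = 3))
  # cluster 1 private to A at 0.9
  Q <- rbind(matrix(c(0.9, 0.1), 3, 2, byrow = TRUE),
             matrix(c(0.05, 0.95), 3, 2, byrow = TRUE))
  rownames(Q) <- pm$sample
  expect_equal(unname(derive_unique_ancestry(Q, pm)), c("Yes", "Yes"))

  # fully admixed: no dominant cluster anywhere
  Q2 <- matrix(1 / 3, 6, 3, dimnames = list(pm$sample, NULL))
  expect_equal(unname(derive_unique_ancestry(Q2, pm)), c("No", "No"))

  # one cluster shared 50/50 by both populations: dominant but not private
  Q3 <- matrix(c(0.5, 0.5), 6, 2, byrow = TRUE,
               dimnames = list(pm$sample, NULL))
  expect_equal(unname(derive_unique_ancestry(Q3, pm)), c("No", "No"))
})

test_that("the pipeline runs end to end and degrades gracefully", {
  sim <- simulate_clonal_snps(sim_config(n_pops = 3, n_loci = 250, fst = 0.2,
                                         fis = 0.1, genets_per_pop = 10,
                                         error_rate = 0.005,
                                         missing_rate = 0.15, seed = 33))
  dir <- withr::local_tempdir()
  write_vcf(sim$genotypes, file.path(dir, "in.vcf"))
  write_tsv_plain(sim$popmap, file.path(dir, "popmap.tsv"))
  write_tsv_plain(sim$coords, file.path(dir, "coords.tsv"))

  cfg <- pipeline_config(vcf = file.path(dir, "in.vcf"),
                         popmap = file.path(dir, "popmap.tsv"),
                         coords = file.path(dir, "coords.tsv"),
                         out_dir = file.path(dir, "out"),
                         min_presence = 0.6, k_range = 1:3,
                         n_perm = 99, seed = 7)
  rep1 <- suppressMessages(run_pipeline(cfg))
  expect_equal(nrow(rep1$assessment), 3L)
  expect_true(all(rep1$assessment$genetic_value %in%
                    c("Low", "Moderate", "High")))
  expect_true(file.exists(file.path(dir, "out", "report.json")))
  expect_false(is.null(rep1$mantel))

  # reruns with the same config are reproducible
  rep2 <- suppressMessages(run_pipeline(cfg))
  expect_equal(rep1$fst, rep2$fst)
  expect_equal(rep1$best_k, rep2$best_k)
  expect_equal(rep1$assessment, rep2$assessment)

  # deleting the coordinates: Mantel and maps skipped, run completes
  file.remove(file.path(dir, "coords.tsv"))
  rep3 <- suppressMessages(run_pipeline(cfg))
  expect_null(rep3$mantel)
  expect_match(paste(rep3$skipped, collapse = " "), "skipped")
  expect_equal(nrow(rep3$assessment), 3L)
})
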