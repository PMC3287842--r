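# The synthetic-data generator: construction guarantees, seeded
# determinism, and the statistical properties the study designs rely on.

test_that("planted gene layout is recovered exactly and sampling matches the MAF", {
  cfg <- sim_config(n_samples = 697, n_genes = 1, variants_per_gene = c(2L, 2L),
                    causal_genes = list(causal_spec(n_variants = 1L,
                                                    maf_values = 0.5, effect = 0)),
                    n_replicates = 1L)
  geno <- simulate_genotypes(cfg, seed = 3)
  # membership reconstructed from coordinates equals the planted blocks
  expect_equal(map_variants_to_genes(geno$variants, geno$regions), geno$index)
  # point-mass maf 0.5 lands within 3 binomial SE at n = 697
  vid <- geno$truth$variant_id
  f <- sum(geno$counts[, vid]) / (2 * 697)
  se <- sqrt(0.5 * 0.5 / (2 * 697))
  expect_lt(abs(min(f, 1 - f) - 0.5), 3 * se + 1e-12)
})

test_that("same seed gives bit-identical datasets; genotypes fixed, phenotypes redrawn", {
  cfg <- sim_preset("null", n_samples = 50, n_genes = 5, n_replicates = 3)
  a <- simulate_dataset(cfg, seed = 12)
  b <- simulate_dataset(cfg, seed = 12)
  expect_identical(a$counts, b$counts)
  expect_identical(a$phenotypes, b$phenotypes)
  # one genotype panel, distinct phenotype draws per replicate
  q <- split(a$phenotypes$Q, a$phenotypes$replicate)
  expect_false(identical(q[[1]], q[[2]]))
  expect_false(identical(q[[2]], q[[3]]))
  c2 <- simulate_dataset(cfg, seed = 13)
  expect_false(identical(a$counts, c2$counts))
})

test_that("null traits are uncorrelated with genotypes and Q2-like traits with Age", {
  cfg <- sim_preset("null", n_samples = 300, n_genes = 10, n_replicates = 10)
  ds <- simulate_dataset(cfg, seed = 21)
  rs <- sapply(1:10, function(r) {
    sub <- ds$phenotypes[ds$phenotypes$replicate == r, ]
    y <- sub$Q[match(rownames(ds$counts), sub$sample_id)]
    poly <- which(ds$variants$maf > 0)
    mean(suppressWarnings(cor(ds$counts[, poly], y)), na.rm = TRUE)
  })
  expect_lt(abs(mean(rs)), 3 / sqrt(300 * 10))

  q2 <- simulate_dataset(sim_preset("q2like", n_samples = 300, n_genes = 10,
                                    n_replicates = 10,
                                    causal_genes = rep(list(causal_spec(2L,
                                      maf_values = c(0.02, 0.17), effect = 0.35)), 3L)),
                         seed = 22)
  r_age <- sapply(1:10, function(r) {
    sub <- q2$phenotypes[q2$phenotypes$replicate == r, ]
    cor(sub$Q2, sub$Age)
  })
  expect_lt(abs(mean(r_age)), 3 / sqrt(300 * 10))
})

test_that("a positive causal effect raises the trait among carriers", {
  cfg <- sim_preset("q2like", n_samples = 400, n_genes = 5, n_replicates = 50,
                    causal_genes = list(causal_spec(2L, maf_values = c(0.05, 0.17),
                                                    effect = 0.35)))
  ds <- simulate_dataset(cfg, seed = 8)
  vid <- ds$truth$variant_id[2]      # the common causal variant
  carrier <- ds$counts[, vid] > 0
  diff_by_rep <- sapply(1:50, function(r) {
    sub <- ds$phenotypes[ds$phenotypes$replicate == r, ]
    y <- sub$Q2[match(rownames(ds$counts), sub$sample_id)]
    mean(y[carrier]) - mean(y[!carrier])
  })
  expect_gt(mean(diff_by_rep), 0)
})

test_that("binary traits are 0/1 with the configured prevalence", {
  ds <- simulate_dataset(sim_preset("q1like", n_samples = 200, n_replicates = 3,
                                    n_genes = 20,
                                    causal_genes = rep(list(causal_spec()), 5L)),
                         seed = 14)
  expect_true(all(ds$phenotypes$Affected %in% c(0, 1)))
  prev <- tapply(ds$phenotypes$Affected, ds$phenotypes$replicate, mean)
  expect_true(all(abs(prev - 0.3) < 0.05))
})

test_that("degenerate confounding reduces to an ordinary null panel", {
  cfg <- sim_preset("confounded", n_samples = 100, n_genes = 10, n_replicates = 2,
                    confounding = confounding_spec(age_shift = 0, freq_mode = "shared"),
                    traits = list(Q = trait_spec(genetic = FALSE)))
  ds <- make_confounded_null(cfg, seed = 5)
  # same-law frequencies for both halves: subpopulation explains no burden
  pop <- ds$pop
  expect_equal(sort(unique(pop)), 1:2)
  burden <- rowSums(ds$counts)
  expect_gt(t.test(burden[pop == 1], burden[pop == 2])$p.value, 0.01)
  sub <- ds$phenotypes[ds$phenotypes$replicate == 1, ]
  expect_gt(t.test(sub$Age[pop == 1], sub$Age[pop == 2])$p.value, 0.001)
})

test_that("confounded panels stratify both allele frequencies and Age", {
  ds <- make_confounded_null(sim_preset("confounded", n_samples = 300,
                                        n_genes = 30, n_replicates = 2), seed = 6)
  pop <- ds$pop
  sub <- ds$phenotypes[ds$phenotypes$replicate == 1, ]
  age <- sub$Age[match(rownames(ds$counts), sub$sample_id)]
  expect_gt(mean(age[pop == 2]) - mean(age[pop == 1]), 5)   # planted 10-year shift
  # per-variant frequency differences are large for many variants
  f1 <- colMeans(ds$counts[pop == 1, ]) / 2
  f2 <- colMeans(ds$counts[pop == 2, ]) / 2
  expect_gt(mean(abs(f1 - f2) > 0.01), 0.3)
  expect_equal(nrow(ds$truth), 0L)
})

test_that("dataset files round-trip through the plain-text dialects", {
  td <- withr::local_tempdir()
  ds <- simulate_dataset(sim_preset("null", n_samples = 12, n_genes = 3,
                                    n_replicates = 2), seed = 44)
  paths <- write_dataset(ds, td)
  geno <- read_genotypes(paths[["genotypes"]], "matrix-tsv",
                         variant_path = paths[["variants"]])
  expect_identical(unname(geno$counts), unname(ds$counts))
  reg <- read_gene_regions(paths[["regions"]])
  expect_equal(reg, ds$regions)
  expect_equal(map_variants_to_genes(compute_maf(geno$counts, geno$variants), reg),
               ds$index)
})

test_that("simulation configs round-trip through YAML", {
  td <- withr::local_tempdir()
  ypath <- file.path(td, "sim.yaml")
  writeLines(c(
    "n_samples: 120",
    "n_genes: 8",
    "n_replicates: 3",
    "variants_per_gene: [3, 6]",
    "causal_genes:",
    "  - n_variants: 2",
    "    maf_values: [0.01, 0.17]",
    "    effect: 0.4",
    "traits:",
    "  Q2:",
    "    genetic: true",
    "confounding:",
    "  age_shift: 8",
    "binary:",
    "  weights:",
    "    Q2: 1.0",
    "  prevalence: 0.25"), ypath)
  cfg <- read_sim_config(ypath)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_samples, 120L)
  expect_equal(cfg$causal_genes[[1]]$maf_values, c(0.01, 0.17))
  expect_equal(cfg$confounding$age_shift, 8)
  expect_equal(cfg$binary$prevalence, 0.25)
  ds <- simulate_dataset(cfg, seed = 3)
  expect_equal(nrow(ds$counts), 120L)
  expect_true(all(ds$phenotypes$Affected %in% 0:1))

  writeLines(c("n_samples: 10", "bogus_key: 1"), ypath)
  expect_error(read_sim_config(ypath), "bogus_key")
})
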