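# Weights, burdens, the score z, permutation p-values, and the four tests
# against independent brute-force oracles.

test_that("threshold weights use a strict cutoff", {
  expect_equal(threshold_weights(c(0.005, 0.02), 0.01), c(1, 0))
  expect_equal(threshold_weights(c(0.01, 0.009), 0.01), c(0, 1))  # boundary excluded
  expect_equal(threshold_weights(c(0.1, 0.3, 0.49), 0.5), c(1, 1, 1))
})

test_that("weighted-sum weights follow the inverse-variance formula and decrease in maf", {
  expect_equal(ws_weights(0.5, 1), 2)  # 1/sqrt(0.25)
  set.seed(3)
  p <- sort(runif(20, 0.001, 0.5))
  w <- ws_weights(p, 85)
  expect_equal(w, 1 / sqrt(85 * p * (1 - p)))
  expect_true(all(diff(w) < 0))  # rarer variant, larger weight
  expect_error(ws_weights(c(0.1, 0), 10), "maf = 0")
})

test_that("weighted burden matches a double-loop oracle and rejects empty weights", {
  set.seed(8)
  counts <- matrix(rbinom(24, 2, 0.4), 6, 4)
  w <- runif(4)
  expect_equal(weighted_burden(counts, w), oracle_burden(counts, w))
  expect_equal(weighted_burden(counts[, 1, drop = FALSE], 1), counts[, 1])
  expect_error(weighted_burden(counts, rep(0, 4)), "no qualifying")
})

test_that("z statistic matches the fixed score form and its symmetries", {
  set.seed(12)
  C <- rbinom(10, 4, 0.3)
  y <- rnorm(10)
  z <- z_statistic(C, y)
  expect_equal(z, oracle_z(C, y))
  # sign agrees with the regression slope t statistic
  tstat <- summary(lm(y ~ C))$coefficients["C", "t value"]
  expect_equal(sign(z), sign(tstat))
  expect_equal(z_statistic(C, -y), -z)
  perm <- sample(10)
  expect_equal(z_statistic(C[perm], y[perm]), z)
  expect_equal(z_statistic(rep(2, 10), y), 0)  # constant burden is neutral
  expect_error(z_statistic(C, rep(1, 10)), "constant")
})

test_that("add-one permutation p-values count ties against the observed value", {
  expect_equal(permutation_pvalue(5, rep(1, 99)), 1 / 100)
  expect_equal(permutation_pvalue(2, rep(2, 9)), 1)
  expect_equal(permutation_pvalue(-3, c(-5, -4, 2), sided = "two-sided"), 3 / 4)
  # exhaustive enumeration agrees with counting over the same enumeration
  toy <- make_toy_gene(n = 6)
  z_obs <- oracle_z(toy$counts[, 1], toy$y)
  perms <- oracle_perms(6)
  z_all <- apply(perms, 2, function(pp) oracle_z(toy$counts[, 1], toy$y[pp]))
  expect_equal(permutation_pvalue(z_obs, z_all),
               (1 + sum(z_all >= z_obs - 1e-9)) / (1 + 720))
})

test_that("all four tests in exhaustive mode equal the brute-force enumerator", {
  plan <- permutation_plan(mode = "exhaustive")
  for (seed in c(42L, 101L, 7L)) {
    toy <- make_toy_gene(n = 6, m = 3, seed = seed)
    env <- wrap_gene(toy$counts)
    mafs <- env$variants$maf
    for (tn in c("T1", "T5", "WS", "VT")) {
      orc <- oracle_gene_test(toy$counts, mafs, toy$y, tn)
      got <- switch(tn,
        T1 = fixed_threshold_test("g1", env$counts, env$variants, env$index,
                                  toy$y, 0.01, plan),
        T5 = fixed_threshold_test("g1", env$counts, env$variants, env$index,
                                  toy$y, 0.05, plan),
        WS = weighted_sum_test("g1", env$counts, env$variants, env$index,
                               toy$y, plan),
        VT = variable_threshold_test("g1", env$counts, env$variants, env$index,
                                     toy$y, plan))
      if (!orc$testable) {
        expect_true(is.na(got$p_value))
      } else {
        expect_equal(got$p_value, orc$p, info = paste(tn, seed))
        expect_equal(got$statistic, orc$stat, info = paste(tn, seed))
        if (tn == "VT") expect_equal(got$optimal_threshold, orc$opt)
      }
    }
  }
})

test_that("genes outside a test's reach are flagged not-testable", {
  counts <- matrix(c(0, 1, 1, 2, 0, 1), 3, 2)  # mafs 1/3 and 1/2: nothing rare
  env <- wrap_gene(counts)
  y <- c(0.1, -0.4, 1.2)
  plan <- permutation_plan(n_perm = 50, seed = 1)
  r <- fixed_threshold_test("g1", env$counts, env$variants, env$index, y, 0.01, plan)
  expect_true(is.na(r$p_value) && is.na(r$statistic))
  expect_equal(r$n_variants_used, 0L)
  # monomorphic-only gene is not testable by any test
  mono <- wrap_gene(matrix(0, 4, 2))
  y4 <- c(0.3, -1, 0.5, 2)
  expect_true(is.na(weighted_sum_test("g1", mono$counts, mono$variants,
                                      mono$index, y4, plan)$p_value))
  expect_true(is.na(variable_threshold_test("g1", mono$counts, mono$variants,
                                            mono$index, y4, plan)$p_value))
})

test_that("single-variant genes give identical p for WS, fixed and VT (scale invariance)", {
  set.seed(21)
  counts <- matrix(rbinom(12, 2, 0.15), 12, 1)
  env <- wrap_gene(counts)
  y <- rnorm(12)
  plan <- permutation_plan(n_perm = 400, seed = 5)
  p_fix <- fixed_threshold_test("g1", env$counts, env$variants, env$index, y,
                                0.49, plan)$p_value
  p_ws <- weighted_sum_test("g1", env$counts, env$variants, env$index, y, plan)$p_value
  p_vt <- variable_threshold_test("g1", env$counts, env$variants, env$index,
                                  y, plan)$p_value
  expect_equal(p_fix, p_ws)
  expect_equal(p_fix, p_vt)  # one distinct maf: single-candidate collapse
})

test_that("VT z_max dominates every single-threshold statistic", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(8:20, 1)
    m <- sample(2:6, 1)
    counts <- matrix(rbinom(n * m, 2, runif(m, 0.05, 0.45)), n, m, byrow = FALSE)
    counts <- rarepool:::fold_minor(counts)
    mafs <- compute_maf(counts)$maf
    keep <- mafs > 0
    if (!any(keep)) next
    y <- rnorm(n)
    cand <- sort(unique(mafs[keep]))
    z_all <- vapply(cand, function(t) {
      z_statistic(rowSums(counts[, keep, drop = FALSE][, mafs[keep] <= t,
                                                       drop = FALSE]), y)
    }, numeric(1))
    env <- wrap_gene(counts)
    vt <- variable_threshold_test("g1", env$counts, env$variants, env$index, y,
                                  permutation_plan(n_perm = 2, seed = 1))
    expect_true(vt$statistic >= max(z_all) - 1e-12)
    # and dominates any fixed-threshold statistic on the same gene
    thr <- runif(1, 0.01, 0.5)
    if (any(mafs[keep] < thr)) {
      zf <- z_statistic(rowSums(counts[, keep, drop = FALSE][, mafs[keep] < thr,
                                                             drop = FALSE]), y)
      expect_true(vt$statistic >= zf - 1e-12)
    }
  }
})

test_that("results are bit-identical under the same seed and order independent", {
  ds <- simulate_dataset(sim_preset("null", n_samples = 30, n_replicates = 2,
                                    n_genes = 5), seed = 9)
  a <- run_association(ds, trait = "Q", n_perm = 99, seed = 4)
  b <- run_association(ds, trait = "Q", n_perm = 99, seed = 4)
  expect_identical(a, b)
  # per-gene derived seeds: testing a subset reproduces the full run's rows
  sub <- run_association(ds, trait = "Q", n_perm = 99, seed = 4,
                         genes = c("gene0003", "gene0001"))
  full_rows <- a[a$gene %in% c("gene0001", "gene0003"), ]
  sub <- sub[order(sub$gene, sub$replicate, sub$test), ]
  full_rows <- full_rows[order(full_rows$gene, full_rows$replicate, full_rows$test), ]
  rownames(sub) <- rownames(full_rows) <- NULL
  expect_equal(sub, full_rows, ignore_attr = TRUE)
})

test_that("a binary phenotype goes through the same linear path as a quantitative one", {
  set.seed(50)
  counts <- matrix(rbinom(40, 2, 0.2), 20, 2)
  env <- wrap_gene(counts)
  y <- rbinom(20, 1, 0.4)
  plan <- permutation_plan(n_perm = 200, seed = 2)
  r_bin <- weighted_sum_test("g1", env$counts, env$variants, env$index, y, plan)
  r_num <- weighted_sum_test("g1", env$counts, env$variants, env$index,
                             as.numeric(y), plan)
  expect_identical(r_bin$p_value, r_num$p_value)
  expect_identical(r_bin$statistic, r_num$statistic)
})

test_that("shared permutation streams make per-test p-values match standalone calls", {
  toy <- make_toy_gene(n = 15, m = 4, seed = 77)
  env <- wrap_gene(toy$counts)
  plan <- permutation_plan(n_perm = 300, seed = 8)
  all4 <- pooled_gene_tests("g1", env$counts, env$variants, env$index, toy$y,
                            plan = plan)
  vt <- variable_threshold_test("g1", env$counts, env$variants, env$index,
                                toy$y, plan)
  ws <- weighted_sum_test("g1", env$counts, env$variants, env$index, toy$y, plan)
  expect_equal(all4$p_value[all4$test == "VT"], vt$p_value)
  expect_equal(all4$p_value[all4$test == "WS"], ws$p_value)
})
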