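# The four gene-level pooled association tests. All are linear-score
# burden tests: collapse a gene's minor-allele counts into a per-sample
# weighted burden C_j = sum_i w_i x_ji, form the standardized score
#
#   z = sum_j C_j (y_j - ybar) / ( sd_n(y) * sqrt(sum_j (C_j - Cbar)^2) )
#
# (sd_n = divide-by-n standard deviation; equivalent to the regression
# score test of the burden slope), and assess significance by permuting
# the phenotype. T1/T5 use 0/1 weights at a fixed MAF cutoff (strictly
# below 1% / 5%); WS weights every variant by the inverse square root of
# its expected genotype variance; VT maximizes z over every candidate
# cutoff (the observed distinct MAFs, inclusive) and re-runs that
# maximization inside every permutation. Binary phenotypes take the same
# linear path as quantitative ones.
#
# ybar and sd_n(y) are invariant under permutation, and the burden
# denominators depend only on genotypes, so the permuted statistics for
# all tests and all VT cutoffs reduce to one crossproduct of the burden
# matrix with the permuted centered phenotypes.

# Tolerance when counting permuted statistics at least as extreme as the
# observed one: per-sample burdens are small integers, so permutations
# within equal-burden groups are exact mathematical ties whose floating-
# point sums can differ in the last bit by summation order.
.z_tie_tol <- 1e-9

#' Describe a permutation scheme
#'
#' @param n_perm number of Monte-Carlo permutations (ignored in exhaustive
#'   mode). The full-scale default mirrors common practice of 1e5; desk-
#'   scale analyses typically use 999.
#' @param seed integer master seed; per-gene streams are derived from it
#'   and the gene name (and replicate id), so results do not depend on
#'   gene processing order.
#' @param mode `"monte-carlo"` or `"exhaustive"` (all `n!` phenotype
#'   orderings; only legal while `n! <= cap`).
#' @param cap largest factorial allowed in exhaustive mode (default 5040,
#'   i.e. n <= 7).
#' @return a `permutation_plan` list.
#' @export
permutation_plan <- function(n_perm = 100000L, seed = 1L,
                             mode = c("monte-carlo", "exhaustive"),
                             cap = 5040L) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1L, is.numeric(seed), length(seed) == 1L)
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 mode = mode, cap = as.integer(cap)),
            class = "permutation_plan")
}

# Deterministic per-(gene, replicate) seed below 2^31, order-independent.
.derive_seed <- function(seed, gene_name, replicate = 0L) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(as.character(gene_name))) h <- (h * 31 + code) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h * 7919 + replicate * 104729) %% m)
}

# All n! permutations of 1:n as an n x n! integer matrix, lexicographic in
# construction order. Used for exhaustive mode and by test oracles at n <= 7.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (j in seq_len(ncol(sub))) {
    v <- sub[, j]
    for (i in seq_len(n)) {
      k <- k + 1L
      out[, k] <- append(v, n, after = i - 1L)
    }
  }
  out
}

#' Fixed-threshold 0/1 weights
#'
#' `w_i = 1` if `maf_i < threshold` (strictly), else 0 — the T1/T5 rule
#' ("below 1% (or 5%)").
#'
#' @param mafs minor-allele frequencies.
#' @param threshold MAF cutoff in (0, 0.5].
#' @return numeric weight vector.
#' @export
threshold_weights <- function(mafs, threshold) {
  stopifnot(length(mafs) >= 1L, threshold > 0, threshold <= 0.5)
  as.numeric(mafs < threshold)
}

#' Weighted-sum (inverse expected-variance) weights
#'
#' `w_i = 1 / sqrt(n p_i (1 - p_i))` with `p_i` the full-sample minor
#' allele frequency: rarer variants get larger weights. The factor `n`
#' cancels in the z-statistic (which is scale invariant in the burden), so
#' only `p_i (1 - p_i)` affects any p-value.
#'
#' @param mafs minor-allele frequencies, all in (0, 0.5].
#' @param n_samples number of samples.
#' @return numeric weight vector.
#' @export
ws_weights <- function(mafs, n_samples) {
  stopifnot(length(mafs) >= 1L, n_samples >= 1L)
  if (any(mafs <= 0))
    stop("ws_weights undefined for maf = 0 (zero expected variance); drop monomorphic variants first")
  if (any(mafs > 0.5)) stop("maf must be folded to the minor allele (<= 0.5)")
  1 / sqrt(n_samples * mafs * (1 - mafs))
}

#' Per-sample weighted burden
#'
#' `C_j = sum_i w_i x_ji` over a gene's variants.
#'
#' @param counts_gene samples x variants count submatrix for one gene.
#' @param weights weight vector aligned to its columns.
#' @return numeric vector of per-sample burdens.
#' @export
weighted_burden <- function(counts_gene, weights) {
  counts_gene <- as.matrix(counts_gene)
  stopifnot(ncol(counts_gene) == length(weights))
  if (all(weights == 0)) stop("no qualifying variants (all weights zero)")
  as.vector(counts_gene %*% weights)
}

#' Standardized score z-statistic of a burden against a phenotype
#'
#' `z = sum_j C_j (y_j - ybar) / (sd_n(y) * sqrt(sum_j (C_j - Cbar)^2))`,
#' with `sd_n` the divide-by-n standard deviation. This is the
#' standardized score statistic for the slope of the linear regression of
#' `y` on the burden; `ybar` and `sd_n(y)` are permutation invariant,
#' which is what makes permutation re-computation cheap. A constant burden
#' gives `z = 0` (association undefined, statistic neutral).
#'
#' @param burden per-sample burden `C_j`.
#' @param y per-sample phenotype (quantitative or 0/1).
#' @return the z score (scalar).
#' @export
z_statistic <- function(burden, y) {
  stopifnot(length(burden) == length(y), length(y) >= 2L)
  yc <- y - mean(y)
  sdy <- sqrt(mean(yc^2))
  if (sdy == 0) stop("phenotype is constant; z undefined")
  ss <- sum((burden - mean(burden))^2)
  if (ss == 0) return(0)
  sum(burden * yc) / (sdy * sqrt(ss))
}

#' Add-one permutation p-value
#'
#' `p = (1 + #\{k : s_k >= s_obs\}) / (1 + P)`; ties count against the
#' observed statistic, and `p >= 1/(P+1)` always. For `"two-sided"` the
#' statistics are compared on the absolute scale.
#'
#' @param observed observed statistic.
#' @param permuted vector of permuted statistics.
#' @param sided `"greater"` (one-sided, default) or `"two-sided"`.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, permuted, sided = c("greater", "two-sided")) {
  sided <- match.arg(sided)
  stopifnot(length(permuted) >= 1L)
  if (sided == "two-sided") {
    observed <- abs(observed)
    permuted <- abs(permuted)
  }
  (1 + sum(permuted >= observed - .z_tie_tol)) / (1 + length(permuted))
}

# ---- shared per-gene machinery -----------------------------------------

# Build the burden-column structure for one gene: a single n x K matrix B
# whose columns cover every requested test (one column per fixed/WS test,
# one per VT candidate threshold), plus per-column centered sums of
# squares. Monomorphic variants (maf 0) are dropped first. Tests with no
# qualifying variants are flagged not-testable.
.prep_gene <- function(counts_gene, mafs, tests, thresholds) {
  counts_gene <- as.matrix(counts_gene)
  keep <- which(mafs > 0)
  counts_gene <- counts_gene[, keep, drop = FALSE]
  mafs <- mafs[keep]
  n <- nrow(counts_gene)
  cols <- list()
  meta <- list()
  for (tn in tests) {
    if (tn %in% c("T1", "T5") || startsWith(tn, "fixed(")) {
      thr <- if (tn %in% names(thresholds)) thresholds[[tn]]
             else as.numeric(sub("^fixed\\((.*)\\)$", "\\1", tn))
      sel <- mafs < thr
      if (length(mafs) == 0L || !any(sel)) {
        meta[[tn]] <- list(testable = FALSE, n_used = 0L)
        next
      }
      cols[[length(cols) + 1L]] <- rowSums(counts_gene[, sel, drop = FALSE])
      meta[[tn]] <- list(testable = TRUE, n_used = sum(sel), col = length(cols))
    } else if (tn == "WS") {
      if (length(mafs) == 0L) {
        meta[[tn]] <- list(testable = FALSE, n_used = 0L)
        next
      }
      w <- ws_weights(mafs, n)
      cols[[length(cols) + 1L]] <- as.vector(counts_gene %*% w)
      meta[[tn]] <- list(testable = TRUE, n_used = length(mafs), col = length(cols))
    } else if (tn == "VT") {
      if (length(mafs) == 0L) {
        meta[[tn]] <- list(testable = FALSE, n_used = 0L)
        next
      }
      cand <- sort(unique(mafs))
      vt_cols <- integer(length(cand))
      for (k in seq_along(cand)) {
        cols[[length(cols) + 1L]] <- rowSums(counts_gene[, mafs <= cand[k], drop = FALSE])
        vt_cols[k] <- length(cols)
      }
      meta[[tn]] <- list(testable = TRUE, n_used = length(mafs),
                         col = vt_cols, cand = cand)
    } else stop("unknown test name: ", tn)
  }
  B <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0L)
  ss <- if (ncol(B)) colSums(sweep(B, 2L, colMeans(B))^2) else numeric(0)
  list(B = B, ss = ss, meta = meta, n = n)
}

# Observed and permuted statistics for every prepared test of one gene.
# Returns a data frame row per test. The permutation stream is shared by
# all tests in one call (same phenotype shuffles), which makes cross-test
# comparisons paired.
.gene_stats <- function(prep, y, plan, sided, gene_name, replicate = 0L) {
  stopifnot(length(y) == prep$n)
  yc <- y - mean(y)
  sdy <- sqrt(mean(yc^2))
  if (sdy == 0) stop("phenotype is constant; tests undefined")
  d <- sdy * sqrt(prep$ss)
  zobs <- as.vector(crossprod(prep$B, yc))
  zobs <- ifelse(d > 0, zobs / d, 0)

  n <- prep$n
  if (plan$mode == "exhaustive") {
    if (factorial(n) > plan$cap)
      stop("exhaustive mode needs n! <= ", plan$cap, " (n = ", n, ")")
    idx <- .all_perms(n)
  } else {
    set.seed(.derive_seed(plan$seed, gene_name, replicate))
    idx <- vapply(seq_len(plan$n_perm), function(i) sample.int(n), integer(n))
  }
  P <- ncol(idx)
  Yc <- matrix(yc[idx], n, P)
  Z <- crossprod(prep$B, Yc)
  if (any(d == 0)) Z[d == 0, ] <- 0
  Z <- Z / ifelse(d > 0, d, 1)
  if (sided == "two-sided") {
    Z <- abs(Z)
    zobs_cmp <- abs(zobs)
  } else zobs_cmp <- zobs

  rows <- lapply(names(prep$meta), function(tn) {
    m <- prep$meta[[tn]]
    if (!m$testable)
      return(data.frame(gene = gene_name, test = tn, n_variants_used = 0L,
                        statistic = NA_real_, optimal_threshold = NA_real_,
                        n_permutations = NA_integer_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    if (tn == "VT" && length(m$col) > 1L) {
      j <- which.max(zobs_cmp[m$col])        # first max = smallest threshold
      s_obs <- zobs_cmp[m$col][j]
      stat <- zobs[m$col][j]
      opt <- m$cand[j]
      s_perm <- do.call(pmax, lapply(m$col, function(cc) Z[cc, ]))
    } else {
      cc <- m$col[1L]
      s_obs <- zobs_cmp[cc]
      stat <- zobs[cc]
      opt <- if (tn == "VT") m$cand[1L] else NA_real_
      s_perm <- Z[cc, ]
    }
    p <- (1 + sum(s_perm >= s_obs - .z_tie_tol)) / (1 + P)
    data.frame(gene = gene_name, test = tn, n_variants_used = m$n_used,
               statistic = stat, optimal_threshold = opt,
               n_permutations = P, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.single_test <- function(test, gene, counts, variants, index, y, plan, sided,
                         thresholds = c(T1 = 0.01, T5 = 0.05), replicate = 0L) {
  if (!gene %in% names(index)) stop("gene not in index: ", gene)
  vi <- index[[gene]]
  prep <- .prep_gene(counts[, vi, drop = FALSE], variants$maf[vi], test, thresholds)
  .gene_stats(prep, y, plan, sided, gene, replicate)
}

#' Fixed-threshold burden test for one gene
#'
#' Collapses the gene's variants with `maf < threshold` (strictly) into an
#' unweighted burden and assesses the score z by phenotype permutation.
#' Named "T1" at threshold 0.01 and "T5" at 0.05, else `fixed(T)`. A gene
#' with no variant below the threshold is returned flagged not-testable
#' (`NA` statistic and p-value): such genes are outside this test's
#' universe.
#'
#' @param gene gene name (must be in `index`).
#' @param counts samples x variants minor-allele count matrix.
#' @param variants variant data frame with `maf` filled.
#' @param index gene index from [map_variants_to_genes()].
#' @param y phenotype vector aligned to rows of `counts`.
#' @param threshold MAF cutoff.
#' @param plan a [permutation_plan()].
#' @param sided `"greater"` or `"two-sided"`.
#' @param replicate replicate id folded into the derived seed.
#' @return one-row data frame (`gene`, `test`, `n_variants_used`,
#'   `statistic`, `optimal_threshold`, `n_permutations`, `p_value`).
#' @export
fixed_threshold_test <- function(gene, counts, variants, index, y,
                                 threshold = 0.01, plan = permutation_plan(),
                                 sided = c("greater", "two-sided"), replicate = 0L) {
  sided <- match.arg(sided)
  tn <- if (isTRUE(all.equal(threshold, 0.01))) "T1"
        else if (isTRUE(all.equal(threshold, 0.05))) "T5"
        else paste0("fixed(", threshold, ")")
  .single_test(tn, gene, counts, variants, index, y, plan, sided,
               thresholds = stats::setNames(threshold, tn), replicate = replicate)
}

#' Weighted-sum burden test for one gene
#'
#' Uses [ws_weights()] over all the gene's polymorphic variants (no MAF
#' threshold), then the same score-permutation machinery as the fixed
#' tests. A gene with no polymorphic variant is flagged not-testable.
#'
#' @inheritParams fixed_threshold_test
#' @return one-row data frame as in [fixed_threshold_test()].
#' @export
weighted_sum_test <- function(gene, counts, variants, index, y,
                              plan = permutation_plan(),
                              sided = c("greater", "two-sided"), replicate = 0L) {
  sided <- match.arg(sided)
  .single_test("WS", gene, counts, variants, index, y, plan, sided, replicate = replicate)
}

#' Variable-threshold burden test for one gene
#'
#' Candidate thresholds are the gene's distinct observed MAFs, each used as
#' an inclusive cutoff (`maf <= t`). The statistic is `z_max`, the maximum
#' score z over candidates; `optimal_threshold` is the argmax (smallest on
#' ties). Within every permutation the maximization is re-run on the
#' permuted phenotype, so a permuted `z_max` may attain its maximum at a
#' different threshold — this is what keeps the test valid despite the
#' data-driven threshold choice.
#'
#' @inheritParams fixed_threshold_test
#' @return one-row data frame as in [fixed_threshold_test()], with
#'   `optimal_threshold` filled.
#' @export
variable_threshold_test <- function(gene, counts, variants, index, y,
                                    plan = permutation_plan(),
                                    sided = c("greater", "two-sided"), replicate = 0L) {
  sided <- match.arg(sided)
  .single_test("VT", gene, counts, variants, index, y, plan, sided, replicate = replicate)
}

#' Run several pooled tests on one gene with a shared permutation stream
#'
#' All requested tests see the same phenotype shuffles (one stream per
#' gene/replicate, seeded from the plan's master seed and the gene name),
#' which makes cross-test comparisons paired and independent of gene
#' processing order.
#'
#' @inheritParams fixed_threshold_test
#' @param tests subset of `c("T1", "T5", "WS", "VT")`.
#' @param thresholds named cutoffs for the fixed tests.
#' @return data frame with one row per test.
#' @export
pooled_gene_tests <- function(gene, counts, variants, index, y,
                              tests = c("T1", "T5", "WS", "VT"),
                              plan = permutation_plan(),
                              sided = c("greater", "two-sided"),
                              thresholds = c(T1 = 0.01, T5 = 0.05),
                              replicate = 0L) {
  sided <- match.arg(sided)
  if (!gene %in% names(index)) stop("gene not in index: ", gene)
  vi <- index[[gene]]
  prep <- .prep_gene(counts[, vi, drop = FALSE], variants$maf[vi], tests, thresholds)
  .gene_stats(prep, y, plan, sided, gene, replicate)
}
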