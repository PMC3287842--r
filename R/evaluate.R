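# Evaluation statistics for comparing the pooled tests over replicated
# simulations: per-test gene universes, the type I error rate on null
# data, true- and false-positive proportions against a known causal gene
# set, ROC curves over a significance-level grid, trapezoid AUC, and the
# Bonferroni family-wise threshold. All rates are means of rejection
# indicators over (gene, replicate) cells; not-testable cells (genes
# outside a test's universe) are excluded from numerator and denominator
# alike.

#' Per-test gene universe
#'
#' The set of genes a test can evaluate: for a fixed-threshold test, genes
#' with at least one polymorphic variant strictly below its MAF cutoff;
#' for WS and VT, all genes with at least one polymorphic variant. The
#' universes nest: `T1 <= T5 <= WS = VT`.
#'
#' @param test_name one of `"T1"`, `"T5"`, `"WS"`, `"VT"`.
#' @param variants variant data frame with `maf` filled.
#' @param index gene index from [map_variants_to_genes()].
#' @param thresholds named MAF cutoffs for the fixed tests.
#' @return character vector of gene names.
#' @export
build_universe <- function(test_name, variants, index,
                           thresholds = c(T1 = 0.01, T5 = 0.05)) {
  ok <- vapply(index, function(vi) {
    maf <- variants$maf[vi]
    maf <- maf[maf > 0]
    if (test_name %in% c("WS", "VT")) length(maf) > 0L
    else if (test_name %in% names(thresholds)) any(maf < thresholds[[test_name]])
    else stop("unknown test name: ", test_name)
  }, logical(1))
  names(index)[ok]
}

#' Arrange association results as per-test p-value grids
#'
#' @param results long data frame from [run_association()] (columns
#'   `replicate`, `gene`, `test`, `p_value`; `NA` marks not-testable).
#' @return named list, one genes x replicates p-value matrix per test.
#' @export
pvalue_grid <- function(results) {
  stopifnot(all(c("replicate", "gene", "test", "p_value") %in% names(results)))
  lapply(split(results, results$test), function(d) {
    genes <- sort(unique(d$gene))
    reps <- sort(unique(d$replicate))
    m <- matrix(NA_real_, length(genes), length(reps),
                dimnames = list(genes, as.character(reps)))
    m[cbind(match(d$gene, genes), match(d$replicate, reps))] <- d$p_value
    m
  })
}

#' Type I error rate on a null p-value grid
#'
#' The proportion of testable (gene, replicate) cells with `p <= alpha`,
#' over genes in the test's universe and all replicates — meaningful only
#' when no gene carries signal (a null trait).
#'
#' @param grid genes x replicates p-value matrix (`NA` = not testable).
#' @param alpha significance level (vectorized).
#' @return rejection rate(s).
#' @export
type1_error <- function(grid, alpha) {
  p <- grid[!is.na(grid)]
  if (!length(p)) stop("empty universe: no testable (gene, replicate) cells")
  vapply(alpha, function(a) mean(p <= a), numeric(1))
}

#' True-positive proportion
#'
#' Rejection rate over causal genes within the test's universe. Causal
#' genes with no testable cell (outside the universe) are excluded and
#' reported via the `excluded` attribute; it is an error if none remain.
#'
#' @param grid genes x replicates p-value matrix.
#' @param causal_genes character vector of causal gene names.
#' @param alpha significance level (vectorized).
#' @return rejection rate(s) with attribute `excluded`.
#' @export
true_positive_proportion <- function(grid, causal_genes, alpha) {
  stopifnot(length(causal_genes) >= 1L)
  rows <- intersect(rownames(grid), causal_genes)
  sub <- grid[rows, , drop = FALSE]
  testable <- rows[rowSums(!is.na(sub)) > 0L]
  excluded <- setdiff(causal_genes, testable)
  if (!length(testable))
    stop("no causal gene is testable by this test; excluded: ",
         paste(excluded, collapse = ", "))
  p <- grid[testable, , drop = FALSE]
  p <- p[!is.na(p)]
  structure(vapply(alpha, function(a) mean(p <= a), numeric(1)),
            excluded = excluded)
}

#' False-positive proportion
#'
#' Rejection rate over non-causal genes (the universe minus the causal
#' set). Reduces to [type1_error()] when the causal set is empty.
#'
#' @inheritParams true_positive_proportion
#' @return rejection rate(s).
#' @export
false_positive_proportion <- function(grid, causal_genes, alpha) {
  rows <- setdiff(rownames(grid), causal_genes)
  sub <- grid[rows, , drop = FALSE]
  p <- sub[!is.na(sub)]
  if (!length(p)) stop("empty complement: every testable gene is causal")
  vapply(alpha, function(a) mean(p <= a), numeric(1))
}

#' ROC curve of a test against the causal truth
#'
#' Sweeps the significance level over `alpha_grid` (default 200
#' log-spaced points from 1e-5 to 1), computes (FPP, TPP) at each level,
#' sorts by FPP and extends the polyline to the exact endpoints (0, 0)
#' and (1, 1). The curve thresholds the permutation p-value, which is how
#' the proportions are defined.
#'
#' @inheritParams true_positive_proportion
#' @param alpha_grid significance levels spanning (0, 1].
#' @return data frame (`alpha`, `fpp`, `tpp`) sorted by `fpp` then `tpp`,
#'   endpoints included (`alpha` `NA` there).
#' @export
roc_curve <- function(grid, causal_genes, alpha_grid = default_alpha_grid()) {
  if (!length(intersect(rownames(grid), causal_genes)))
    stop("degenerate truth: no causal gene present in the grid")
  tpp <- true_positive_proportion(grid, causal_genes, alpha_grid)
  fpp <- false_positive_proportion(grid, causal_genes, alpha_grid)
  pts <- data.frame(alpha = c(NA, alpha_grid, NA),
                    fpp = c(0, fpp, 1), tpp = c(0, tpp, 1))
  pts[order(pts$fpp, pts$tpp), , drop = FALSE]
}

#' Default significance-level grid for ROC sweeps
#' @param n number of points.
#' @param from smallest level.
#' @return numeric vector of log-spaced levels ending at 1.
#' @export
default_alpha_grid <- function(n = 200L, from = 1e-5) {
  exp(seq(log(from), log(1), length.out = n))
}

#' Trapezoid area under an ROC polyline
#' @param roc data frame from [roc_curve()] (sorted, endpoints included).
#' @return AUC in [0, 1].
#' @export
auc <- function(roc) {
  x <- roc$fpp
  y <- roc$tpp
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Interpolated TPP at a matched FPP
#'
#' Linear interpolation along the ROC polyline, for comparing tests at
#' the same false-positive proportion rather than the same nominal level.
#'
#' @param roc data frame from [roc_curve()].
#' @param fpp target false-positive proportion(s).
#' @return interpolated TPP value(s).
#' @export
tpp_at_fpp <- function(roc, fpp) {
  stats::approx(roc$fpp, roc$tpp, xout = fpp, ties = max, rule = 2)$y
}

#' Bonferroni family-wise threshold
#'
#' `fwer / n_genes`; e.g. 0.05 over 3,205 genes gives 1.56e-5.
#'
#' @param n_genes number of genes tested.
#' @param fwer family-wise error rate in (0, 1).
#' @return per-gene significance level.
#' @export
bonferroni_threshold <- function(n_genes, fwer = 0.05) {
  stopifnot(n_genes >= 1L, fwer > 0, fwer < 1)
  fwer / n_genes
}
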