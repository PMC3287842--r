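# End-to-end orchestration: adjust (optionally), test every gene in every
# replicate with shared per-gene permutation streams, and summarize the
# resulting p-value grids. These two functions are what the analysis
# drivers and the acceptance script call.

#' Run the pooled tests over every gene and replicate
#'
#' For each replicate the trait is (optionally) residualized on the
#' requested covariates, then every gene is tested with the selected
#' tests, all tests of a gene sharing one permutation stream whose seed
#' derives from (`seed`, gene name, replicate) — results are deterministic
#' and independent of processing order. Per-gene burden structures are
#' prepared once and reused across replicates.
#'
#' @param dataset a `sim_dataset`, or `NULL` to pass components
#'   explicitly.
#' @param counts,variants,index,phenotypes components (ignored when
#'   `dataset` is given): folded count matrix, variant table with `maf`,
#'   gene index, and a long phenotype table with a `replicate` column.
#' @param trait phenotype column to analyze.
#' @param tests subset of `c("T1", "T5", "WS", "VT")`.
#' @param adjust_covariates covariate columns to residualize on before
#'   testing (empty vector = unadjusted).
#' @param n_perm Monte-Carlo permutations per gene.
#' @param seed master seed.
#' @param sided `"greater"` or `"two-sided"`.
#' @param mode `"monte-carlo"` or `"exhaustive"`.
#' @param thresholds named MAF cutoffs for the fixed tests.
#' @param genes optional subset of gene names to test.
#' @return long data frame: `replicate`, `gene`, `test`,
#'   `n_variants_used`, `statistic`, `optimal_threshold`,
#'   `n_permutations`, `p_value` (`NA` p-value = not testable).
#' @export
run_association <- function(dataset = NULL, counts = NULL, variants = NULL,
                            index = NULL, phenotypes = NULL, trait,
                            tests = c("T1", "T5", "WS", "VT"),
                            adjust_covariates = character(),
                            n_perm = 999L, seed = 1L,
                            sided = c("greater", "two-sided"),
                            mode = c("monte-carlo", "exhaustive"),
                            thresholds = c(T1 = 0.01, T5 = 0.05),
                            genes = NULL) {
  sided <- match.arg(sided)
  mode <- match.arg(mode)
  if (!is.null(dataset)) {
    counts <- dataset$counts
    variants <- dataset$variants
    index <- dataset$index
    phenotypes <- dataset$phenotypes
  }
  stopifnot(!is.null(counts), !is.null(variants), !is.null(index),
            !is.null(phenotypes), trait %in% names(phenotypes))
  if (is.null(genes)) genes <- names(index)
  plan <- permutation_plan(n_perm = n_perm, seed = seed, mode = mode)

  reps <- sort(unique(phenotypes$replicate))
  y_by_rep <- lapply(reps, function(r) {
    ph <- phenotypes[phenotypes$replicate == r, , drop = FALSE]
    ph <- ph[match(rownames(counts), ph$sample_id), , drop = FALSE]
    if (anyNA(ph$sample_id)) stop("phenotype/genotype sample id mismatch in replicate ", r)
    y <- ph[[trait]]
    if (length(adjust_covariates))
      y <- adjust_phenotype(y, ph[, adjust_covariates, drop = FALSE])
    y
  })

  out <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    vi <- index[[g]]
    prep <- .prep_gene(counts[, vi, drop = FALSE], variants$maf[vi], tests, thresholds)
    rows <- lapply(seq_along(reps), function(ri)
      cbind(replicate = reps[ri],
            .gene_stats(prep, y_by_rep[[ri]], plan, sided, g, replicate = reps[ri])))
    out[[gi]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "manifest") <- list(
    trait = trait, tests = tests, adjust_covariates = adjust_covariates,
    n_perm = as.integer(n_perm), seed = as.integer(seed), sided = sided,
    mode = mode, thresholds = thresholds, genes = genes,
    package_version = as.character(utils::packageVersion("rarepool")))
  res
}

#' Extract the run manifest of an association result
#'
#' The manifest echoes every argument that determines the output (trait,
#' test selection, adjustment covariates, permutation settings, seed,
#' thresholds, gene subset) plus the package version: replaying it on the
#' same dataset reproduces the results exactly. Timestamps are kept out
#' deliberately so repeated runs stay bit-identical.
#'
#' @param results data frame from [run_association()].
#' @return named list of run parameters.
#' @export
run_manifest <- function(results) {
  m <- attr(results, "manifest")
  if (is.null(m)) stop("no manifest attached; was this produced by run_association()?")
  m
}

#' Summarize association results into calibration and power statistics
#'
#' With an empty causal set the summary is a type-I-error table over
#' `alphas`; with causal genes it adds TPP/FPP at each level, the ROC
#' curve over `alpha_grid`, the trapezoid AUC, and the counts `|T_g|`,
#' `|S_g ∩ T_g|`, `|T_g \\ S_g|` per test.
#'
#' @param results long data frame from [run_association()].
#' @param causal_genes character vector (empty = null analysis).
#' @param alphas significance levels for the rate tables.
#' @param alpha_grid levels for the ROC sweep.
#' @return list with elements `rates` (long data frame: `test`, `alpha`,
#'   `metric`, `value`), `summary` (per test: universe size, causal in
#'   universe, AUC when applicable), and `roc` (named list of ROC data
#'   frames, power analyses only).
#' @export
run_evaluation <- function(results, causal_genes = character(),
                           alphas = c(0.001, 0.005, 0.01, 0.05, 0.1),
                           alpha_grid = default_alpha_grid()) {
  grids <- pvalue_grid(results)
  rates <- list()
  roc_list <- list()
  summ <- list()
  for (tn in names(grids)) {
    g <- grids[[tn]]
    universe <- rownames(g)[rowSums(!is.na(g)) > 0L]
    if (!length(causal_genes)) {
      t1 <- type1_error(g, alphas)
      rates[[tn]] <- data.frame(test = tn, alpha = alphas, metric = "type1",
                                value = t1, stringsAsFactors = FALSE)
      summ[[tn]] <- data.frame(test = tn, universe_size = length(universe),
                               causal_in_universe = 0L, auc = NA_real_,
                               stringsAsFactors = FALSE)
    } else {
      tpp <- true_positive_proportion(g, causal_genes, alphas)
      fpp <- false_positive_proportion(g, causal_genes, alphas)
      roc <- roc_curve(g, causal_genes, alpha_grid)
      rates[[tn]] <- rbind(
        data.frame(test = tn, alpha = alphas, metric = "tpp", value = as.numeric(tpp),
                   stringsAsFactors = FALSE),
        data.frame(test = tn, alpha = alphas, metric = "fpp", value = fpp,
                   stringsAsFactors = FALSE))
      roc_list[[tn]] <- roc
      summ[[tn]] <- data.frame(
        test = tn, universe_size = length(universe),
        causal_in_universe = length(intersect(universe, causal_genes)),
        auc = auc(roc), stringsAsFactors = FALSE)
    }
  }
  list(rates = do.call(rbind, c(rates, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       roc = roc_list)
}
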