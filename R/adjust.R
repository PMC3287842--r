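# Two-stage covariate adjustment: regress each phenotype on the
# covariates by ordinary least squares and carry the residuals forward as
# the adjusted phenotype. Binary traits are residualized through the same
# linear model — the downstream tests are linear-score tests for every
# trait type, so the adjustment matches the analysis model.

#' Residualize a phenotype on covariates
#'
#' Ordinary-least-squares residuals of `y` on an intercept plus the
#' covariate columns; the residuals are the adjusted phenotype. With no
#' covariates this reduces to mean-centering, which changes no permutation
#' p-value (the score statistic is centering invariant) but lets adjusted
#' and unadjusted analyses share one code path. Residualization is a
#' projection: applying it twice equals applying it once, and a vector
#' already orthogonal to the covariate span passes through unchanged.
#'
#' @param y phenotype vector (quantitative or 0/1; both are treated
#'   linearly).
#' @param covariates data frame or matrix of covariate columns aligned to
#'   `y`, or `NULL` for intercept-only centering.
#' @return numeric vector of residuals.
#' @export
adjust_phenotype <- function(y, covariates = NULL) {
  n <- length(y)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(covariates) == n)
    X <- cbind("(Intercept)" = 1, covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  as.vector(qr.resid(qx, y))
}

#' Residualize every trait of a phenotype table
#'
#' Applies [adjust_phenotype()] to each declared trait column (quantitative
#' and binary alike), separately within each replicate when a replicate
#' column is declared — each replicate is an independent phenotype
#' realization, so the regression is refit per replicate. Covariate
#' columns are retained and recorded as consumed in the
#' `adjusted_covariates` attribute.
#'
#' @param phenotypes a table from [read_phenotypes()] or
#'   [simulate_traits()] (attributes `traits`, `binary_traits`,
#'   `covariates`, `replicate_col` declare column roles).
#' @param covariate_names covariates to adjust for; the empty vector
#'   mean-centers every trait.
#' @return the table with trait columns replaced by residuals.
#' @export
adjust_table <- function(phenotypes, covariate_names = character()) {
  covs_avail <- attr(phenotypes, "covariates")
  unknown <- setdiff(covariate_names, covs_avail)
  if (length(unknown))
    stop("unknown covariates: ", paste(unknown, collapse = ", "),
         " (declared: ", paste(covs_avail, collapse = ", "), ")")
  trait_cols <- c(attr(phenotypes, "traits"), attr(phenotypes, "binary_traits"))
  rep_col <- attr(phenotypes, "replicate_col")
  groups <- if (is.null(rep_col)) list(seq_len(nrow(phenotypes)))
            else split(seq_len(nrow(phenotypes)), phenotypes[[rep_col]])
  for (tr in trait_cols) {
    for (g in groups) {
      cv <- if (length(covariate_names))
        phenotypes[g, covariate_names, drop = FALSE] else NULL
      phenotypes[[tr]][g] <- adjust_phenotype(phenotypes[[tr]][g], cv)
    }
  }
  attr(phenotypes, "adjusted_covariates") <- covariate_names
  phenotypes
}
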