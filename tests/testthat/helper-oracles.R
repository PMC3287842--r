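# Independent naive oracles. These deliberately avoid the package's
# vectorized code paths: plain loops, a different permutation enumerator,
# and direct transcriptions of the defining formulas.

# Allele-frequency tally by explicit per-sample, per-allele loop.
oracle_maf <- function(counts) {
  m <- ncol(counts)
  maf <- numeric(m)
  for (i in seq_len(m)) {
    minor <- 0L
    total <- 0L
    for (j in seq_len(nrow(counts))) {
      minor <- minor + counts[j, i]
      total <- total + 2L
    }
    f <- minor / total
    maf[i] <- min(f, 1 - f)
  }
  maf
}

# Gene membership by double-loop interval check.
oracle_gene_map <- function(variants, regions) {
  out <- list()
  for (g in seq_len(nrow(regions))) {
    hits <- integer(0)
    for (v in seq_len(nrow(variants))) {
      if (variants$chrom[v] == regions$chrom[g] &&
          variants$pos[v] >= regions$start[g] &&
          variants$pos[v] <= regions$end[g]) hits <- c(hits, v)
    }
    out[[regions$gene_name[g]]] <- hits
  }
  out
}

# Weighted burden by double loop.
oracle_burden <- function(counts, w) {
  n <- nrow(counts)
  C <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(ncol(counts))) s <- s + w[i] * counts[j, i]
    C[j] <- s
  }
  C
}

# Score z by direct transcription of the formula.
oracle_z <- function(C, y) {
  n <- length(y)
  ybar <- sum(y) / n
  sdy <- sqrt(sum((y - ybar)^2) / n)
  ss <- sum((C - sum(C) / n)^2)
  if (ss == 0) return(0)
  num <- 0
  for (j in seq_len(n)) num <- num + C[j] * (y[j] - ybar)
  num / (sdy * sqrt(ss))
}

# All permutations of 1:n via repeated next-permutation in lexicographic
# order (a different algorithm from the package's recursive builder).
oracle_perms <- function(n) {
  perm <- seq_len(n)
  out <- matrix(0L, n, factorial(n))
  k <- 1L
  out[, 1L] <- perm
  repeat {
    i <- n - 1L
    while (i >= 1L && perm[i] >= perm[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (perm[j] <= perm[i]) j <- j - 1L
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    perm[(i + 1L):n] <- rev(perm[(i + 1L):n])
    k <- k + 1L
    out[, k] <- perm
  }
  out
}

# Brute-force exhaustive permutation test for one gene. `test` is one of
# "T1", "T5", "WS", "VT"; fixed thresholds 0.01 / 0.05. Monomorphic
# variants are dropped, p is the add-one count over all n! phenotype
# orderings, with the same tie tolerance the package documents (burden
# statistics tie exactly under within-group permutations).
oracle_gene_test <- function(counts_g, mafs, y, test, tol = 1e-9) {
  keep <- mafs > 0
  counts_g <- counts_g[, keep, drop = FALSE]
  mafs <- mafs[keep]
  n <- length(y)
  stat_fun <- if (test == "VT") {
    cand <- sort(unique(mafs))
    function(yy) {
      zz <- sapply(cand, function(t) {
        oracle_z(oracle_burden(counts_g, as.numeric(mafs <= t)), yy)
      })
      list(stat = max(zz), opt = cand[which.max(zz)])
    }
  } else {
    w <- switch(test,
                T1 = as.numeric(mafs < 0.01),
                T5 = as.numeric(mafs < 0.05),
                WS = 1 / sqrt(n * mafs * (1 - mafs)))
    if (all(w == 0)) return(list(testable = FALSE))
    function(yy) list(stat = oracle_z(oracle_burden(counts_g, w), yy), opt = NA)
  }
  obs <- stat_fun(y)
  perms <- oracle_perms(n)
  hits <- 0L
  for (k in seq_len(ncol(perms))) {
    sk <- stat_fun(y[perms[, k]])$stat
    if (sk >= obs$stat - tol) hits <- hits + 1L
  }
  list(testable = TRUE, stat = obs$stat, opt = obs$opt,
       p = (1L + hits) / (1L + ncol(perms)))
}

# Small deterministic gene fixture: n samples, m variants with assorted
# counts, plus a quantitative phenotype with distinct values.
make_toy_gene <- function(n = 6L, m = 3L, seed = 42L) {
  set.seed(seed)
  counts <- matrix(rbinom(n * m, 2, 0.3), n, m,
                   dimnames = list(sprintf("s%02d", 1:n), sprintf("v%02d", 1:m)))
  counts <- rarepool:::fold_minor(counts)
  y <- round(rnorm(n), 3)
  list(counts = counts, mafs = colSums(counts) / (2 * n), y = y)
}

# Assemble a full test-ready dataset around one gene's counts.
wrap_gene <- function(counts, mafs = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("v%02d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  variants <- data.frame(variant_id = colnames(counts), chrom = "1",
                         pos = seq_len(ncol(counts)) * 100L,
                         stringsAsFactors = FALSE)
  variants <- compute_maf(counts, variants)
  regions <- data.frame(gene_name = "g1", chrom = "1", start = 1L,
                        end = 100000L, stringsAsFactors = FALSE)
  index <- map_variants_to_genes(variants, regions)
  list(counts = counts, variants = variants, index = index)
}
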