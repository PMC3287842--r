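# Readers/writers for the plain-text dialects used throughout: a
# tab-separated genotype count matrix (+ companion variant table), a
# minimal biallelic-SNP VCF, 1-based inclusive gene regions, phenotype
# tables, and per-gene test results. Counts always tally the minor allele
# (folded at load time), so every entry is in {0, 1, 2}.

#' Read a genotype count matrix
#'
#' Loads minor-allele counts for `n_samples x n_variants`. Two dialects are
#' supported:
#' \describe{
#'   \item{`matrix-tsv`}{tab-separated; header `sample_id` followed by
#'     variant ids; one row per sample; cells in \{0, 1, 2\}. An optional
#'     companion variant table (`variant_path`, columns `variant_id`,
#'     `chrom`, `pos`) supplies coordinates.}
#'   \item{`vcf-minimal`}{a VCFv4.x file restricted to biallelic SNP
#'     records; the GT field is converted to alternate-allele counts
#'     (FILTER is ignored). Multi-allelic or indel records are rejected.}
#' }
#' Counts are re-polarized so that columns tally the minor allele in the
#' loaded sample (a column with allele frequency above 0.5 is replaced by
#' `2 - counts`). Missing genotypes are an error unless
#' `missing_policy = "zero"`, which imputes homozygous major (count 0) and
#' emits a message.
#'
#' @param path file to read.
#' @param format `"matrix-tsv"` or `"vcf-minimal"`.
#' @param variant_path optional companion variant table for `matrix-tsv`.
#' @param missing_policy `"error"` (default) or `"zero"`.
#' @return A list with `counts` (integer matrix, sample ids as rownames,
#'   variant ids as colnames) and `variants` (data frame with `variant_id`,
#'   `chrom`, `pos`, and `maf` left `NA` until [compute_maf()]).
#' @seealso [compute_maf()], [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("matrix-tsv", "vcf-minimal"),
                           variant_path = NULL,
                           missing_policy = c("error", "zero")) {
  format <- match.arg(format)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix-tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 1L || names(tab)[1L] != "sample_id")
      stop("matrix-tsv genotype file must start with a 'sample_id' column")
    sample_ids <- as.character(tab[[1L]])
    counts <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(counts) <- "double"
    rownames(counts) <- sample_ids
    vid0 <- colnames(counts)
    if (is.null(vid0)) vid0 <- character(0)
    variants <- data.frame(variant_id = vid0,
                           chrom = rep(NA_character_, ncol(counts)),
                           pos = rep(NA_integer_, ncol(counts)),
                           maf = rep(NA_real_, ncol(counts)),
                           stringsAsFactors = FALSE)
    if (!is.null(variant_path)) {
      vt <- read.delim(variant_path, stringsAsFactors = FALSE)
      need <- c("variant_id", "chrom", "pos")
      if (!all(need %in% names(vt)))
        stop("variant table must have columns: ", paste(need, collapse = ", "))
      if (!setequal(vt$variant_id, colnames(counts)))
        stop("variant table ids do not match genotype columns")
      vt <- vt[match(colnames(counts), vt$variant_id), , drop = FALSE]
      variants <- data.frame(variant_id = vt$variant_id,
                             chrom = as.character(vt$chrom),
                             pos = as.integer(vt$pos),
                             maf = NA_real_, stringsAsFactors = FALSE)
    }
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                         dimnames = list(NULL, names(fix)))
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    bad <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
    if (any(bad))
      stop("vcf-minimal accepts biallelic SNPs only; offending records: ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    cnt <- (a1 == "1") + (a2 == "1")
    cnt[a1 == "." | a2 == "."] <- NA_real_
    counts <- t(cnt)                      # samples x variants
    vid <- fix$ID
    vid[is.na(vid) | vid == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(vid) | vid == "."]
    colnames(counts) <- vid
    variants <- data.frame(variant_id = vid, chrom = as.character(fix$CHROM),
                           pos = as.integer(fix$POS), maf = NA_real_,
                           stringsAsFactors = FALSE)
  }
  if (anyNA(counts)) {
    if (missing_policy == "error")
      stop("missing genotypes present and missing_policy = 'error'")
    message("imputing ", sum(is.na(counts)), " missing genotypes as 0 (homozygous major)")
    counts[is.na(counts)] <- 0
  }
  if (!all(counts %in% c(0, 1, 2)))
    stop("genotype counts outside {0,1,2}: first offending cell at index ",
         which(!(counts %in% c(0, 1, 2)))[1L])
  if (nrow(counts) < 2L) stop("need at least 2 samples")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant ids: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]), collapse = ", "))
  counts <- fold_minor(counts)
  list(counts = counts, variants = variants)
}

# Re-polarize columns so counts tally the minor allele (frequency <= 0.5).
fold_minor <- function(counts) {
  if (ncol(counts) == 0L) return(counts)
  f <- colSums(counts) / (2 * nrow(counts))
  flip <- f > 0.5
  if (any(flip)) counts[, flip] <- 2 - counts[, flip]
  counts
}

#' Compute minor-allele frequencies from a count matrix
#'
#' `maf_i = min(f_i, 1 - f_i)` with `f_i = sum_j counts_ji / (2 n)`: the
#' folded allele frequency estimated from all loaded samples pooled
#' (cases and controls together; there is no external reference panel).
#'
#' @param counts samples x variants minor-allele count matrix.
#' @param variants optional variant data frame to fill; created minimally
#'   when `NULL`.
#' @return the variant data frame with its `maf` column filled.
#' @export
compute_maf <- function(counts, variants = NULL) {
  if (nrow(counts) == 0L) stop("cannot compute MAF from 0 samples")
  f <- colSums(counts) / (2 * nrow(counts))
  maf <- pmin(f, 1 - f)
  if (is.null(variants)) {
    if (is.null(colnames(counts)))
      colnames(counts) <- sprintf("v%d", seq_len(ncol(counts)))
    variants <- data.frame(variant_id = colnames(counts),
                           chrom = NA_character_, pos = NA_integer_,
                           stringsAsFactors = FALSE)
  }
  stopifnot(nrow(variants) == ncol(counts))
  variants$maf <- unname(maf)
  variants
}

#' Read gene regions
#'
#' Tab-separated file with columns `gene_name`, `chrom`, `start`, `end`.
#' Coordinates are 1-based with both ends inclusive — a deliberate
#' divergence from 0-based half-open BED (the column order differs too).
#'
#' @param path file to read.
#' @return data frame of regions.
#' @export
read_gene_regions <- function(path) {
  reg <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_name", "chrom", "start", "end")
  if (!all(need %in% names(reg)))
    stop("gene region file must have columns: ", paste(need, collapse = ", "))
  reg$chrom <- as.character(reg$chrom)
  reg$start <- as.integer(reg$start)
  reg$end <- as.integer(reg$end)
  if (any(reg$start > reg$end)) stop("region with start > end")
  if (anyDuplicated(reg$gene_name))
    stop("duplicate gene names: ",
         paste(unique(reg$gene_name[duplicated(reg$gene_name)]), collapse = ", "))
  reg[, need]
}

#' Map variants to gene regions
#'
#' A variant belongs to gene `g` iff its chromosome matches and
#' `start <= pos <= end` (both ends inclusive). A variant inside two
#' overlapping regions appears under both. Genes with no member variants
#' are retained with an empty index; they are excluded later, per test.
#'
#' @param variants data frame with `variant_id`, `chrom`, `pos`.
#' @param regions data frame of gene regions (see [read_gene_regions()]).
#' @return named list: gene name -> ordered integer vector of variant row
#'   indices into `variants`.
#' @export
map_variants_to_genes <- function(variants, regions) {
  if (nrow(regions) == 0L) stop("regions must be non-empty")
  if (anyDuplicated(regions$gene_name))
    stop("duplicate gene names: ",
         paste(unique(regions$gene_name[duplicated(regions$gene_name)]), collapse = ", "))
  idx <- lapply(seq_len(nrow(regions)), function(i) {
    which(variants$chrom == regions$chrom[i] &
            variants$pos >= regions$start[i] &
            variants$pos <= regions$end[i])
  })
  names(idx) <- regions$gene_name
  idx
}

#' Read a phenotype table
#'
#' Tab-separated with a header; the caller declares which columns are
#' quantitative traits, binary traits, covariates, and (optionally) the
#' replicate id. Binary columns must contain only 0/1. When genotype
#' sample ids are supplied the join is validated in both directions and
#' offenders are listed.
#'
#' @param path file to read.
#' @param traits,binary_traits,covariates character vectors of column names.
#' @param replicate_col optional replicate id column name.
#' @param sample_ids optional genotype sample ids to validate against.
#' @return data frame with attributes `traits`, `binary_traits`,
#'   `covariates`, `replicate_col` recording the roles.
#' @export
read_phenotypes <- function(path, traits = character(), binary_traits = character(),
                            covariates = character(), replicate_col = NULL,
                            sample_ids = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  declared <- c("sample_id", traits, binary_traits, covariates, replicate_col)
  missing_cols <- setdiff(declared, names(tab))
  if (length(missing_cols))
    stop("phenotype file lacks declared columns: ", paste(missing_cols, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  for (b in binary_traits) {
    if (!all(tab[[b]] %in% c(0, 1)))
      stop("binary trait '", b, "' contains values outside {0,1}")
  }
  if (!is.null(sample_ids)) {
    extra <- setdiff(unique(tab$sample_id), sample_ids)
    absent <- setdiff(sample_ids, unique(tab$sample_id))
    if (length(extra) || length(absent))
      stop("sample id mismatch between phenotypes and genotypes; ",
           "in phenotypes only: [", paste(extra, collapse = ", "),
           "]; in genotypes only: [", paste(absent, collapse = ", "), "]")
  }
  structure(tab, traits = traits, binary_traits = binary_traits,
            covariates = covariates, replicate_col = replicate_col)
}

#' Write per-gene test results
#'
#' One row per (gene, test), sorted by gene then test name, tab-separated
#' with columns `gene`, `test`, `n_variants_used`, `statistic`,
#' `optimal_threshold` (empty unless VT), `n_permutations`, `p_value`.
#' Not-testable genes carry empty `statistic` and `p_value`.
#'
#' @param results data frame as produced by [run_association()] (a
#'   `replicate` column, if present, is written too).
#' @param path output file.
#' @export
write_results <- function(results, path) {
  need <- c("gene", "test", "n_variants_used", "statistic",
            "optimal_threshold", "n_permutations", "p_value")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  cols <- c(intersect("replicate", names(results)), need)
  results <- results[order(results$gene, results$test), cols, drop = FALSE]
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(NULL)
}

#' Read a results file written by [write_results()]
#' @param path file to read.
#' @return data frame; empty cells become `NA`.
#' @export
read_results <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Write a genotype matrix (and optional variant table) in matrix-tsv dialect
#' @param counts samples x variants count matrix with dimnames.
#' @param path genotype file to write.
#' @param variants,variant_path optional variant table and its destination.
#' @export
write_genotypes <- function(counts, path, variants = NULL, variant_path = NULL) {
  tab <- data.frame(sample_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(variants) && !is.null(variant_path))
    write.table(variants[, c("variant_id", "chrom", "pos")], variant_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write a phenotype table
#' @param phenotypes data frame.
#' @param path output file.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write gene regions
#' @param regions data frame with `gene_name`, `chrom`, `start`, `end`.
#' @param path output file.
#' @export
write_gene_regions <- function(regions, path) {
  write.table(regions[, c("gene_name", "chrom", "start", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write the causal-truth table of a simulated dataset
#' @param truth data frame with `gene_name`, `variant_id`, `effect_size`.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  write.table(truth[, c("gene_name", "variant_id", "effect_size")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
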