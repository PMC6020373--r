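#' Expression matrix container
#'
#' Genes x samples numeric matrix plus gene annotations and a unit tag that
#' tracks how the values were produced (`"raw_count"`, `"fpkm"`,
#' `"log_normalized"` or `"zscore"`). Unit transitions happen only through
#' the declared operations (`compute_fpkm()`, `normalize_expression()`,
#' `zscore_expression()`, `adjust_latent_factors()`).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `stop`
#'   and optionally `length` (transcript length in bp; defaults to
#'   `stop - start + 1`). One row per row of `values`.
#' @param unit unit tag for `values`.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, genes = NULL,
                              unit = c("raw_count", "fpkm",
                                       "log_normalized", "zscore")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (is.null(genes)) {
    genes <- data.frame(gene_id = rownames(values), chrom = NA_character_,
                        start = NA_integer_, stop = NA_integer_,
                        length = NA_integer_, stringsAsFactors = FALSE)
  } else {
    genes <- as.data.frame(genes)
    stopifnot(all(c("gene_id", "chrom", "start", "stop") %in% names(genes)))
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in annotation")
    genes <- genes[match(rownames(values), genes$gene_id), , drop = FALSE]
    if (anyNA(genes$gene_id))
      stop("gene annotation missing for: ",
           paste(head(setdiff(rownames(values), genes$gene_id)), collapse = ", "))
    if (is.null(genes$length)) genes$length <- genes$stop - genes$start + 1L
    rownames(genes) <- NULL
  }
  structure(list(values = values, genes = genes, unit = unit),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
expr_values <- function(x) x$values

#' @rdname expression_matrix
#' @export
gene_anno <- function(x) x$genes

#' Subset an ExpressionMatrix by gene and/or sample ids
#'
#' @param x an `ExpressionMatrix`.
#' @param genes,samples character vectors of ids to keep (NULL = keep all).
#' @return subsetted `ExpressionMatrix`.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(x$values)) else {
    idx <- match(genes, rownames(x$values))
    if (anyNA(idx)) stop("unknown gene ids: ",
                         paste(head(genes[is.na(idx)]), collapse = ", "))
    idx
  }
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else {
    idx <- match(samples, colnames(x$values))
    if (anyNA(idx)) stop("unknown sample ids: ",
                         paste(head(samples[is.na(idx)]), collapse = ", "))
    idx
  }
  expression_matrix(x$values[gi, si, drop = FALSE],
                    x$genes[gi, , drop = FALSE], unit = x$unit)
}

#' Per-gene z-score transform
#'
#' Standardizes every gene to mean 0, SD 1 across samples. Genes with zero
#' variance are set to 0 and reported via the `"constant_genes"` attribute.
#'
#' @param x an `ExpressionMatrix` (any unit).
#' @return `ExpressionMatrix` with unit `"zscore"`.
#' @export
zscore_expression <- function(x) {
  v <- x$values
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  z <- (v - mu) / s
  z[const, ] <- 0
  out <- expression_matrix(z, x$genes, unit = "zscore")
  attr(out, "constant_genes") <- rownames(v)[const]
  out
}

#' Genotype matrix container
#'
#' SNPs x samples additive dosage matrix (0/1/2, NA = missing) plus SNP
#' annotations (position, ref/alt alleles). Per-SNP minor allele frequency
#' and missing rate are computed on demand.
#'
#' @param dosages numeric matrix, SNPs in rows (rownames = SNP ids), samples
#'   in columns; entries in 0/1/2 or NA.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`. One row per row of `dosages`.
#' @return a `GenotypeMatrix` object.
#' @export
genotype_matrix <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) && nrow(dosages) > 0)
    stop("dosages must have SNP ids as rownames")
  if (is.null(colnames(dosages))) stop("dosages must have sample ids as colnames")
  snps <- as.data.frame(snps)
  stopifnot(all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(snps)))
  snps <- snps[match(rownames(dosages), snps$snp_id), , drop = FALSE]
  if (anyNA(snps$snp_id)) stop("SNP annotation missing for some dosage rows")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  rownames(snps) <- NULL
  structure(list(dosages = dosages, snps = snps), class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d samples (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosages)

#' @rdname genotype_matrix
#' @param x a `GenotypeMatrix`.
#' @export
geno_dosages <- function(x) x$dosages

#' @rdname genotype_matrix
#' @export
snp_anno <- function(x) x$snps

#' Per-SNP minor allele frequency
#'
#' Computed from non-missing dosages; always folded to `[0, 0.5]`.
#'
#' @param x a `GenotypeMatrix`.
#' @return named numeric vector of MAFs.
#' @export
snp_maf <- function(x) {
  af <- rowMeans(x$dosages, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  pmin(af, 1 - af)
}

#' Per-SNP missing-data rate
#'
#' @param x a `GenotypeMatrix`.
#' @return named numeric vector of missing fractions.
#' @export
snp_missing_rate <- function(x) rowMeans(is.na(x$dosages))

#' Subset a GenotypeMatrix by SNP and/or sample ids
#'
#' @param x a `GenotypeMatrix`.
#' @param snps,samples character vectors of ids to keep (NULL = keep all).
#' @return subsetted `GenotypeMatrix`.
#' @export
subset_genotypes <- function(x, snps = NULL, samples = NULL) {
  ri <- if (is.null(snps)) seq_len(nrow(x$dosages)) else {
    idx <- match(snps, rownames(x$dosages))
    if (anyNA(idx)) stop("unknown SNP ids")
    idx
  }
  ci <- if (is.null(samples)) seq_len(ncol(x$dosages)) else {
    idx <- match(samples, colnames(x$dosages))
    if (anyNA(idx)) stop("unknown sample ids")
    idx
  }
  genotype_matrix(x$dosages[ri, ci, drop = FALSE], x$snps[ri, , drop = FALSE])
}
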