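#' Compute FPKM from raw counts
#'
#' FPKM = count / (gene length in kb x library size in millions). Library
#' size is the per-sample column sum of counts.
#'
#' @param counts [expression_matrix()] with unit `"raw_count"` and gene
#'   lengths in the annotation.
#' @param lib_sizes optional per-sample library sizes (total mapped
#'   reads). Defaults to the column sums, or to the `"library_sizes"`
#'   attribute if a filtering step recorded the pre-filter totals.
#' @return [expression_matrix()] with unit `"fpkm"`.
#' @export
compute_fpkm <- function(counts, lib_sizes = NULL) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (counts$unit != "raw_count") stop("compute_fpkm expects raw counts")
  len <- counts$genes$length
  if (anyNA(len) || any(len <= 0))
    stop("missing gene length for: ",
         paste(head(counts$genes$gene_id[is.na(len) | len <= 0]), collapse = ", "))
  lib <- lib_sizes %||% attr(counts, "library_sizes") %||%
    colSums(counts$values)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(head(colnames(counts$values)[lib == 0]), collapse = ", "))
  fpkm <- counts$values / (len / 1e3) %o% (lib / 1e6)
  expression_matrix(fpkm, counts$genes, unit = "fpkm")
}

#' Filter to expressed genes
#'
#' Keeps a gene iff the number of samples with count > `min_count` exceeds
#' `min_individuals` AND its FPKM exceeds `min_fpkm` (by default the mean
#' FPKM across samples; `fpkm_rule = "any"` instead requires at least one
#' sample above the threshold). Thresholds follow the common whole-blood
#' RNA-seq practice of >10 individuals with >6 reads and FPKM > 0.1.
#'
#' @param counts raw-count [expression_matrix()] with gene lengths.
#' @param min_individuals strict lower bound on the number of samples
#'   exceeding `min_count`.
#' @param min_count strict per-sample count threshold.
#' @param min_fpkm strict FPKM threshold.
#' @param fpkm_rule `"mean"` (default) or `"any"`.
#' @return filtered raw-count [expression_matrix()]; the drop report (gene,
#'   kept flag, reason) is in `attr(, "filter_report")` and the original
#'   library sizes in `attr(, "library_sizes")` (FPKM is defined against
#'   total mapped reads, so refiltering reuses them — the filter is
#'   idempotent).
#' @export
filter_expressed_genes <- function(counts, min_individuals = 10,
                                   min_count = 6, min_fpkm = 0.1,
                                   fpkm_rule = c("mean", "any")) {
  stopifnot(is(counts, "ExpressionMatrix"), counts$unit == "raw_count")
  fpkm_rule <- match.arg(fpkm_rule)
  lib_sizes <- attr(counts, "library_sizes") %||% colSums(counts$values)
  if (nrow(counts$values) == 0) return(counts)
  fpkm <- compute_fpkm(counts, lib_sizes)$values
  n_expressed <- rowSums(counts$values > min_count)
  pass_count <- n_expressed > min_individuals
  fpkm_stat <- if (fpkm_rule == "mean") rowMeans(fpkm) else
    apply(fpkm, 1, max)
  pass_fpkm <- fpkm_stat > min_fpkm
  keep <- pass_count & pass_fpkm
  reason <- rep("kept", nrow(counts$values))
  reason[!pass_count & pass_fpkm] <- "too_few_expressed_samples"
  reason[pass_count & !pass_fpkm] <- "low_fpkm"
  reason[!pass_count & !pass_fpkm] <- "too_few_expressed_samples;low_fpkm"
  report <- data.frame(gene_id = rownames(counts$values), kept = keep,
                       n_samples_over_count = n_expressed,
                       fpkm_stat = fpkm_stat, reason = reason,
                       stringsAsFactors = FALSE)
  out <- expression_matrix(counts$values[keep, , drop = FALSE],
                           counts$genes[keep, , drop = FALSE],
                           unit = "raw_count")
  attr(out, "filter_report") <- report
  attr(out, "library_sizes") <- lib_sizes
  out
}

#' Log-CPM normalization
#'
#' `log2(counts-per-million + pseudocount)` with per-sample library-size
#' scaling; exactly scale-invariant (samples with proportional counts get
#' identical profiles). A simple linear-model-friendly stand-in for
#' count-model normalizations; the unit tag records the transform.
#'
#' @param counts raw-count [expression_matrix()].
#' @param pseudocount added on the CPM scale before log2 (default 1).
#' @return [expression_matrix()] with unit `"log_normalized"`.
#' @export
normalize_expression <- function(counts, pseudocount = 1) {
  stopifnot(is(counts, "ExpressionMatrix"), counts$unit == "raw_count")
  if (nrow(counts$values) == 0 || ncol(counts$values) == 0)
    stop("empty count matrix")
  lib <- colSums(counts$values)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(head(colnames(counts$values)[lib == 0]), collapse = ", "))
  cpm <- sweep(counts$values, 2, lib / 1e6, "/")
  expression_matrix(log2(cpm + pseudocount), counts$genes,
                    unit = "log_normalized")
}

#' Remove latent expression factors while protecting known variables
#'
#' Surrogate-variable-style adjustment in two documented steps:
#' (1) each gene is regressed on the protected design (disease sub-type and
#' any covariates to preserve) and the top `n_factors` principal components
#' of the residual matrix are taken as latent factors; (2) each gene is
#' refit jointly on protected design + latent factors and only the latent
#' factor contribution is subtracted, so protected group structure is
#' retained up to numerical tolerance.
#'
#' @param expr log-normalized [expression_matrix()].
#' @param protected data.frame of protected variables (factors/numeric),
#'   rows aligned with the expression samples.
#' @param n_factors number of latent factors to estimate and remove
#'   (default 15, a typical choice for ~200-sample whole-blood studies).
#' @return adjusted [expression_matrix()] (same unit, genes and samples);
#'   the estimated factors are in `attr(, "latent_factors")`.
#' @export
adjust_latent_factors <- function(expr, protected, n_factors = 15) {
  stopifnot(is(expr, "ExpressionMatrix"))
  Y <- expr$values                       # genes x samples
  n <- ncol(Y)
  protected <- as.data.frame(protected)
  if (nrow(protected) != n)
    stop("protected design must have one row per sample")
  # single-level factors carry no protectable structure; drop them
  keep <- vapply(protected, function(x)
    !is.factor(x) && !is.character(x) ||
      length(unique(x)) > 1, logical(1))
  protected <- protected[, keep, drop = FALSE]
  M <- if (ncol(protected) > 0) model.matrix(~ ., data = protected)
       else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    aliased <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("collinear protected design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  if (n_factors < 0) stop("n_factors must be >= 0")
  if (n_factors == 0) return(expr)
  if (n_factors >= min(n - qrM$rank, nrow(Y)))
    stop("n_factors must be < min(samples - rank(design), genes)")
  # step 1: residualize on protected design, PCA of residuals
  R <- t(qr.resid(qrM, t(Y)))
  sv <- svd(R, nu = 0, nv = n_factors)
  F_lat <- sv$v[, seq_len(n_factors), drop = FALSE]
  colnames(F_lat) <- sprintf("LF%02d", seq_len(n_factors))
  rownames(F_lat) <- colnames(Y)
  # step 2: joint fit, subtract only the latent-factor component
  X <- cbind(M, F_lat)
  B <- solve(crossprod(X), crossprod(X, t(Y)))
  idx <- (ncol(M) + 1):ncol(X)
  adj <- Y - t(F_lat %*% B[idx, , drop = FALSE])
  out <- expression_matrix(adj, expr$genes, unit = expr$unit)
  attr(out, "latent_factors") <- F_lat
  out
}

#' Genotype QC thresholds
#'
#' Standard variant-level filters: biallelic sites only, Hardy-Weinberg
#' equilibrium p >= `hwe_p_min`, minor allele frequency >= `maf_min`,
#' missing rate <= `missing_max`. Defaults are the common PLINK-style
#' choices (HWE p < 1e-3, MAF < 1%, missingness > 5% removed).
#'
#' @param hwe_p_min,maf_min,missing_max numeric thresholds in `[0, 1]`.
#' @param biallelic_only drop non-biallelic sites.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-3, maf_min = 0.01,
                          missing_max = 0.05, biallelic_only = TRUE) {
  vals <- c(hwe_p_min, maf_min, missing_max)
  if (any(vals < 0 | vals > 1)) stop("thresholds must be probabilities")
  structure(list(hwe_p_min = hwe_p_min, maf_min = maf_min,
                 missing_max = missing_max, biallelic_only = biallelic_only),
            class = "qc_thresholds")
}

#' Genotype quality control
#'
#' Applies the [qc_thresholds()] filters. The HWE test is exact when any
#' expected genotype-class count is below 5, otherwise chi-square (1 df).
#' Dosages are expected as rounded 0/1/2 calls; the HWE and MAF statistics
#' use non-missing calls only.
#'
#' @param geno a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return filtered [genotype_matrix()]; per-filter drop counts and the
#'   per-SNP decision table are in `attr(, "qc_report")`. If every SNP is
#'   dropped a warning is raised and an empty matrix returned.
#' @export
qc_genotypes <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(is(geno, "GenotypeMatrix"), is(thresholds, "qc_thresholds"))
  d <- geno$dosages
  biallelic <- !grepl(",", geno$snps$alt) & nchar(geno$snps$ref) == 1 &
    nchar(geno$snps$alt) == 1 & geno$snps$alt != "."
  n0 <- rowSums(d == 0, na.rm = TRUE)
  n1 <- rowSums(d == 1, na.rm = TRUE)
  n2 <- rowSums(d == 2, na.rm = TRUE)
  hwe_p <- vapply(seq_len(nrow(d)),
                  function(i) hwe_test(n0[i], n1[i], n2[i]), numeric(1))
  maf <- snp_maf(geno)
  miss <- snp_missing_rate(geno)
  pass_bi <- if (thresholds$biallelic_only) biallelic else TRUE
  pass_hwe <- hwe_p >= thresholds$hwe_p_min
  pass_maf <- maf >= thresholds$maf_min
  pass_miss <- miss <= thresholds$missing_max
  keep <- pass_bi & pass_hwe & pass_maf & pass_miss
  report <- list(
    n_input = nrow(d),
    n_kept = sum(keep),
    dropped = c(non_biallelic = sum(!pass_bi),
                hwe = sum(!pass_hwe),
                maf = sum(!pass_maf),
                missing = sum(!pass_miss)),
    table = data.frame(snp_id = rownames(d), hwe_p = hwe_p, maf = maf,
                       missing_rate = miss, biallelic = biallelic,
                       kept = keep, stringsAsFactors = FALSE))
  if (!any(keep)) {
    warning("all SNPs removed by QC")
    out <- genotype_matrix(d[keep, , drop = FALSE],
                           geno$snps[keep, , drop = FALSE])
  } else {
    out <- genotype_matrix(d[keep, , drop = FALSE],
                           geno$snps[keep, , drop = FALSE])
  }
  attr(out, "qc_report") <- report
  out
}
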