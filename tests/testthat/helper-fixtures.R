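# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# small six-group cohort config (scaled-down counts, same group structure)
small_config <- function(seed = 1, ...) {
  sim_config(n_samples_per_group = c(control = 12, oligoJIA = 20,
                                     polyJIA = 20, sJIA = 15,
                                     CD = 25, UC = 10),
             n_genes = 200, n_snps = 300, seed = seed, ...)
}

# toy count matrix with controllable library sizes and gene lengths
toy_counts <- function(counts, lengths = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- samples %||%
      sprintf("S%02d", seq_len(ncol(counts)))
  if (is.null(lengths)) lengths <- rep(1000L, nrow(counts))
  genes <- data.frame(gene_id = rownames(counts), chrom = "chr1",
                      start = seq_len(nrow(counts)) * 10000L,
                      stop = seq_len(nrow(counts)) * 10000L + lengths - 1L,
                      length = lengths)
  expression_matrix(counts, genes, unit = "raw_count")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expression matrix wrapper for a bare numeric matrix (no coordinates)
as_expr <- function(m, unit = "log_normalized") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  expression_matrix(m, unit = unit)
}

# toy genotype matrix from a dosage matrix
as_geno <- function(d, pos = NULL, chrom = "chr1", ref = "A", alt = "G") {
  if (is.null(rownames(d))) rownames(d) <- sprintf("rs%03d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("S%03d", seq_len(ncol(d)))
  snps <- data.frame(snp_id = rownames(d), chrom = chrom,
                     pos = pos %||% (seq_len(nrow(d)) * 1000L),
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(d, snps)
}

# random dosage vector under HWE at frequency p
rdosage <- function(n, p) rbinom(n, 2L, p)
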