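# Readers/writers for the plain-text interchange formats used by the
# pipeline: counts/dosage TSV, minimal VCF v4.2 (GT only), BED gene
# coordinates, GMT gene sets, GWAS summary TSV, metadata TSV, JSON reports.

#' Write / read a genes-x-samples count matrix as TSV
#'
#' Header row = sample ids, first column `gene_id`.
#'
#' @param counts an [expression_matrix()] (unit `"raw_count"`).
#' @param path output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts$values), counts$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param bed_path optional BED file with gene coordinates to attach.
#' @param unit unit tag for the returned matrix.
#' @export
read_counts_tsv <- function(path, bed_path = NULL, unit = "raw_count") {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  genes <- if (!is.null(bed_path)) read_gene_bed(bed_path) else NULL
  expression_matrix(m, genes, unit = unit)
}

#' Write / read gene coordinates as BED (0-based half-open)
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `stop`
#'   (1-based inclusive, as carried by [expression_matrix()]).
#' @param path BED file path.
#' @export
write_gene_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$stop),
                               name = genes$gene_id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             stop = GenomicRanges::end(gr),
             length = GenomicRanges::width(gr),
             stringsAsFactors = FALSE)
}

#' Write / read a SNPs-x-samples dosage matrix as TSV
#'
#' Columns: `snp_id`, `chrom`, `pos`, `ref`, `alt`, then one column per
#' sample with 0/1/2 dosages (NA = missing).
#'
#' @param geno a [genotype_matrix()].
#' @param path output file.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- cbind(geno$snps, as.data.frame(geno$dosages, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  anno_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  m <- as.matrix(df[, setdiff(names(df), anno_cols), drop = FALSE])
  rownames(m) <- df$snp_id
  genotype_matrix(m, df[, anno_cols])
}

#' Write a minimal VCF v4.2 (GT field only)
#'
#' Hard-called genotypes from the dosage matrix: 0 -> `0/0`, 1 -> `0/1`,
#' 2 -> `1/1`, NA -> `./.`.
#'
#' @param geno a [genotype_matrix()].
#' @param path output `.vcf` file (uncompressed).
#' @export
write_vcf <- function(geno, path) {
  gt <- matrix(c("0/0", "0/1", "1/1")[geno$dosages + 1L],
               nrow(geno$dosages), ncol(geno$dosages))
  gt[is.na(geno$dosages)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       colnames(geno$dosages)), collapse = "\t")), con)
  body <- cbind(geno$snps$chrom, geno$snps$pos, geno$snps$snp_id,
                geno$snps$ref, geno$snps$alt, ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Parses the GT field via vcfR; alt-allele counts become 0/1/2 dosages
#' (missing genotypes -> NA). Multi-allelic records are kept as annotated
#' (comma-separated ALT) so downstream QC can drop them.
#'
#' @param path VCF file.
#' @return a [genotype_matrix()].
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | grepl("\\.", x), NA_integer_,
           vapply(strsplit(x, "[/|]"),
                  function(a) sum(a != "0"), integer(1)))
  }
  d <- apply(gt, 2, count_alt)
  rownames(d) <- rownames(gt)
  fix <- vcfR::getFIX(v)
  snps <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                     alt = fix[, "ALT"], stringsAsFactors = FALSE)
  genotype_matrix(d, snps)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#' A placeholder seven-axis collection with synthetic gene ids ships at
#' `system.file("extdata", "axes_synthetic.gmt", package = "diseqtl")`;
#' real axis/module memberships (published gene lists) are supplied by
#' the user in the same format.
#'
#' @param sets named list of character vectors.
#' @param path GMT file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' Write / read GWAS summary statistics as TSV
#'
#' @param gwas data.frame as produced by [generate_gwas_summary()] (at
#'   minimum `snp_id`, alleles, `beta`, `se`, `p`).
#' @param path TSV file.
#' @export
write_gwas_tsv <- function(gwas, path) {
  write.table(gwas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}
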