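#' Enumerate cis SNP-gene pairs
#'
#' All (SNP, gene) pairs with the SNP position within
#' `[start - window, stop + window]` of the gene, bounds inclusive (a SNP
#' at exactly `stop + window` is paired). Signed distance is 0 for SNPs in
#' the gene body, negative upstream of the start, positive downstream of
#' the stop.
#'
#' @param genes data.frame (`gene_id`, `chrom`, `start`, `stop`) or an
#'   [expression_matrix()] (its annotation is used).
#' @param snps data.frame (`snp_id`, `chrom`, `pos`) or a
#'   [genotype_matrix()].
#' @param window cis window in bp (default 250 kb).
#' @return data.frame of `CisPair`s: `snp_id`, `gene_id`, `distance`.
#' @export
build_cis_pairs <- function(genes, snps, window = 250000) {
  if (is(genes, "ExpressionMatrix")) genes <- genes$genes
  if (is(snps, "GenotypeMatrix")) snps <- snps$snps
  stopifnot(window >= 0)
  genes <- as.data.frame(genes); snps <- as.data.frame(snps)
  shared <- intersect(unique(genes$chrom), unique(snps$chrom))
  if (length(shared) == 0 && nrow(genes) > 0 && nrow(snps) > 0)
    stop("no shared chromosome names between genes (",
         paste(unique(genes$chrom), collapse = ","), ") and SNPs (",
         paste(unique(snps$chrom), collapse = ","), ")")
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - as.integer(window)),
                     genes$stop + as.integer(window)))
  gr_snps <- GenomicRanges::GRanges(snps$chrom,
                                    IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes)
  si <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  pos <- snps$pos[si]
  dist <- ifelse(pos < genes$start[gi], pos - genes$start[gi],
          ifelse(pos > genes$stop[gi], pos - genes$stop[gi], 0L))
  data.frame(snp_id = snps$snp_id[si], gene_id = genes$gene_id[gi],
             distance = as.integer(dist), stringsAsFactors = FALSE)
}

#' Single-pair additive eQTL fit
#'
#' Ordinary least squares of expression on alt-allele dosage (plus optional
#' covariates): `expr ~ intercept + dosage (+ covariates)`. Missing dosages
#' are mean-imputed. Two-sided p from the t statistic of the dosage
#' coefficient, floored at 1e-300.
#'
#' @param dosage numeric vector of 0/1/2 dosages (NA allowed).
#' @param expression numeric vector, same length.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @param min_n minimum non-missing sample count (default 10); below it the
#'   pair is skipped with a flag.
#' @return one-row data.frame (`AssociationRecord`): `beta`, `se`, `t`,
#'   `p`, `n`, `maf`, `flag` (`"ok"`, `"monomorphic"` or `"skipped_low_n"`).
#' @export
fit_eqtl <- function(dosage, expression, covariates = NULL, min_n = 10) {
  ok <- !is.na(expression)
  dosage <- dosage[ok]; expression <- expression[ok]
  if (!is.null(covariates))
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
  n <- length(expression)
  maf <- {
    af <- mean(dosage, na.rm = TRUE) / 2
    if (is.nan(af)) 0 else min(af, 1 - af)
  }
  rec <- data.frame(beta = NA_real_, se = NA_real_, t = NA_real_,
                    p = NA_real_, n = n, maf = maf, flag = "ok",
                    stringsAsFactors = FALSE)
  if (n < min_n) { rec$flag <- "skipped_low_n"; return(rec) }
  g <- impute_dosage(dosage)
  if (var(g) == 0) {
    rec$p <- 1; rec$flag <- "monomorphic"; return(rec)
  }
  X <- cbind(`(Intercept)` = 1, dosage = g, covariates)
  fit <- lm.fit(X, expression)
  df <- n - fit$rank
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X[, seq_len(fit$rank), drop = FALSE])))
  sigma2 <- rss / max(df, 1)
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- fit$coefficients["dosage"]
  if (se == 0 || df <= 0) {
    # perfect fit: underflow-floored p
    rec$beta <- beta; rec$se <- 0; rec$t <- sign(beta) * Inf
    rec$p <- .P_FLOOR
    return(rec)
  }
  rec$beta <- beta; rec$se <- se; rec$t <- beta / se
  rec$p <- .floor_p(2 * pt(-abs(rec$t), df))
  rec
}

#' Map cis-eQTL with peak-eSNP selection and permutation FDR
#'
#' Fits the additive model for every cis pair, retains the minimum-p
#' (peak) SNP per gene, calls eGenes at `p_threshold`, and estimates the
#' empirical FDR as the mean number of peak hits over sample-permuted
#' expression divided by the observed hit count. Covariates (e.g. ancestry
#' principal components) are residualized out of both expression and
#' dosages before the per-pair fits.
#'
#' @param pairs cis pairs from [build_cis_pairs()].
#' @param genotypes a [genotype_matrix()].
#' @param expression an [expression_matrix()] (adjusted / log scale).
#' @param p_threshold eGene calling threshold (default 1e-4, a common
#'   choice corresponding to empirical FDR < 5% in whole-blood cohorts of
#'   this size).
#' @param n_perms permutations for the empirical FDR (default 100; below
#'   10 a warning marks the estimate low-confidence).
#' @param covariates optional numeric matrix/data.frame (samples x k).
#' @param cohort cohort tag stored on every record.
#' @param seed optional integer seed for the permutations.
#' @return an `EqtlCallSet`: list with `peaks` (per-gene peak records,
#'   all genes), `calls` (peaks with p <= threshold), `p_threshold`,
#'   `n_perms`, `perm_hits`, `fdr` and `fdr_confidence`.
#' @export
call_eqtls <- function(pairs, genotypes, expression, p_threshold = 1e-4,
                       n_perms = 100, covariates = NULL, cohort = NA,
                       seed = NULL) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(expression, "ExpressionMatrix"))
  samples <- intersect(colnames(expression$values), colnames(genotypes$dosages))
  if (length(samples) < 10) stop("fewer than 10 shared samples")
  pairs <- pairs[pairs$snp_id %in% rownames(genotypes$dosages) &
                 pairs$gene_id %in% rownames(expression$values), , drop = FALSE]
  if (nrow(pairs) == 0) stop("no testable cis pairs")
  if (!is.null(seed)) set.seed(seed)
  low_conf <- n_perms > 0 && n_perms < 10
  if (low_conf) warning("n_perms < 10: empirical FDR is low-confidence")

  n <- length(samples)
  G <- genotypes$dosages[unique(pairs$snp_id), samples, drop = FALSE]
  G <- t(apply(G, 1, impute_dosage))
  maf_all <- {
    af <- rowMeans(G) / 2
    pmin(af, 1 - af)
  }
  Y <- expression$values[unique(pairs$gene_id), samples, drop = FALSE]
  # residualize on intercept + covariates (Frisch-Waugh)
  Xc <- cbind(rep(1, n), if (!is.null(covariates))
    as.matrix(covariates)[match(samples, colnames(expression$values)), , drop = FALSE])
  qx <- qr(Xc)
  G <- t(qr.resid(qx, t(G)))
  Y <- t(qr.resid(qx, t(Y)))
  df <- n - qx$rank - 1L

  perm_mat <- if (n_perms > 0)
    vapply(seq_len(n_perms), function(i) sample.int(n), integer(n)) else NULL

  by_gene <- split(pairs$snp_id, pairs$gene_id)
  peak_rows <- vector("list", length(by_gene))
  perm_min_p <- matrix(NA_real_, length(by_gene), max(n_perms, 1))
  pair_fit <- function(Gs, y) {
    gg <- rowSums(Gs^2)
    gy <- as.numeric(Gs %*% y)
    yy <- sum(y^2)
    beta <- ifelse(gg > 1e-12, gy / gg, NA_real_)
    rss <- yy - ifelse(gg > 1e-12, beta^2 * gg, 0)
    sigma2 <- pmax(rss, 0) / df
    se <- sqrt(sigma2 / gg)
    t <- beta / se
    p <- .floor_p(2 * pt(-abs(t), df))
    p[gg <= 1e-12] <- 1
    p[se == 0 & gg > 1e-12] <- .P_FLOOR
    list(beta = beta, se = se, t = t, p = p)
  }
  for (gi in seq_along(by_gene)) {
    gene <- names(by_gene)[gi]
    snp_ids <- by_gene[[gi]]
    Gs <- G[snp_ids, , drop = FALSE]
    y <- Y[gene, ]
    f <- pair_fit(Gs, y)
    k <- which.min(f$p)
    peak_rows[[gi]] <- data.frame(
      snp_id = snp_ids[k], gene_id = gene, cohort = cohort,
      beta = f$beta[k], se = f$se[k], t = f$t[k], p = f$p[k], n = n,
      maf = maf_all[snp_ids[k]], n_cis_snps = length(snp_ids),
      stringsAsFactors = FALSE)
    if (n_perms > 0) {
      gg <- rowSums(Gs^2)
      yy <- sum(y^2)
      Yp <- matrix(y[perm_mat], n, n_perms)
      GY <- Gs %*% Yp                       # snps x perms
      beta <- GY / gg
      rss <- matrix(yy, nrow(Gs), n_perms) - beta^2 * gg
      tstat <- beta / sqrt(pmax(rss, 0) / df / gg)
      pm <- 2 * pt(-abs(tstat), df)
      pm[gg <= 1e-12, ] <- 1
      perm_min_p[gi, seq_len(n_perms)] <- apply(pm, 2, min)
    }
  }
  peaks <- do.call(rbind, peak_rows)
  peaks$significant <- peaks$p <= p_threshold
  n_hits <- sum(peaks$significant)
  perm_hits <- if (n_perms > 0)
    colSums(perm_min_p[, seq_len(n_perms), drop = FALSE] <= p_threshold,
            na.rm = TRUE) else NA
  fdr <- if (n_perms > 0 && n_hits > 0) min(1, mean(perm_hits) / n_hits)
         else if (n_hits == 0) NA_real_ else NA_real_
  structure(list(peaks = peaks, calls = peaks[peaks$significant, , drop = FALSE],
                 p_threshold = p_threshold, n_perms = n_perms,
                 perm_hits = perm_hits, fdr = fdr,
                 fdr_confidence = if (low_conf) "low" else "ok",
                 cohort = cohort, samples = samples),
            class = "EqtlCallSet")
}

#' @export
print.EqtlCallSet <- function(x, ...) {
  cat(sprintf("EqtlCallSet [%s]: %d eGenes at p <= %g (of %d genes); empirical FDR %s (%d perms)\n",
              x$cohort %||% "?", nrow(x$calls), x$p_threshold, nrow(x$peaks),
              ifelse(is.na(x$fdr), "NA", sprintf("%.3f", x$fdr)), x$n_perms))
  invisible(x)
}

#' MAF-versus-significance diagnostic and single-outlier leverage check
#'
#' Low-MAF eQTL can be driven by a single minor-allele homozygote with
#' outlying expression. This diagnostic (a) correlates MAF with
#' -log10 p across called eQTL, and (b) refits each call after removing
#' the single most extreme expression value among minor-allele
#' homozygotes, flagging calls whose p-value no longer clears the
#' threshold.
#'
#' @param callset an `EqtlCallSet` from [call_eqtls()].
#' @param genotypes,expression the inputs used for calling.
#' @param covariates optional covariates (as in [call_eqtls()]).
#' @param refit_threshold p-value a call must keep after outlier removal
#'   (default: the callset's own threshold).
#' @return list: `correlation` (MAF vs -log10 p), `table` (per-call
#'   diagnostics: n minor homozygotes, refit p, flagged), `flagged`
#'   (subset of calls failing the leverage check).
#' @export
maf_significance_check <- function(callset, genotypes, expression,
                                   covariates = NULL,
                                   refit_threshold = NULL) {
  stopifnot(is(callset, "EqtlCallSet"))
  calls <- callset$calls
  if (nrow(calls) == 0) stop("empty call set")
  refit_threshold <- refit_threshold %||% callset$p_threshold
  samples <- callset$samples
  correlation <- if (nrow(calls) >= 3 && sd(calls$maf) > 0)
    cor(calls$maf, -log10(calls$p)) else NA_real_
  covm <- if (!is.null(covariates))
    as.matrix(covariates)[match(samples, colnames(expression$values)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    dos <- genotypes$dosages[calls$snp_id[i], samples]
    y <- expression$values[calls$gene_id[i], samples]
    af <- mean(dos, na.rm = TRUE) / 2
    minor_dos <- if (af <= 0.5) 2 else 0
    hom <- which(!is.na(dos) & dos == minor_dos)
    out <- data.frame(snp_id = calls$snp_id[i], gene_id = calls$gene_id[i],
                      n_minor_hom = length(hom), p_refit = NA_real_,
                      flagged = FALSE, stringsAsFactors = FALSE)
    if (length(hom) >= 1) {
      extreme <- hom[which.max(abs(y[hom] - mean(y)))]
      keep <- setdiff(seq_along(y), extreme)
      ref <- fit_eqtl(dos[keep], y[keep],
                      covariates = if (!is.null(covm)) covm[keep, , drop = FALSE])
      out$p_refit <- ref$p
      out$flagged <- is.na(ref$p) || ref$p > refit_threshold
    }
    out
  })
  tab <- do.call(rbind, rows)
  list(correlation = correlation, table = tab,
       flagged = calls[tab$flagged, , drop = FALSE])
}
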