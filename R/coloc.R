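#' Wakefield approximate Bayes factors for a summary series
#'
#' Per-SNP log approximate Bayes factor against the null from summary
#' statistics: with `z = beta/se` and prior effect variance `W =
#' prior_sd^2`,
#' `log ABF = 0.5 * (log(se^2 / (se^2 + W)) + z^2 * W / (se^2 + W))`.
#'
#' @param beta,se numeric vectors of per-SNP effect sizes and standard
#'   errors (`se > 0`).
#' @param prior_sd prior SD of the true effect (0.15 is the usual choice
#'   for quantitative traits, 0.2 on the log-odds scale for case-control).
#' @param snp_id optional ids for error messages.
#' @return numeric vector of log ABFs.
#' @export
approximate_bayes_factors <- function(beta, se, prior_sd = 0.15,
                                      snp_id = NULL) {
  stopifnot(length(beta) == length(se))
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0)) {
    bad <- which(!is.finite(beta) | !is.finite(se) | se <= 0)
    ids <- if (!is.null(snp_id)) snp_id[bad] else bad
    stop("non-finite beta or non-positive se for SNP(s): ",
         paste(head(ids), collapse = ", "))
  }
  W <- prior_sd^2
  z <- beta / se
  r <- W / (se^2 + W)
  0.5 * (log(1 - r) + z^2 * r)
}

#' Five-hypothesis colocalization of two summary series
#'
#' Given per-SNP association summaries for two traits at one locus
#' (restricted to their shared SNPs), computes posterior probabilities for
#' the five standard hypotheses: H0 no association with either trait, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant. Evidence is combined from Wakefield log ABFs
#' under the single-causal-variant assumption with priors `p1`, `p2`
#' (SNP causal for trait 1 / 2) and `p12` (causal for both).
#'
#' @param series_1,series_2 data.frames with columns `snp_id`, `beta`,
#'   `se` and optionally `type` attribute columns; see `prior_sd_1/2` for
#'   trait-type prior SDs.
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd_1,prior_sd_2 prior effect SDs for the two traits
#'   (default 0.15; 0.2 on the log-odds scale is conventional for a
#'   case-control trait).
#' @param type_1,type_2 trait types, `"quant"` (default) or `"cc"`. For a
#'   case-control trait only the z-scores are used: standard errors are
#'   recomputed on a canonical `1/sqrt(n)` scale (per-SNP `n` column if
#'   present), so the result is invariant to any common rescaling of that
#'   trait's betas and SEs.
#' @return a `ColocResult`: list with `pp` (named PP0..PP4, summing to 1),
#'   `n_snps`, `priors`, and `snp_h4` (per-SNP posterior contribution to
#'   H4, i.e. the credible-set weights).
#' @export
colocalize <- function(series_1, series_2, p1 = 1e-4, p2 = 1e-4,
                       p12 = 1e-5, prior_sd_1 = 0.15, prior_sd_2 = 0.15,
                       type_1 = c("quant", "cc"),
                       type_2 = c("quant", "cc")) {
  type_1 <- match.arg(type_1); type_2 <- match.arg(type_2)
  s1 <- as.data.frame(series_1); s2 <- as.data.frame(series_2)
  stopifnot(all(c("snp_id", "beta", "se") %in% names(s1)),
            all(c("snp_id", "beta", "se") %in% names(s2)))
  canonical_cc <- function(s) {
    z <- s$beta / s$se
    n <- if ("n" %in% names(s)) s$n else rep(1e4, nrow(s))
    s$se <- 1 / sqrt(n)
    s$beta <- z * s$se
    s
  }
  if (type_1 == "cc") s1 <- canonical_cc(s1)
  if (type_2 == "cc") s2 <- canonical_cc(s2)
  shared <- intersect(s1$snp_id, s2$snp_id)
  if (length(shared) == 0) stop("no shared SNPs between the two series")
  i1 <- match(shared, s1$snp_id); i2 <- match(shared, s2$snp_id)
  l1 <- approximate_bayes_factors(s1$beta[i1], s1$se[i1], prior_sd_1, shared)
  l2 <- approximate_bayes_factors(s2$beta[i2], s2$se[i2], prior_sd_2, shared)

  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  # sum over i != j of BF1_i * BF2_j, in log space
  lsum3 <- lsum1 + lsum2 + log1p(-pmin(exp(lsum12 - lsum1 - lsum2), 1 - 1e-16))
  lh <- c(H0 = 0,
          H1 = log(p1) + lsum1,
          H2 = log(p2) + lsum2,
          H3 = log(p1) + log(p2) + lsum3,
          H4 = log(p12) + lsum12)
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  names(pp) <- paste0("PP", 0:4)
  snp_h4 <- exp(l1 + l2 - lsum12)
  names(snp_h4) <- shared
  structure(list(pp = pp, n_snps = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 snp_h4 = snp_h4),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult over %d shared SNPs:\n", x$n_snps))
  print(round(x$pp, 4))
  invisible(x)
}

#' Build per-locus eQTL summary series from a genotype/expression pair
#'
#' Computes the per-SNP univariate association statistics of one gene
#' against all its cis SNPs (the eQTL side of a colocalization).
#'
#' @param gene_id gene to test.
#' @param pairs cis pairs from [build_cis_pairs()].
#' @param genotypes a [genotype_matrix()].
#' @param expression an [expression_matrix()].
#' @param covariates optional covariates passed to [fit_eqtl()].
#' @return data.frame: `snp_id`, `beta`, `se`, `p`, `n`.
#' @export
eqtl_summary_series <- function(gene_id, pairs, genotypes, expression,
                                covariates = NULL) {
  snp_ids <- pairs$snp_id[pairs$gene_id == gene_id]
  if (length(snp_ids) == 0) stop("no cis SNPs for gene ", gene_id)
  samples <- intersect(colnames(expression$values),
                       colnames(genotypes$dosages))
  y <- expression$values[gene_id, samples]
  rows <- lapply(snp_ids, function(s) {
    rec <- fit_eqtl(genotypes$dosages[s, samples], y, covariates)
    data.frame(snp_id = s, beta = rec$beta, se = rec$se, p = rec$p,
               n = rec$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$se) & out$se > 0, , drop = FALSE]
}
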