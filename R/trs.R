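#' Build a transcriptional risk score definition
#'
#' Selects the genes supported as both eQTL and GWAS signals (coloc H4
#' posterior above `h4_min`) and assigns each a polarity: +1 if the GWAS
#' risk allele increases the gene's expression, -1 if it decreases it.
#' GWAS and eQTL alleles are harmonized first (matching the risk allele to
#' the eQTL effect or other allele, with a strand-flip rescue); genes whose
#' alleles cannot be reconciled are dropped with a warning.
#'
#' @param gwas data.frame of GWAS records: `snp_id`, `risk_allele` and
#'   (for harmonization) the allele pair via `effect_allele` /
#'   `other_allele`.
#' @param eqtl data.frame of eQTL records (e.g. `calls` from
#'   [call_eqtls()] merged with SNP annotation): `snp_id`, `gene_id`,
#'   `beta`, `effect_allele` (allele counted by the dosage), `other_allele`.
#' @param coloc_results data.frame: `gene_id`, `pp_h4` (per-locus H4
#'   posterior). NULL accepts every eQTL gene (h4 recorded as NA).
#' @param h4_min minimum H4 posterior (default 0.5).
#' @return `TrsDefinition` data.frame: `gene_id`, `polarity`, `snp_id`,
#'   `risk_allele`, `eqtl_beta`, `h4`.
#' @export
build_trs_definition <- function(gwas, eqtl, coloc_results = NULL,
                                 h4_min = 0.5) {
  stopifnot(all(c("snp_id", "risk_allele") %in% names(gwas)),
            all(c("snp_id", "gene_id", "beta", "effect_allele",
                  "other_allele") %in% names(eqtl)))
  m <- merge(eqtl, gwas[, c("snp_id", "risk_allele")], by = "snp_id")
  if (!is.null(coloc_results)) {
    m <- merge(m, coloc_results[, c("gene_id", "pp_h4")], by = "gene_id")
    m <- m[m$pp_h4 >= h4_min, , drop = FALSE]
  } else m$pp_h4 <- NA_real_
  if (nrow(m) == 0) stop("no genes pass the H4 filter")
  flip <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- lapply(seq_len(nrow(m)), function(i) {
    risk <- toupper(m$risk_allele[i])
    eff <- toupper(m$effect_allele[i]); oth <- toupper(m$other_allele[i])
    sign_mult <- if (risk == eff) 1
      else if (risk == oth) -1
      else if (!is.na(flip[risk]) && flip[risk] == eff) 1
      else if (!is.na(flip[risk]) && flip[risk] == oth) -1
      else NA_real_
    if (is.na(sign_mult) || m$beta[i] == 0) return(NULL)
    data.frame(gene_id = m$gene_id[i],
               polarity = sign(m$beta[i]) * sign_mult,
               snp_id = m$snp_id[i], risk_allele = risk,
               eqtl_beta = m$beta[i], h4 = m$pp_h4[i],
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " gene(s) dropped: risk allele irreconcilable with ",
            "eQTL alleles even after strand flip")
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no harmonizable genes remain")
  # one entry per gene: keep the highest-H4 (then strongest) record
  ord <- order(out$gene_id, -ifelse(is.na(out$h4), 0, out$h4),
               -abs(out$eqtl_beta))
  out <- out[ord, ][!duplicated(out$gene_id[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute per-sample transcriptional risk scores
#'
#' TRS of a sample = sum over definition genes of polarity x expression
#' z-score, so positive TRS represents elevated risk (a risk allele that
#' decreases expression contributes an inverted z-score). Expression is
#' z-scored per gene across all samples unless already in z-score units.
#' Definition genes missing from the matrix are excluded from the sum and
#' reported, never silently skipped.
#'
#' @param expr an [expression_matrix()].
#' @param definition a `TrsDefinition` from [build_trs_definition()] (any
#'   data.frame with `gene_id` and `polarity`).
#' @return `TrsScores` data.frame: `sample_id`, `trs`; attributes
#'   `genes_used`, `genes_missing`, `coverage`.
#' @export
compute_trs <- function(expr, definition) {
  stopifnot(is(expr, "ExpressionMatrix"),
            all(c("gene_id", "polarity") %in% names(definition)))
  if (any(!definition$polarity %in% c(-1, 1)))
    stop("polarity must be +1 or -1")
  present <- definition$gene_id %in% rownames(expr$values)
  if (!any(present)) stop("no definition genes present in the matrix")
  used <- definition[present, , drop = FALSE]
  Z <- if (expr$unit == "zscore") expr$values else
    zscore_expression(expr)$values
  trs <- as.numeric(crossprod(Z[used$gene_id, , drop = FALSE],
                              used$polarity))
  out <- data.frame(sample_id = colnames(expr$values), trs = trs,
                    stringsAsFactors = FALSE)
  attr(out, "genes_used") <- used$gene_id
  attr(out, "genes_missing") <- definition$gene_id[!present]
  attr(out, "coverage") <- sum(present) / nrow(definition)
  out
}

#' Contrast transcriptional risk scores between groups
#'
#' For each group, the difference from the reference group in pooled
#' standard deviation units (Cohen's d with pooled SD) and a two-sided
#' two-group p-value, plus an overall one-way ANOVA across all groups.
#'
#' @param scores `TrsScores` from [compute_trs()].
#' @param groups factor of group labels aligned with `scores` rows.
#' @param reference reference group label (default: first factor level).
#' @return list: `contrasts` (data.frame: group, n, mean, sd, delta_sd,
#'   p), `anova_p`, `reference`.
#' @export
trs_group_contrast <- function(scores, groups, reference = NULL) {
  groups <- as.factor(groups)
  stopifnot(nrow(scores) == length(groups))
  reference <- reference %||% levels(groups)[1]
  if (!reference %in% groups) stop("reference group not present")
  ref_x <- scores$trs[groups == reference]
  if (length(ref_x) < 3) stop("reference group needs at least 3 samples")
  rows <- lapply(setdiff(levels(droplevels(groups)), reference), function(g) {
    x <- scores$trs[groups == g]
    n1 <- length(x); n0 <- length(ref_x)
    sp2 <- ((n1 - 1) * var(x) + (n0 - 1) * var(ref_x)) / (n1 + n0 - 2)
    if (sp2 == 0) stop("zero pooled SD for group ", g)
    delta <- (mean(x) - mean(ref_x)) / sqrt(sp2)
    tstat <- (mean(x) - mean(ref_x)) / sqrt(sp2 * (1 / n1 + 1 / n0))
    p <- 2 * pt(-abs(tstat), n1 + n0 - 2)
    data.frame(group = g, n = n1, mean = mean(x), sd = sd(x),
               delta_sd = delta, p = p, stringsAsFactors = FALSE)
  })
  anova_p <- if (nlevels(droplevels(groups)) > 1)
    anova(lm(scores$trs ~ droplevels(groups)))$`Pr(>F)`[1] else NA_real_
  list(contrasts = do.call(rbind, rows), anova_p = anova_p,
       reference = reference,
       reference_stats = data.frame(group = reference, n = length(ref_x),
                                    mean = mean(ref_x), sd = sd(ref_x)))
}
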