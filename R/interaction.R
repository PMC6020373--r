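#' Pool peak eQTL candidates from two cohorts
#'
#' Union of the peak SNP-gene pairs called significant in either cohort,
#' deduplicated by (snp, gene), with provenance (discovered in A only, B
#' only, or both). These candidates feed the genotype-by-disease
#' interaction test.
#'
#' @param calls_a,calls_b `EqtlCallSet`s (or data.frames with `snp_id`,
#'   `gene_id`) for the two cohorts.
#' @param tag_a,tag_b provenance labels (default `"A"`, `"B"`).
#' @return data.frame: `snp_id`, `gene_id`, `discovery`
#'   (`tag_a` / `tag_b` / `"both"`).
#' @export
pool_cohorts <- function(calls_a, calls_b, tag_a = "A", tag_b = "B") {
  get_calls <- function(x) {
    if (is(x, "EqtlCallSet")) x$calls else as.data.frame(x)
  }
  a <- unique(get_calls(calls_a)[, c("snp_id", "gene_id")])
  b <- unique(get_calls(calls_b)[, c("snp_id", "gene_id")])
  key_a <- paste(a$snp_id, a$gene_id); key_b <- paste(b$snp_id, b$gene_id)
  all_keys <- union(key_a, key_b)
  if (length(all_keys) == 0) stop("empty union of eQTL candidates")
  both <- intersect(key_a, key_b)
  pooled <- rbind(a, b[!(key_b %in% key_a), , drop = FALSE])
  key <- paste(pooled$snp_id, pooled$gene_id)
  pooled$discovery <- ifelse(key %in% both, "both",
                      ifelse(key %in% key_a, tag_a, tag_b))
  rownames(pooled) <- NULL
  pooled
}

#' Genotype-by-disease interaction test for one SNP-gene pair
#'
#' Joint OLS of expression on genotype, disease indicator and their
#' product: `expr ~ g + d + g:d (+ covariates)`, Wald p-values from the
#' coefficient t statistics. Per-disease marginal slopes are derived from
#' the joint fit (`beta_ref = beta_genotype`;
#' `beta_alt = beta_genotype + beta_interaction`).
#'
#' @param dosage numeric 0/1/2 dosages (NA mean-imputed).
#' @param expression numeric vector, same samples.
#' @param disease two-level factor (first level = reference disease).
#' @param covariates optional numeric matrix/data.frame.
#' @param min_group_n minimum samples per disease group (default 10).
#' @return one-row data.frame (`InteractionRecord`) with joint
#'   coefficients, their SEs and p-values, the per-disease marginal betas
#'   and SEs, `n`, and a `flag` (`"ok"` or `"untestable"`).
#' @export
interaction_test <- function(dosage, expression, disease,
                             covariates = NULL, min_group_n = 10) {
  disease <- droplevels(as.factor(disease))
  if (nlevels(disease) != 2) stop("disease must have exactly 2 levels")
  lev <- levels(disease)
  d <- as.numeric(disease == lev[2])
  rec <- data.frame(beta_genotype = NA_real_, se_genotype = NA_real_,
                    p_genotype = NA_real_,
                    beta_disease = NA_real_, se_disease = NA_real_,
                    p_disease = NA_real_,
                    beta_interaction = NA_real_, se_interaction = NA_real_,
                    p_interaction = NA_real_,
                    beta_ref = NA_real_, se_ref = NA_real_,
                    beta_alt = NA_real_, se_alt = NA_real_,
                    ref_level = lev[1], alt_level = lev[2],
                    n = length(expression), flag = "ok",
                    stringsAsFactors = FALSE)
  g <- impute_dosage(dosage)
  tab <- table(disease)
  if (any(tab < min_group_n) ||
      var(g[d == 0]) == 0 || var(g[d == 1]) == 0) {
    rec$flag <- "untestable"
    return(rec)
  }
  X <- cbind(1, g = g, d = d, gd = g * d, covariates)
  fit <- lm.fit(X, expression)
  df <- length(expression) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df
  V <- chol2inv(chol(crossprod(X))) * sigma2
  b <- fit$coefficients
  se <- sqrt(diag(V))
  pv <- function(bi, si) if (si == 0) .P_FLOOR else
    .floor_p(2 * pt(-abs(bi / si), df))
  rec$beta_genotype <- b["g"];  rec$se_genotype <- se[2]
  rec$p_genotype <- pv(b["g"], se[2])
  rec$beta_disease <- b["d"];   rec$se_disease <- se[3]
  rec$p_disease <- pv(b["d"], se[3])
  rec$beta_interaction <- b["gd"]; rec$se_interaction <- se[4]
  rec$p_interaction <- pv(b["gd"], se[4])
  rec$beta_ref <- b["g"];       rec$se_ref <- se[2]
  rec$beta_alt <- b["g"] + b["gd"]
  rec$se_alt <- sqrt(V[2, 2] + V[4, 4] + 2 * V[2, 4])
  rec
}

#' Run interaction tests for a pooled candidate list
#'
#' Convenience driver applying [interaction_test()] to every pooled
#' SNP-gene pair across the merged two-cohort sample set.
#'
#' @param pooled candidates from [pool_cohorts()].
#' @param genotypes a [genotype_matrix()] covering both cohorts.
#' @param expression an [expression_matrix()] covering both cohorts.
#' @param disease two-level factor named by sample id.
#' @param covariates optional numeric matrix (samples x k, rownames =
#'   sample ids).
#' @return data.frame of `InteractionRecord`s (one per candidate) with
#'   `snp_id`, `gene_id`, `discovery` carried through.
#' @export
test_interactions <- function(pooled, genotypes, expression, disease,
                              covariates = NULL) {
  samples <- intersect(names(disease), intersect(
    colnames(genotypes$dosages), colnames(expression$values)))
  if (length(samples) < 20) stop("too few shared samples")
  dis <- droplevels(as.factor(disease[samples]))
  covm <- if (!is.null(covariates))
    as.matrix(covariates)[samples, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pooled)), function(i) {
    rec <- interaction_test(
      genotypes$dosages[pooled$snp_id[i], samples],
      expression$values[pooled$gene_id[i], samples], dis, covm)
    cbind(pooled[i, , drop = FALSE], rec, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Call significant genotype-by-disease interactions
#'
#' Benjamini-Hochberg control at the stated FDR on the interaction
#' p-values; also reports the nominal count at p < 0.02 for comparability
#' across cohorts.
#'
#' @param records data.frame of `InteractionRecord`s with valid
#'   `p_interaction` (untestable records are excluded).
#' @param fdr BH threshold (default 0.10).
#' @param nominal_p nominal threshold for the comparability count.
#' @return list: `records` (with `q` and `significant` added),
#'   `significant` (subset), `n_significant`, `n_nominal`.
#' @export
call_interactions <- function(records, fdr = 0.10, nominal_p = 0.02) {
  ok <- !is.na(records$p_interaction)
  records <- records[ok, , drop = FALSE]
  records$q <- p.adjust(records$p_interaction, method = "BH")
  records$significant <- records$q <= fdr
  list(records = records,
       significant = records[records$significant, , drop = FALSE],
       n_significant = sum(records$significant),
       n_nominal = sum(records$p_interaction < nominal_p))
}

#' Cross-cohort effect-size comparison with winner's-curse stratification
#'
#' Pearson correlation of the per-disease marginal effect sizes across
#' records, stratified by discovery cohort, with the mean |beta| ratio per
#' stratum. Effects estimated in their discovery cohort are inflated by
#' winner's curse, so a ratio > 1 in the discovery stratum is expected
#' even for fully shared effects; the output carries that caveat.
#'
#' @param records data.frame with `beta_a`, `beta_b` (marginal effects in
#'   the two cohorts) and `discovery` (`"A"`, `"B"` or `"both"`).
#' @return list: `r` (overall Pearson correlation), `by_discovery`
#'   (data.frame: stratum, n, mean |beta| in each cohort, ratio
#'   discovery/other), `caveat`.
#' @export
effect_size_comparison <- function(records) {
  stopifnot(all(c("beta_a", "beta_b", "discovery") %in% names(records)))
  records <- records[complete.cases(records[, c("beta_a", "beta_b")]), ,
                     drop = FALSE]
  if (nrow(records) < 3) stop("need at least 3 records")
  r <- cor(records$beta_a, records$beta_b)
  strat <- lapply(intersect(c("A", "B", "both"), records$discovery),
                  function(s) {
    sub <- records[records$discovery == s, , drop = FALSE]
    ma <- mean(abs(sub$beta_a)); mb <- mean(abs(sub$beta_b))
    ratio <- switch(s, A = ma / mb, B = mb / ma, both = NA_real_)
    data.frame(discovery = s, n = nrow(sub), mean_abs_beta_a = ma,
               mean_abs_beta_b = mb, discovery_ratio = ratio,
               stringsAsFactors = FALSE)
  })
  list(r = r, by_discovery = do.call(rbind, strat),
       caveat = paste("discovery-stratum |beta| ratios are inflated by",
                      "winner's curse; cross-cohort r is attenuated by",
                      "estimation noise"))
}
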