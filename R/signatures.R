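#' First-principal-component score of a gene set (immune axis score)
#'
#' Summarizes a co-regulated gene set (e.g. a blood-informative-transcript
#' axis) by the first principal component of the set's genes across
#' samples. Genes are standardized first, so the score is invariant to
#' per-gene affine rescaling; the sign is oriented so the mean gene loading
#' is positive (high score = high average expression of the set).
#'
#' @param expr log-normalized or z-scored [expression_matrix()].
#' @param gene_set character vector of gene ids; at least 2 must resolve
#'   against the matrix.
#' @param score_name name for the score column.
#' @return data.frame (`ScoreTable`): `sample_id`, one score column;
#'   attributes `variance_explained` (PC1 share of the set's variance),
#'   `loadings`, `unresolved` (ids not found).
#' @export
axis_score <- function(expr, gene_set, score_name = "score") {
  stopifnot(is(expr, "ExpressionMatrix"))
  present <- intersect(gene_set, rownames(expr$values))
  unresolved <- setdiff(gene_set, present)
  if (length(present) < 2)
    stop("fewer than 2 gene-set members resolvable in the expression matrix")
  Z <- zscore_expression(subset_expression(expr, genes = present))$values
  pc <- prcomp(t(Z), center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  load <- pc$rotation[, 1]
  if (mean(load) < 0) { score <- -score; load <- -load }
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out <- data.frame(sample_id = colnames(expr$values), score,
                    stringsAsFactors = FALSE)
  names(out)[2] <- score_name
  rownames(out) <- NULL
  attr(out, "variance_explained") <- ve
  attr(out, "loadings") <- load
  attr(out, "unresolved") <- unresolved
  out
}

#' Score a collection of gene modules
#'
#' [axis_score()] applied to every module in a collection (e.g. ~247 blood
#' transcript modules). Modules with fewer than 2 resolvable genes are
#' skipped with a warning. When group labels are supplied, a module x group
#' mean-score matrix (heat-map export) is attached.
#'
#' @param expr [expression_matrix()].
#' @param collection named list of gene-id vectors (as from [read_gmt()]).
#' @param groups optional factor of group labels, aligned with samples.
#' @return data.frame: `sample_id` plus one column per scored module;
#'   attributes `variance_explained` (named vector), `group_means`
#'   (module x group matrix, if `groups` given), `skipped`.
#' @export
btm_scores <- function(expr, collection, groups = NULL) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  out <- data.frame(sample_id = colnames(expr$values),
                    stringsAsFactors = FALSE)
  ve <- numeric(0); skipped <- character(0)
  for (m in names(collection)) {
    present <- intersect(collection[[m]], rownames(expr$values))
    if (length(present) < 2) { skipped <- c(skipped, m); next }
    s <- axis_score(expr, present, score_name = m)
    out[[m]] <- s[[m]]
    ve[m] <- attr(s, "variance_explained")
  }
  if (length(skipped))
    warning("modules skipped (<2 resolvable genes): ",
            paste(skipped, collapse = ", "))
  if (ncol(out) < 2) stop("no module could be scored")
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    gm <- sapply(names(out)[-1], function(m)
      tapply(out[[m]], groups, mean))
    attr(out, "group_means") <- t(as.matrix(gm))
  }
  attr(out, "variance_explained") <- ve
  attr(out, "skipped") <- skipped
  out
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances of
#' z-scored expression), cut at `k` clusters, with a per-group cluster
#' membership proportion table (each group's row sums to 1).
#'
#' @param expr_z z-scored [expression_matrix()] (other units are z-scored
#'   on the fly with a message).
#' @param k number of clusters (default 6).
#' @param groups optional factor of disease sub-type labels per sample.
#' @return list: `clusters` (named integer vector), `tree` (hclust),
#'   `membership` (group x cluster proportion matrix or NULL).
#' @export
cluster_samples <- function(expr_z, k = 6, groups = NULL) {
  stopifnot(is(expr_z, "ExpressionMatrix"))
  if (expr_z$unit != "zscore") {
    message("z-scoring expression before clustering")
    expr_z <- zscore_expression(expr_z)
  }
  n <- ncol(expr_z$values)
  if (k > n) stop("k exceeds the number of samples")
  tree <- hclust(dist(t(expr_z$values)), method = "ward.D2")
  clusters <- cutree(tree, k = k)
  membership <- NULL
  if (!is.null(groups)) {
    tab <- table(groups, clusters)
    membership <- sweep(tab, 1, rowSums(tab), "/")
    membership <- as.matrix(unclass(membership))
  }
  list(clusters = clusters, tree = tree, membership = membership)
}

#' Principal variance component analysis
#'
#' Partitions expression variance among experimental factors: the top
#' `n_pc` principal components are each regressed on the factors
#' (sequential / type-I sums of squares in the order given), the per-factor
#' eta-squared shares are weighted by each PC's fraction of total variance,
#' and the remainder closes the budget as residual.
#'
#' @param expr [expression_matrix()].
#' @param factors data.frame of categorical factors (order matters for the
#'   sequential decomposition), rows aligned with samples.
#' @param n_pc number of leading PCs (default 5).
#' @return data.frame: factor (plus `resid`), `weighted_proportion`
#'   (non-negative, summing to 1); attribute `pc_variance` has the
#'   eigenvalue fractions.
#' @export
pvca <- function(expr, factors, n_pc = 5) {
  stopifnot(is(expr, "ExpressionMatrix"))
  factors <- as.data.frame(factors)
  factors[] <- lapply(factors, as.factor)
  n <- ncol(expr$values)
  if (nrow(factors) != n) stop("factors must have one row per sample")
  if (n_pc > n - 1) stop("n_pc must be <= samples - 1")
  # nested factors (e.g. sub-type within disease) legitimately share span
  # with their parent; only a factor adding NO rank at all is confounded
  rank_sofar <- 1L; aliased <- character(0)
  for (fi in seq_along(factors)) {
    Xf <- model.matrix(~ ., data = factors[, seq_len(fi), drop = FALSE])
    r <- qr(Xf)$rank
    if (r == rank_sofar && nlevels(factors[[fi]]) > 1L)
      aliased <- c(aliased, names(factors)[fi])
    rank_sofar <- r
  }
  if (length(aliased))
    stop("aliased (confounded) factors: ", paste(aliased, collapse = ", "))
  pc <- prcomp(t(expr$values), center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  weights <- pc$sdev[seq_len(n_pc)]^2 / total_var
  shares <- matrix(0, n_pc, ncol(factors),
                   dimnames = list(NULL, names(factors)))
  for (i in seq_len(n_pc)) {
    fit <- lm(pc$x[, i] ~ ., data = factors)
    an <- anova(fit)
    ss <- an[["Sum Sq"]]
    shares[i, ] <- ss[seq_len(ncol(factors))] / sum(ss)
  }
  weighted <- colSums(weights * shares)
  out <- data.frame(factor = c(names(factors), "resid"),
                    weighted_proportion = c(weighted, 1 - sum(weighted)),
                    stringsAsFactors = FALSE)
  attr(out, "pc_variance") <- weights
  out
}

#' Two-group differential expression on the log scale
#'
#' Per-gene two-group linear-model contrast (equivalent to a pooled-variance
#' t-test) on log-normalized expression, with Benjamini-Hochberg adjustment
#' and direction labels. Genes with zero pooled variance are flagged and
#' assigned p = 1.
#'
#' @param expr log-normalized [expression_matrix()].
#' @param labels factor/character of group labels aligned with samples.
#' @param group_a,group_b the two groups to contrast (effect = A - B).
#' @param fdr BH false-discovery-rate threshold for the significant set.
#' @return data.frame per gene: `gene_id`, `log_fc` (mean A - mean B),
#'   `t`, `p`, `q`, `significant`, `direction` (`"up_in_A"`/`"up_in_B"`),
#'   `degenerate` flag.
#' @export
differential_expression <- function(expr, labels, group_a, group_b,
                                    fdr = 0.05) {
  stopifnot(is(expr, "ExpressionMatrix"))
  labels <- as.character(labels)
  ia <- which(labels == group_a); ib <- which(labels == group_b)
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  if (length(ia) < 3 || length(ib) < 3)
    stop("each group needs at least 3 samples")
  A <- expr$values[, ia, drop = FALSE]; B <- expr$values[, ib, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2); vb <- rowSums((B - mb)^2)
  df <- na + nb - 2
  s2 <- (va + vb) / df
  se <- sqrt(s2 * (1 / na + 1 / nb))
  degenerate <- s2 <= 0 | !is.finite(se) | se == 0
  tstat <- ifelse(degenerate, 0, (ma - mb) / se)
  p <- ifelse(degenerate, 1, 2 * pt(-abs(tstat), df))
  q <- p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(expr$values),
             log_fc = ma - mb, t = tstat, p = .floor_p(p), q = q,
             significant = q <= fdr & !degenerate,
             direction = ifelse(ma >= mb, "up_in_A", "up_in_B"),
             degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-way ANOVA of scores across groups
#'
#' For each score column, a one-way ANOVA contrasting the sample groups
#' (e.g. the six disease sub-types).
#'
#' @param scores data.frame with `sample_id` and numeric score columns.
#' @param groups factor of group labels aligned with the rows of `scores`.
#' @return data.frame: `score`, `F`, `df1`, `df2`, `p`.
#' @export
group_anova <- function(scores, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(droplevels(groups)) < 2))
    stop("each group needs at least 2 samples")
  cols <- setdiff(names(scores), "sample_id")
  cols <- cols[vapply(scores[cols], is.numeric, logical(1))]
  res <- lapply(cols, function(cn) {
    fit <- lm(scores[[cn]] ~ groups)
    an <- anova(fit)
    data.frame(score = cn, F = an$`F value`[1], df1 = an$Df[1],
               df2 = an$Df[2], p = an$`Pr(>F)`[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
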