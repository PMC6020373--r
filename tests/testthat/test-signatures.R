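test_that("axis_score recovers a planted one-factor module", {
  set.seed(21)
  n <- 150; m <- 20
  f <- rnorm(n)
  X <- outer(rep(1, m), f) + matrix(rnorm(m * n, 0, 0.3), m, n)
  expr <- as_expr(X)
  sc <- axis_score(expr, rownames(expr_values(expr)))
  expect_gt(abs(cor(sc$score, f)), 0.99)
  # orientation: positive mean loading, so score tracks f positively
  expect_gt(cor(sc$score, f), 0)
  expect_gt(attr(sc, "variance_explained"), 0.7)
})

test_that("identical expression rows give 100% variance explained", {
  n <- 40
  prof <- rnorm(n)
  X <- rbind(a = prof, b = prof, c = prof)
  colnames(X) <- sprintf("S%03d", seq_len(n))
  sc <- axis_score(expression_matrix(X, unit = "log_normalized"),
                   c("a", "b", "c"))
  expect_equal(attr(sc, "variance_explained"), 1)
  # scores equal the (scaled) centered shared profile
  expect_gt(abs(cor(sc$score, prof)), 1 - 1e-10)
})

test_that("axis_score is affine-invariant per gene and odd under negation", {
  set.seed(22)
  X <- matrix(rnorm(10 * 50), 10, 50)
  expr <- as_expr(X)
  sc <- axis_score(expr, rownames(expr_values(expr)))
  # per-gene affine rescaling changes nothing (genes standardized first)
  X2 <- X * runif(10, 0.5, 4) + rnorm(10)
  dimnames(X2) <- dimnames(expr_values(expr))
  sc2 <- axis_score(as_expr(X2), rownames(X2))
  expect_equal(sc2$score, sc$score, tolerance = 1e-8)
  # negating the matrix negates the score
  X3 <- -X
  dimnames(X3) <- dimnames(expr_values(expr))
  sc3 <- axis_score(as_expr(X3), rownames(X3))
  expect_equal(sc3$score, -sc$score, tolerance = 1e-8)
  expect_error(axis_score(expr, c("G001", "nope")), "fewer than 2")
})

test_that("btm_scores reduces to axis_score and keeps modules independent", {
  set.seed(23)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- rbind(outer(rep(1, 10), f1), outer(rep(1, 10), f2)) +
    matrix(rnorm(20 * n, 0, 0.3), 20, n)
  expr <- as_expr(X)
  ids <- rownames(expr_values(expr))
  coll <- list(A = ids[1:10], B = ids[11:20])
  # single-module collection == axis_score
  one <- btm_scores(expr, coll["A"])
  expect_equal(one$A, axis_score(expr, coll$A)$score)
  both <- btm_scores(expr, coll)
  # independent planted factors -> near-zero cross-module correlation
  expect_lt(abs(cor(both$A, both$B)), 0.15)
  # group means consistent with per-sample scores
  grp <- factor(rep(c("x", "y"), each = n / 2))
  gm <- attr(btm_scores(expr, coll, groups = grp), "group_means")
  expect_equal(gm["A", "x"], mean(both$A[grp == "x"]), tolerance = 1e-12)
  # unresolvable module skipped with warning
  expect_warning(btm_scores(expr, c(coll, list(C = c("zz1", "zz2")))),
                 "skipped")
})

test_that("cluster_samples separates blobs and reports sane membership", {
  set.seed(24)
  n_half <- 30
  X <- cbind(matrix(rnorm(40 * n_half, -2), 40, n_half),
             matrix(rnorm(40 * n_half, 2), 40, n_half))
  truthlab <- rep(1:2, each = n_half)
  expr <- zscore_expression(as_expr(X))
  cl <- cluster_samples(expr, k = 2, groups = factor(truthlab))
  expect_equal(adjusted_rand_index(cl$clusters, truthlab), 1)
  expect_equal(unname(rowSums(cl$membership)), c(1, 1), tolerance = 1e-12)
  expect_error(cluster_samples(expr, k = 100), "exceeds")
})

test_that("cluster recovery matches the mclust adjusted Rand oracle", {
  skip_if_not_installed("mclust")
  set.seed(25)
  k <- 4; per <- 15
  centers <- matrix(rnorm(30 * k, sd = 3), 30, k)
  X <- do.call(cbind, lapply(1:k, function(j)
    centers[, j] + matrix(rnorm(30 * per), 30, per)))
  truthlab <- rep(1:k, each = per)
  cl <- cluster_samples(zscore_expression(as_expr(X)), k = k)
  ari <- adjusted_rand_index(cl$clusters, truthlab)
  expect_equal(ari, mclust::adjustedRandIndex(cl$clusters, truthlab),
               tolerance = 1e-12)
  expect_gt(ari, 0.8)
})

test_that("pvca attributes variance where it was planted", {
  set.seed(26)
  n <- 200; n_genes <- 300
  grp <- factor(rep(c("a", "b"), each = n / 2))
  u <- scale(as.numeric(grp == "b"))[, 1]
  # independent factor -> share ~ 0
  noisefac <- factor(sample(1:2, n, TRUE))
  b <- sqrt(0.3 / 0.7)
  X <- outer(rep(b, n_genes), u) + matrix(rnorm(n_genes * n), n_genes, n)
  expr <- as_expr(X)
  res <- pvca(expr, data.frame(grp = grp, noise = noisefac), n_pc = 5)
  p_grp <- res$weighted_proportion[res$factor == "grp"]
  p_noise <- res$weighted_proportion[res$factor == "noise"]
  expect_lt(abs(p_grp - 0.3), 0.1)
  expect_lt(p_noise, 0.02)
  expect_true(all(res$weighted_proportion >= -1e-12))
  expect_equal(sum(res$weighted_proportion), 1, tolerance = 1e-12)
  # permutation sanity: permuting the factor labels kills its share
  res_perm <- pvca(expr, data.frame(grp = sample(grp), noise = noisefac),
                   n_pc = 5)
  expect_lt(res_perm$weighted_proportion[res_perm$factor == "grp"], 0.02)
})

test_that("pvca closed form: factor fully determining PC1 at 50% variance", {
  set.seed(27)
  n <- 100; n_genes <- 200
  grp <- factor(rep(c("a", "b"), each = n / 2))
  u <- scale(as.numeric(grp == "b"))[, 1]
  # common component variance == noise variance => PC1 share ~ 0.5
  b <- rep(1, n_genes)
  X <- outer(b, u) * sqrt(n_genes) /
    sqrt(n_genes) + matrix(rnorm(n_genes * n, 0, 1), n_genes, n)
  # scale common part so its total variance equals the noise total
  X <- outer(b * sqrt(1), u) + matrix(rnorm(n_genes * n, 0, 1), n_genes, n)
  res <- pvca(as_expr(X), data.frame(grp = grp), n_pc = 30)
  expect_lt(abs(res$weighted_proportion[res$factor == "grp"] - 0.5), 0.06)
})

test_that("pvca rejects aliased factors", {
  grp <- factor(rep(c("a", "b"), each = 10))
  dup <- factor(rep(c("x", "y"), each = 10))   # same partition, new labels
  X <- matrix(rnorm(50 * 20), 50, 20)
  expect_error(pvca(as_expr(X), data.frame(grp = grp, dup = dup)),
               "aliased.*dup")
})

test_that("differential expression is calibrated under the null and
           powered under planted shifts", {
  set.seed(28)
  # null: BH at 5% rarely rejects anything
  n_sig <- vapply(1:10, function(i) {
    X <- matrix(rnorm(1000 * 30), 1000, 30)
    de <- differential_expression(as_expr(X), rep(c("a", "b"), each = 15),
                                  "a", "b")
    sum(de$significant)
  }, numeric(1))
  expect_gte(sum(n_sig <= 2), 9)
  # planted 2-SD shifts in 50 of 1000 genes
  X <- matrix(rnorm(1000 * 60), 1000, 60)
  X[1:50, 1:30] <- X[1:50, 1:30] + 2
  de <- differential_expression(as_expr(X), rep(c("a", "b"), each = 30),
                                "a", "b")
  called <- which(de$significant)
  expect_gt(mean(1:50 %in% called), 0.9)              # recall
  expect_lte(mean(!(called %in% 1:50)), 0.07)         # empirical FDR
  # direction labels agree with raw group-mean differences
  diffs <- rowMeans(X[called, 1:30, drop = FALSE]) -
    rowMeans(X[called, 31:60, drop = FALSE])
  expect_identical(de$direction[called],
                   ifelse(diffs >= 0, "up_in_A", "up_in_B"))
})

test_that("differential expression handles degenerate genes and matches
           limma's ordinary t-statistics", {
  set.seed(29)
  X <- matrix(rnorm(50 * 20), 50, 20)
  X[7, ] <- 3                        # constant gene
  labels <- rep(c("a", "b"), each = 10)
  de <- differential_expression(as_expr(X), labels, "a", "b")
  expect_true(de$degenerate[7])
  expect_equal(de$p[7], 1)
  skip_if_not_installed("limma")
  design <- cbind(1, as.numeric(labels == "a"))
  fit <- limma::lmFit(X[-7, ], design)
  t_ord <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * fit$sigma)
  expect_equal(unname(de$t[-7]), unname(t_ord), tolerance = 1e-10)
})

test_that("group ANOVA: F equals t-squared for two groups; calibrated null;
           power under ordered means", {
  set.seed(30)
  x <- rnorm(40)
  grp <- factor(rep(c("a", "b"), each = 20))
  sc <- data.frame(sample_id = sprintf("S%02d", 1:40), s = x)
  an <- group_anova(sc, grp)
  tt <- t.test(x ~ grp, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)
  # null calibration over replicates
  ps <- vapply(1:1000, function(i) {
    y <- rnorm(30)
    g <- factor(rep(1:3, each = 10))
    anova(lm(y ~ g))$`Pr(>F)`[1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # ordered planted means: decisive p
  y <- rnorm(90) + rep(c(0, 1, 2), each = 30)
  sc2 <- data.frame(sample_id = sprintf("S%02d", 1:90), s = y)
  an2 <- group_anova(sc2, factor(rep(1:3, each = 30)))
  expect_lt(an2$p, 1e-6)
  expect_error(group_anova(sc2, factor(rep(1, 90))), "2 groups")
})
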