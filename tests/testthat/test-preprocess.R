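test_that("FPKM follows its definition on constructed matrices", {
  # library size exactly 1e6: count 100 at length 1 kb -> FPKM 100
  cm <- toy_counts(cbind(s1 = c(100, 0, 999900)),
                   lengths = c(1000L, 2000L, 500L))
  f <- compute_fpkm(cm)
  expect_equal(unname(expr_values(f)["G001", "s1"]), 100)
  expect_equal(unname(expr_values(f)["G002", "s1"]), 0)  # all-zero gene
  expect_equal(f$unit, "fpkm")
  # 3-gene, 2-sample toy vs hand-computed spreadsheet arithmetic
  counts <- cbind(a = c(10, 20, 70), b = c(5, 5, 190))
  lens <- c(500L, 2000L, 1000L)
  f2 <- expr_values(compute_fpkm(toy_counts(counts, lens)))
  lib <- colSums(counts)
  hand <- counts / ((lens / 1000) %o% (lib / 1e6))
  expect_equal(unname(f2), unname(hand))
})

test_that("FPKM input validation", {
  cm <- toy_counts(cbind(s1 = c(1, 2), s2 = c(0, 0)))
  expect_error(compute_fpkm(cm), "zero library size.*s2")
  cm2 <- toy_counts(cbind(s1 = c(1, 2)))
  cm2$genes$length[1] <- NA
  expect_error(compute_fpkm(cm2), "length")
  nm <- normalize_expression(toy_counts(cbind(s1 = c(1, 2))))
  expect_error(compute_fpkm(nm), "raw counts")
})

test_that("expression filter applies the stated thresholds strictly", {
  # 7 reads in 11 of 12 samples: 11 > 10 qualifies; FPKM kept high by a
  # short length. "lowfpkm" has the same counts but a 100 kb length, which
  # pushes mean FPKM below 0.1.
  m <- matrix(0, 3, 12, dimnames = list(c("keep", "lowfpkm", "lib"), NULL))
  m["keep", 1:11] <- 7
  m["lowfpkm", 1:11] <- 7
  m["lib", ] <- 1e6                # fills library so FPKM is computable
  cm <- toy_counts(m, lengths = c(400L, 100000L, 1000L))
  kept <- filter_expressed_genes(cm)
  expect_identical(rownames(expr_values(kept)), c("keep", "lib"))
  rep <- attr(kept, "filter_report")
  expect_false(rep$kept[rep$gene_id == "lowfpkm"])
  expect_match(rep$reason[rep$gene_id == "lowfpkm"], "low_fpkm")
  # exactly 10 samples over the count threshold is NOT enough (strict >)
  m2 <- m; m2["keep", ] <- 0; m2["keep", 1:10] <- 7
  k2 <- filter_expressed_genes(toy_counts(m2, lengths = c(400L, 100000L, 1000L)))
  expect_false("keep" %in% rownames(expr_values(k2)))
  # counts of exactly 6 never count as expressed (strict >)
  m3 <- m; m3["keep", ] <- 6
  k3 <- filter_expressed_genes(toy_counts(m3, lengths = c(400L, 100000L, 1000L)))
  expect_false("keep" %in% rownames(expr_values(k3)))
})

test_that("filter agrees with a brute-force oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:3) {
    m <- matrix(rpois(200 * 15, lambda = sample(c(0.5, 3, 8), 200, TRUE)),
                200, 15)
    lens <- sample(200:5000, 200, TRUE)
    cm <- toy_counts(m, lengths = as.integer(lens))
    kept <- filter_expressed_genes(cm, min_individuals = 5, min_count = 2,
                                   min_fpkm = 50)
    # oracle: direct boolean scan, independent arithmetic
    lib <- colSums(m)
    fpkm <- sapply(seq_len(ncol(m)),
                   function(s) m[, s] / (lens / 1000) / (lib[s] / 1e6))
    want <- rowSums(m > 2) > 5 & rowMeans(fpkm) > 50
    expect_identical(rownames(expr_values(kept)),
                     rownames(expr_values(cm))[want])
    twice <- filter_expressed_genes(kept, min_individuals = 5,
                                    min_count = 2, min_fpkm = 50)
    expect_identical(expr_values(twice), expr_values(kept))
  }
})

test_that("log-CPM normalization is scale invariant and matches hand math", {
  base <- cbind(s1 = c(10, 40, 50), s2 = c(20, 80, 100))  # s2 = 2 x s1
  nm <- expr_values(normalize_expression(toy_counts(base)))
  expect_equal(unname(nm[, "s1"]), unname(nm[, "s2"]))
  # hand-computed log2(cpm + 1) for a 4 x 3 toy
  m <- matrix(c(1, 2, 3, 4, 10, 0, 5, 5, 2, 8, 0, 10), 4, 3)
  got <- expr_values(normalize_expression(toy_counts(m)))
  hand <- log2(sweep(m, 2, colSums(m) / 1e6, "/") + 1)
  expect_equal(unname(got), unname(hand))
})

test_that("latent-factor adjustment removes a planted batch and keeps the
           disease signal", {
  set.seed(7)
  n <- 120; n_genes <- 300
  disease <- rep(c(0, 1), each = n / 2)
  batch <- rnorm(n)                       # orthogonal to disease by design
  batch <- resid(lm(batch ~ disease))
  shift <- rnorm(n_genes, 0, 0.5)         # per-gene disease effect
  bload <- rnorm(n_genes, 0, 1)           # per-gene batch loading
  X <- outer(shift, disease) + outer(bload, batch) +
    matrix(rnorm(n_genes * n, 0, 0.5), n_genes, n)
  expr <- as_expr(X)
  adj <- adjust_latent_factors(expr, data.frame(disease = factor(disease)),
                               n_factors = 1)
  # batch association is gone
  cors <- apply(expr_values(adj), 1, cor, y = batch)
  expect_lt(max(abs(cors)), 0.05)
  # planted disease shifts retained within 10% (vs oracle: regressing out
  # the true batch vector directly)
  est_shift <- rowMeans(expr_values(adj)[, disease == 1]) -
    rowMeans(expr_values(adj)[, disease == 0])
  oracle <- t(apply(X, 1, function(y) resid(lm(y ~ batch))))
  oracle_shift <- rowMeans(oracle[, disease == 1]) -
    rowMeans(oracle[, disease == 0])
  fit <- lm(est_shift ~ 0 + oracle_shift)
  expect_lt(abs(coef(fit)[1] - 1), 0.1)
  expect_gt(cor(est_shift, oracle_shift), 0.95)
})

test_that("latent-factor adjustment contracts hold", {
  set.seed(8)
  expr <- as_expr(matrix(rnorm(50 * 30), 50, 30))
  prot <- data.frame(g = factor(rep(1:2, each = 15)))
  expect_identical(adjust_latent_factors(expr, prot, n_factors = 0), expr)
  adj <- adjust_latent_factors(expr, prot, n_factors = 3)
  expect_identical(dim(adj), dim(expr))
  expect_identical(rownames(expr_values(adj)), rownames(expr_values(expr)))
  expect_error(adjust_latent_factors(expr, prot, n_factors = 40),
               "n_factors")
  bad <- data.frame(g = factor(rep(1:2, each = 15)),
                    g2 = factor(rep(c("a", "b"), each = 15)))
  expect_error(adjust_latent_factors(expr, bad, n_factors = 2),
               "collinear|aliased")
})

test_that("genotype QC defaults and per-rule behaviour", {
  th <- qc_thresholds()
  expect_equal(th$hwe_p_min, 1e-3)
  expect_equal(th$maf_min, 0.01)
  expect_equal(th$missing_max, 0.05)
  expect_true(th$biallelic_only)
  set.seed(9)
  n <- 200
  d <- rbind(good = rdosage(n, 0.3),
             mono = rep(0L, n),                       # MAF 0
             hwe_bad = rep(1L, n),                    # all hets
             missing = c(rep(NA, 20), rdosage(n - 20, 0.3)),
             multi = rdosage(n, 0.4))
  g <- as_geno(d)
  g$snps$alt[g$snps$snp_id == "multi"] <- "G,T"
  qc <- qc_genotypes(g)
  expect_identical(rownames(geno_dosages(qc)), "good")
  rep <- attr(qc, "qc_report")
  expect_equal(rep$n_kept, 1)
  expect_gte(rep$dropped[["hwe"]], 1)
  expect_gte(rep$dropped[["maf"]], 1)
  expect_gte(rep$dropped[["missing"]], 1)
  expect_gte(rep$dropped[["non_biallelic"]], 1)
})

test_that("QC agrees with an independent per-rule oracle and is idempotent", {
  set.seed(10)
  n <- 150
  d <- t(vapply(1:20, function(i) {
    p <- runif(1, 0.005, 0.5)
    x <- rdosage(n, p)
    x[runif(n) < runif(1, 0, 0.1)] <- NA
    x
  }, integer(n)))
  # plant one HWE violation
  d[3, ] <- rep(c(1L, 1L, 1L, 0L), length.out = n)
  rownames(d) <- sprintf("rs%03d", seq_len(nrow(d)))
  g <- as_geno(d)
  th <- qc_thresholds()
  qc <- qc_genotypes(g, th)
  # oracle: each rule applied independently by direct scan
  keep <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, ]; x <- x[!is.na(x)]
    maf <- min(mean(x) / 2, 1 - mean(x) / 2)
    hwe <- hwe_test(sum(x == 0), sum(x == 1), sum(x == 2))
    miss <- mean(is.na(d[i, ]))
    maf >= th$maf_min && hwe >= th$hwe_p_min && miss <= th$missing_max
  }, logical(1))
  expect_identical(rownames(geno_dosages(qc)), rownames(d)[keep])
  expect_false(keep[3])
  twice <- qc_genotypes(qc, th)
  expect_identical(geno_dosages(twice), geno_dosages(qc))
})

test_that("QC warns and returns empty when everything fails", {
  d <- rbind(a = rep(0L, 50), b = rep(2L, 50))
  expect_warning(qc <- qc_genotypes(as_geno(d)), "all SNPs removed")
  expect_equal(nrow(geno_dosages(qc)), 0)
})

test_that("exact and chi-square HWE tests agree where both are valid", {
  # large balanced counts: exact ~ chi-square
  expect_equal(hwe_exact_p(360, 480, 160), hwe_chisq_p(360, 480, 160),
               tolerance = 0.05)
  # perfect HWE proportions give high p under both
  expect_gt(hwe_exact_p(250, 500, 250), 0.5)
  expect_gt(hwe_chisq_p(250, 500, 250), 0.5)
  # gross violation: tiny p under both
  expect_lt(hwe_exact_p(50, 0, 50), 1e-10)
  expect_lt(hwe_chisq_p(50, 0, 50), 1e-10)
  # exact test matches a direct enumeration oracle on a small panel
  n0 <- 6; n1 <- 2; n2 <- 2
  n <- n0 + n1 + n2; rare <- 2 * min(n0, n2) + n1
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    hr <- (rare - h) / 2; hc <- n - h - hr
    exp(lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
          h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  oracle <- sum(pr[pr <= pr[hets == n1] + 1e-12])
  expect_equal(hwe_exact_p(n0, n1, n2), oracle, tolerance = 1e-10)
})
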