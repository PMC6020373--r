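test_that("cis pairing honors inclusive window bounds", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = 1000000L, stop = 1005000L)
  snps <- data.frame(snp_id = c("at_start", "at_edge", "past_edge",
                                "upstream_edge", "inside"),
                     chrom = "chr1",
                     pos = c(1000000L, 1005000L + 250000L,
                             1005000L + 250001L, 1000000L - 250000L,
                             1002500L))
  pairs <- build_cis_pairs(genes, snps, window = 250000)
  expect_setequal(pairs$snp_id,
                  c("at_start", "at_edge", "upstream_edge", "inside"))
  expect_equal(pairs$distance[pairs$snp_id == "at_start"], 0L)
  expect_equal(pairs$distance[pairs$snp_id == "at_edge"], 250000L)
  expect_equal(pairs$distance[pairs$snp_id == "upstream_edge"], -250000L)
})

test_that("cis pairing matches a brute-force all-pairs scan and is
           monotone in the window", {
  set.seed(31)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
                      start = sort(sample.int(5e6, 10)))
  genes$stop <- genes$start + sample(1000:20000, 10)
  snps <- data.frame(snp_id = sprintf("s%03d", 1:100), chrom = "chr1",
                     pos = sort(sample.int(5e6, 100)))
  w <- 100000
  pairs <- build_cis_pairs(genes, snps, window = w)
  oracle <- do.call(rbind, lapply(1:100, function(i) {
    hit <- which(snps$pos[i] >= genes$start - w & snps$pos[i] <= genes$stop + w)
    if (length(hit))
      data.frame(snp_id = snps$snp_id[i], gene_id = genes$gene_id[hit])
  }))
  expect_setequal(paste(pairs$snp_id, pairs$gene_id),
                  paste(oracle$snp_id, oracle$gene_id))
  pairs2 <- build_cis_pairs(genes, snps, window = 2 * w)
  expect_true(all(paste(pairs$snp_id, pairs$gene_id) %in%
                    paste(pairs2$snp_id, pairs2$gene_id)))
  # chromosome naming mismatch is a hard error
  snps_bad <- snps; snps_bad$chrom <- "1"
  expect_error(build_cis_pairs(genes, snps_bad, w), "chromosome")
})

test_that("fit_eqtl basics: perfect fit, equivariance, constant covariate", {
  set.seed(32)
  g <- rdosage(100, 0.3)
  # expression == dosage exactly
  rec <- fit_eqtl(g, as.numeric(g))
  expect_equal(rec$beta, 1, tolerance = 1e-12)
  expect_equal(rec$p, 1e-300)
  # scaling expression by c scales beta and se by c; p unchanged
  y <- 0.5 * g + rnorm(100)
  r1 <- fit_eqtl(g, y)
  r3 <- fit_eqtl(g, 3 * y)
  expect_equal(r3$beta, 3 * r1$beta, tolerance = 1e-10)
  expect_equal(r3$se, 3 * r1$se, tolerance = 1e-10)
  expect_equal(r3$p, r1$p, tolerance = 1e-10)
  # constant covariate column is a no-op
  r_const <- fit_eqtl(g, y, covariates = cbind(const = rep(2, 100)))
  expect_equal(r_const$beta, r1$beta, tolerance = 1e-10)
  expect_equal(r_const$p, r1$p, tolerance = 1e-10)
  # degenerate cases
  expect_equal(fit_eqtl(rep(1, 100), y)$flag, "monomorphic")
  expect_equal(fit_eqtl(g[1:5], y[1:5])$flag, "skipped_low_n")
})

test_that("fit_eqtl matches lm() and has nominal coverage", {
  set.seed(33)
  for (i in 1:5) {
    g <- rdosage(80, 0.25)
    cov <- cbind(a = rnorm(80), b = rnorm(80))
    y <- 0.4 * g + 0.3 * cov[, 1] + rnorm(80)
    rec <- fit_eqtl(g, y, covariates = cov)
    fit <- summary(lm(y ~ g + cov))$coefficients
    expect_equal(rec$beta, fit["g", 1], tolerance = 1e-10)
    expect_equal(rec$se, fit["g", 2], tolerance = 1e-10)
    expect_equal(rec$p, fit["g", 4], tolerance = 1e-10)
  }
  # coverage: beta within +-2 se in ~95% of replicates
  hits <- vapply(1:500, function(i) {
    g <- rdosage(500, 0.3)
    y <- 0.5 * g + rnorm(500)
    r <- fit_eqtl(g, y)
    abs(r$beta - 0.5) <= 2 * r$se
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("fit_eqtl p-values are uniform under permuted expression", {
  set.seed(34)
  ps <- vapply(1:1000, function(i) {
    g <- rdosage(60, 0.3)
    fit_eqtl(g, rnorm(60))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("peak selection equals the per-pair minimum-p oracle", {
  set.seed(35)
  cfg <- small_config(seed = 35, maf_range = c(0.2, 0.5))
  plan <- auto_eqtl_plan(cfg, 10, 0.8 * rep_len(c(1, -1), 10))
  cfg <- small_config(seed = 35, maf_range = c(0.2, 0.5), eqtl_plan = plan)
  sim <- simulate_cohort(cfg, gwas = FALSE)
  pairs <- build_cis_pairs(sim$expr, sim$genotypes)
  cs <- call_eqtls(pairs, sim$genotypes, sim$expr, n_perms = 0,
                   cohort = "ALL")
  # oracle: fit every pair independently with fit_eqtl, take min p per gene
  for (gene in sample(unique(pairs$gene_id), 15)) {
    snp_ids <- pairs$snp_id[pairs$gene_id == gene]
    ps <- vapply(snp_ids, function(s)
      fit_eqtl(geno_dosages(sim$genotypes)[s, ],
               expr_values(sim$expr)[gene, ])$p, numeric(1))
    peak <- cs$peaks[cs$peaks$gene_id == gene, ]
    expect_equal(peak$p, min(ps), tolerance = 1e-9)
    expect_equal(peak$snp_id, snp_ids[which.min(ps)])
  }
  # single-pair gene: the peak is that pair
  one <- pairs[pairs$gene_id == pairs$gene_id[1], ][1, ]
  cs1 <- call_eqtls(one, sim$genotypes, sim$expr, n_perms = 0)
  expect_equal(cs1$peaks$snp_id, one$snp_id)
})

test_that("empirical FDR calibrates on pure-null data", {
  cfg <- small_config(seed = 36)
  sim <- simulate_cohort(cfg, gwas = FALSE)
  pairs <- build_cis_pairs(sim$expr, sim$genotypes)
  # lenient threshold so null hits occur; all of them are false
  cs <- call_eqtls(pairs, sim$genotypes, sim$expr, p_threshold = 0.05,
                   n_perms = 20, seed = 1)
  expect_gt(nrow(cs$calls), 0)
  expect_gt(cs$fdr, 0.7)                    # ~ everything called is false
  expect_lt(abs(mean(cs$perm_hits) - nrow(cs$calls)) /
              max(nrow(cs$calls), 1), 0.6)
})

test_that("planted eQTL are recovered with controlled FDR", {
  cfg0 <- sim_config(n_samples_per_group = c(JIA = 109), n_genes = 200,
                     n_snps = 400, maf_range = c(0.2, 0.5),
                     module_size = 10, n_modules = 5, seed = 37)
  plan <- auto_eqtl_plan(cfg0, 20, 0.8 * rep_len(c(1, -1), 20))
  cfg <- sim_config(n_samples_per_group = c(JIA = 109), n_genes = 200,
                    n_snps = 400, maf_range = c(0.2, 0.5),
                    module_size = 10, n_modules = 5, eqtl_plan = plan,
                    seed = 37)
  sim <- simulate_cohort(cfg, gwas = FALSE)
  # soak up module factors and confounders before mapping, as the full
  # pipeline does
  adj <- adjust_latent_factors(sim$expr, data.frame(group = sim$labels),
                               n_factors = 10)
  pairs <- build_cis_pairs(adj, sim$genotypes)
  cs <- call_eqtls(pairs, sim$genotypes, adj, n_perms = 20, seed = 2)
  called_planted <- intersect(cs$calls$gene_id, plan$gene_id)
  expect_gte(length(called_planted) / nrow(plan), 0.8)
  expect_lte(cs$fdr, 0.10)
})

test_that("MAF-significance diagnostic flags single-outlier eQTL", {
  set.seed(38)
  n <- 109
  # one genuine eQTL and one fake driven by a single minor homozygote
  g_real <- rdosage(n, 0.4)
  y_real <- 0.9 * g_real + rnorm(n)
  g_fake <- c(2L, rep(0:1, length.out = n - 1))   # a lone minor homozygote
  y_fake <- rnorm(n); y_fake[1] <- 8              # extreme outlier
  d <- rbind(real = g_real, fake = g_fake)
  X <- rbind(G1 = y_real, G2 = y_fake)
  colnames(d) <- colnames(X) <- sprintf("S%03d", 1:n)
  geno <- as_geno(d, pos = c(1000L, 500000L))
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                      start = c(500L, 499500L), stop = c(1500L, 500500L),
                      length = 1000L)
  expr <- expression_matrix(X, genes, unit = "log_normalized")
  pairs <- data.frame(snp_id = c("real", "fake"), gene_id = c("G1", "G2"))
  cs <- call_eqtls(pairs, geno, expr, p_threshold = 1e-3, n_perms = 0)
  expect_setequal(cs$calls$gene_id, c("G1", "G2"))
  chk <- maf_significance_check(cs, geno, expr)
  expect_true("G2" %in% chk$flagged$gene_id)      # outlier-driven call dies
  expect_false("G1" %in% chk$flagged$gene_id)     # genuine call survives
})

test_that("MAF vs significance shows no relationship in balanced
           simulations", {
  set.seed(39)
  n <- 150; n_loci <- 120
  d <- t(vapply(seq_len(n_loci), function(i)
    rdosage(n, runif(1, 0.1, 0.5)), integer(n)))
  rownames(d) <- sprintf("rs%03d", seq_len(n_loci))
  # null pairs: with no genotype effect, significance carries no MAF signal
  X <- matrix(rnorm(n_loci * n), n_loci, n)
  rownames(X) <- sprintf("G%03d", seq_len(n_loci))
  colnames(d) <- colnames(X) <- sprintf("S%03d", seq_len(n))
  geno <- as_geno(d, pos = seq_len(n_loci) * 1000000L)
  genes <- data.frame(gene_id = rownames(X), chrom = "chr1",
                      start = seq_len(n_loci) * 1000000L - 500L,
                      stop = seq_len(n_loci) * 1000000L + 500L,
                      length = 1000L)
  expr <- expression_matrix(X, genes, unit = "log_normalized")
  pairs <- data.frame(snp_id = rownames(d), gene_id = rownames(X))
  cs <- call_eqtls(pairs, geno, expr, p_threshold = 1, n_perms = 0)
  chk <- maf_significance_check(cs, geno, expr, refit_threshold = 1)
  expect_lt(abs(chk$correlation), 0.25)
  expect_equal(nrow(chk$flagged), 0)
})
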