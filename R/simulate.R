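#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by the generator: a whole-blood
#' cohort of six disease groups (healthy controls; oligoarticular,
#' polyarticular and systemic JIA; Crohn's disease; ulcerative colitis),
#' HWE genotypes with first-order LD blocks, co-expression modules driven by
#' latent immune axes, planted cis-eQTL (shared or disease-specific), group
#' mean shifts along modules, latent confounders, and Gaussian residual
#' noise on the log-expression scale.
#'
#' @param n_samples_per_group named integer vector: samples per disease
#'   group. The default mirrors a 202-subject pediatric cohort
#'   (12 controls, 43 oligoarticular / 46 polyarticular / 26 systemic JIA,
#'   60 Crohn's disease, 15 ulcerative colitis).
#' @param n_genes,n_snps number of genes / SNPs.
#' @param maf_range length-2 numeric in (0, 0.5]: per-SNP minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho within-block haplotype copying probability in `[0, 1]`:
#'   each haplotype copies the previous SNP's allele with probability
#'   `ld_rho`, otherwise redraws from the allele frequency.
#' @param n_modules,module_size co-expression modules and genes per module.
#' @param loading_sd SD of gene loadings on their module factor (loadings
#'   are centred at 1 so a module moves coherently with its factor).
#' @param n_latent_confounders number of latent (batch-like) confounders
#'   loading on all genes.
#' @param confounder_loading_sd SD of per-gene confounder loadings.
#' @param eqtl_plan data.frame of planted cis-eQTL as built by
#'   [planted_eqtl()] / [auto_eqtl_plan()]: columns `snp_id`, `gene_id` and
#'   one `beta_<group>` column per disease group (expression SD units per
#'   alt-allele copy). NULL = no planted eQTL.
#' @param group_shift_plan data.frame with columns `module`, `group`,
#'   `shift`: mean shift (factor SD units) applied to a module's latent
#'   factor in a disease group. NULL = no shifts.
#' @param noise_sd residual SD on the log-expression scale.
#' @param missing_rate fraction of dosages set to missing (exercises QC).
#' @param seed integer seed; a fixed seed yields bit-identical output
#'   (R's default Mersenne-Twister RNG).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_samples_per_group = c(control = 12, oligoJIA = 43,
                                               polyJIA = 46, sJIA = 26,
                                               CD = 60, UC = 15),
                       n_genes = 500, n_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 5, ld_rho = 0.9,
                       n_modules = 7, module_size = 20,
                       loading_sd = 0.25,
                       n_latent_confounders = 2,
                       confounder_loading_sd = 0.3,
                       eqtl_plan = NULL, group_shift_plan = NULL,
                       noise_sd = 1, missing_rate = 0, seed = 1L) {
  cfg <- list(n_samples_per_group = n_samples_per_group, n_genes = n_genes,
              n_snps = n_snps, maf_range = maf_range,
              ld_block_size = ld_block_size, ld_rho = ld_rho,
              n_modules = n_modules, module_size = module_size,
              loading_sd = loading_sd,
              n_latent_confounders = n_latent_confounders,
              confounder_loading_sd = confounder_loading_sd,
              eqtl_plan = eqtl_plan, group_shift_plan = group_shift_plan,
              noise_sd = noise_sd, missing_rate = missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$n_samples_per_group)) ||
      any(!nzchar(names(cfg$n_samples_per_group))))
    stop("n_samples_per_group must be a named vector of group sizes")
  counts <- c(cfg$n_samples_per_group, cfg$n_genes, cfg$n_snps,
              cfg$ld_block_size, cfg$n_modules, cfg$module_size)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("all counts in sim_config must be positive integers")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$ld_rho < 0 || cfg$ld_rho > 1) stop("ld_rho must be in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop("n_modules * module_size exceeds n_genes")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(cfg)
}

# genome layout: one chromosome, genes every 100 kb, SNPs evenly spread.
# Deterministic given the config seed so genotype and expression generators
# agree on coordinates without sharing state.
.GENE_SPACING <- 1e5

sim_layout <- function(config) {
  set.seed(config$seed + 1L)
  n_genes <- config$n_genes
  n_snps <- config$n_snps
  span <- n_genes * .GENE_SPACING
  gene_len <- round(runif(n_genes, 500, 5000))
  gene_start <- as.integer((seq_len(n_genes) - 1L) * .GENE_SPACING + 40000L)
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = "chr1",
    start = gene_start,
    stop = as.integer(gene_start + gene_len - 1L),
    length = as.integer(gene_len),
    stringsAsFactors = FALSE)
  snps <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(n_snps)),
    chrom = "chr1",
    pos = as.integer(round(seq_len(n_snps) * span / (n_snps + 1))),
    ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  list(genes = genes, snps = snps)
}

#' Sample labels implied by a sim_config
#'
#' @param config a [sim_config()].
#' @return factor of group labels named by sample id (`S001`, ...).
#' @export
sim_labels <- function(config) {
  groups <- rep(names(config$n_samples_per_group), config$n_samples_per_group)
  n <- length(groups)
  setNames(factor(groups, levels = names(config$n_samples_per_group)),
           sprintf("S%03d", seq_len(n)))
}

#' Build a planted-eQTL plan row set
#'
#' @param snp_id,gene_id character vectors (recycled to common length).
#' @param beta either a single number / vector of length `n` (shared effect
#'   across disease groups) or a named vector / list of per-group effects.
#' @param groups character vector of all group labels in the cohort.
#' @return data.frame with `snp_id`, `gene_id` and `beta_<group>` columns.
#' @export
planted_eqtl <- function(snp_id, gene_id, beta, groups) {
  n <- max(length(snp_id), length(gene_id))
  snp_id <- rep_len(snp_id, n); gene_id <- rep_len(gene_id, n)
  plan <- data.frame(snp_id = snp_id, gene_id = gene_id,
                     stringsAsFactors = FALSE)
  if (!is.null(names(beta))) {
    if (!all(names(beta) %in% groups))
      stop("beta names must be disease group labels")
    for (g in groups)
      plan[[paste0("beta_", g)]] <- if (g %in% names(beta)) rep_len(beta[[g]], n) else 0
  } else {
    b <- rep_len(beta, n)
    for (g in groups) plan[[paste0("beta_", g)]] <- b
  }
  plan
}

#' Automatically place planted cis-eQTL
#'
#' Picks `n` evenly spaced genes and, for each, the closest SNP in the
#' simulated map (always within the cis window given the layout).
#'
#' @param config a [sim_config()].
#' @param n number of eQTL to plant.
#' @param beta as in [planted_eqtl()].
#' @return eQTL plan data.frame.
#' @export
auto_eqtl_plan <- function(config, n, beta) {
  layout <- sim_layout(config)
  stopifnot(n <= config$n_genes)
  gene_idx <- round(seq(1, config$n_genes, length.out = n))
  genes <- layout$genes[gene_idx, , drop = FALSE]
  mid <- (genes$start + genes$stop) / 2
  snp_idx <- vapply(mid, function(m) which.min(abs(layout$snps$pos - m)), 1L)
  if (anyDuplicated(snp_idx))
    stop("could not place distinct SNPs; increase n_snps")
  planted_eqtl(layout$snps$snp_id[snp_idx], genes$gene_id, beta,
               groups = names(config$n_samples_per_group))
}

#' Generate genotypes with HWE structure and LD blocks
#'
#' Two independent haplotypes per sample; within an LD block each haplotype
#' copies the previous SNP's allele with probability `ld_rho`, otherwise
#' redraws from that SNP's allele frequency. Genotype = haplotype sum, so
#' Hardy-Weinberg equilibrium holds by construction.
#'
#' @param config a [sim_config()].
#' @param keep_haplotypes if TRUE, the two haplotype matrices are attached
#'   as attribute `"haplotypes"` (for LD diagnostics).
#' @return a [genotype_matrix()] (alt-allele dosages); allele frequencies
#'   are attached as attribute `"allele_freq"`.
#' @export
generate_genotypes <- function(config, keep_haplotypes = FALSE) {
  validate_sim_config(config)
  layout <- sim_layout(config)
  labels <- sim_labels(config)
  n <- length(labels)
  m <- config$n_snps
  set.seed(config$seed + 2L)
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  block <- (seq_len(m) - 1L) %/% config$ld_block_size
  hap <- function() {
    H <- matrix(0L, m, n)
    for (j in seq_len(m)) {
      draw <- rbinom(n, 1L, p[j])
      if (j > 1L && block[j] == block[j - 1L]) {
        copy <- rbinom(n, 1L, config$ld_rho)
        H[j, ] <- ifelse(copy == 1L, H[j - 1L, ], draw)
      } else H[j, ] <- draw
    }
    H
  }
  h1 <- hap(); h2 <- hap()
  d <- h1 + h2
  if (config$missing_rate > 0) {
    miss <- runif(length(d)) < config$missing_rate
    d[miss] <- NA_integer_
  }
  dimnames(d) <- list(layout$snps$snp_id, names(labels))
  out <- genotype_matrix(d, layout$snps)
  attr(out, "allele_freq") <- setNames(p, layout$snps$snp_id)
  if (keep_haplotypes) attr(out, "haplotypes") <- list(h1 = h1, h2 = h2)
  out
}

#' Generate expression with modules, group shifts, planted eQTL and
#' confounders
#'
#' Per-gene log-scale value = module loading x latent factor (with per-group
#' shifts) + planted eQTL effects x dosage + confounder loadings x
#' confounder + baseline + Gaussian noise. A raw-count view is produced by
#' exponentiation and per-sample multinomial sampling (for filter tests).
#'
#' @param config a [sim_config()].
#' @param genotypes [genotype_matrix()] from [generate_genotypes()].
#' @param labels sample -> group factor as from [sim_labels()].
#' @return list with `expr` (log-scale [expression_matrix()]), `counts`
#'   (raw-count view) and `truth` (ground-truth record: factors, loadings,
#'   module membership, shifts, confounders, planted eQTL, library sizes).
#' @export
generate_expression <- function(config, genotypes, labels) {
  validate_sim_config(config)
  layout <- sim_layout(config)
  n <- length(labels)
  if (is.null(names(labels)) || !setequal(names(labels),
                                          colnames(genotypes$dosages)))
    stop("labels must be named and cover all genotyped samples")
  labels <- labels[colnames(genotypes$dosages)]
  groups <- names(config$n_samples_per_group)

  set.seed(config$seed + 3L)
  g_ids <- layout$genes$gene_id
  mu <- rnorm(config$n_genes, 5, 1.5)
  X <- matrix(rnorm(config$n_genes * n, 0, config$noise_sd),
              config$n_genes, n, dimnames = list(g_ids, names(labels)))
  X <- X + mu

  # co-expression modules
  module_genes <- split(g_ids[seq_len(config$n_modules * config$module_size)],
                        rep(seq_len(config$n_modules), each = config$module_size))
  names(module_genes) <- sprintf("M%02d", seq_len(config$n_modules))
  factors <- matrix(rnorm(config$n_modules * n), config$n_modules, n,
                    dimnames = list(names(module_genes), names(labels)))
  shifts <- config$group_shift_plan
  if (!is.null(shifts)) {
    stopifnot(all(c("module", "group", "shift") %in% names(shifts)))
    for (i in seq_len(nrow(shifts))) {
      mod <- shifts$module[i]
      if (!mod %in% rownames(factors)) stop("unknown module in shift plan: ", mod)
      sel <- labels == shifts$group[i]
      factors[mod, sel] <- factors[mod, sel] + shifts$shift[i]
    }
  }
  loadings <- lapply(module_genes, function(gs)
    setNames(rnorm(length(gs), 1, config$loading_sd), gs))
  for (m in names(module_genes))
    X[module_genes[[m]], ] <- X[module_genes[[m]], , drop = FALSE] +
      outer(loadings[[m]], factors[m, ])

  # latent confounders load on every gene
  confounders <- NULL; conf_loadings <- NULL
  if (config$n_latent_confounders > 0) {
    confounders <- matrix(rnorm(config$n_latent_confounders * n),
                          config$n_latent_confounders, n,
                          dimnames = list(
                            sprintf("C%02d", seq_len(config$n_latent_confounders)),
                            names(labels)))
    conf_loadings <- matrix(rnorm(config$n_genes * config$n_latent_confounders,
                                  0, config$confounder_loading_sd),
                            config$n_genes, config$n_latent_confounders,
                            dimnames = list(g_ids, rownames(confounders)))
    X <- X + conf_loadings %*% confounders
  }

  # planted cis-eQTL
  plan <- config$eqtl_plan
  if (!is.null(plan) && nrow(plan) > 0) {
    bad_snp <- setdiff(plan$snp_id, rownames(genotypes$dosages))
    bad_gene <- setdiff(plan$gene_id, g_ids)
    if (length(bad_snp) || length(bad_gene))
      stop("eqtl_plan references unknown ids: ",
           paste(c(bad_snp, bad_gene), collapse = ", "))
    beta_cols <- paste0("beta_", groups)
    if (!all(beta_cols %in% names(plan)))
      stop("eqtl_plan must carry beta_<group> columns for every group")
    for (i in seq_len(nrow(plan))) {
      dos <- impute_dosage(genotypes$dosages[plan$snp_id[i], ])
      bvec <- setNames(as.numeric(plan[i, beta_cols]),
                       sub("^beta_", "", beta_cols))
      X[plan$gene_id[i], ] <- X[plan$gene_id[i], ] +
        unname(bvec[as.character(labels)]) * dos
    }
  }

  expr <- expression_matrix(X, layout$genes, unit = "log_normalized")

  # raw-count view: per-sample multinomial over exponentiated abundances
  lib_sizes <- round(runif(n, 1.5e6, 2.5e6))
  lambda <- 2^X
  counts <- vapply(seq_len(n), function(s)
    rmultinom(1, lib_sizes[s], lambda[, s])[, 1], numeric(config$n_genes))
  dimnames(counts) <- dimnames(X)
  counts_em <- expression_matrix(counts, layout$genes, unit = "raw_count")

  truth <- list(labels = labels, module_genes = module_genes,
                loadings = loadings, factors = factors,
                group_shift_plan = shifts, confounders = confounders,
                confounder_loadings = conf_loadings, eqtl_plan = plan,
                baseline = setNames(mu, g_ids),
                lib_sizes = setNames(lib_sizes, names(labels)))
  list(expr = expr, counts = counts_em, truth = truth)
}

#' Generate GWAS summary statistics with known risk-allele directions
#'
#' For every planted eQTL locus, a disease-association signal is placed at
#' the planted SNP (risk allele chosen at random between ref and alt, odds
#' ratio `risk_or`) and propagated to the locus's other cis SNPs through
#' the realized LD (z_j = r_j x z_causal + noise). SNPs outside planted
#' loci receive pure-null z-scores. The true TRS polarity of each planted
#' gene (+1 if the risk allele increases expression) is recorded in the
#' returned truth table.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth record from [generate_expression()].
#' @param genotypes [genotype_matrix()] (for allele frequencies and LD).
#' @param n_cases,n_controls GWAS case-control sample sizes.
#' @param risk_or odds ratio at each causal risk SNP.
#' @param window cis window used to define each planted locus (bp).
#' @return list with `gwas` (per-SNP summary data.frame: snp_id, chrom,
#'   pos, effect_allele, other_allele, risk_allele, beta, se, z, p, n,
#'   locus_gene, is_causal) and `truth` (per planted gene: risk allele,
#'   expression direction, true polarity).
#' @export
generate_gwas_summary <- function(config, truth, genotypes,
                                  n_cases = 5000, n_controls = 5000,
                                  risk_or = 1.3, window = 250000) {
  set.seed(config$seed + 4L)
  snps <- genotypes$snps
  dos <- genotypes$dosages
  af <- rowMeans(dos, na.rm = TRUE) / 2          # alt allele frequency
  f <- pmin(pmax(af, 0.01), 0.99)
  se <- sqrt(1 / (2 * n_cases * f * (1 - f)) + 1 / (2 * n_controls * f * (1 - f)))
  z <- rnorm(nrow(snps))                          # null background
  locus_gene <- rep(NA_character_, nrow(snps))
  is_causal <- rep(FALSE, nrow(snps))
  effect_allele <- rep(snps$alt, length.out = nrow(snps))

  plan <- truth$eqtl_plan
  truth_rows <- NULL
  if (!is.null(plan) && nrow(plan) > 0) {
    beta_cols <- grep("^beta_", names(plan), value = TRUE)
    gene_anno_all <- data.frame(gene_id = names(truth$baseline))
    for (i in seq_len(nrow(plan))) {
      ci <- match(plan$snp_id[i], snps$snp_id)
      pos_c <- snps$pos[ci]
      in_locus <- which(abs(snps$pos - pos_c) <= window)
      risk_is_alt <- runif(1) < 0.5
      z_causal <- log(risk_or) / se[ci] * (if (risk_is_alt) 1 else -1)
      g_c <- impute_dosage(dos[ci, ])
      r <- vapply(in_locus, function(j)
        suppressWarnings(cor(g_c, impute_dosage(dos[j, ]))), numeric(1))
      r[is.na(r)] <- 0
      z[in_locus] <- r * z_causal + rnorm(length(in_locus))
      z[ci] <- z_causal + rnorm(1, 0, 0.1)        # near-exact at the causal SNP
      locus_gene[in_locus] <- plan$gene_id[i]
      is_causal[ci] <- TRUE
      eqtl_beta <- mean(unlist(plan[i, beta_cols]))
      risk_allele <- if (risk_is_alt) snps$alt[ci] else snps$ref[ci]
      polarity <- if (risk_is_alt) sign(eqtl_beta) else -sign(eqtl_beta)
      truth_rows <- rbind(truth_rows, data.frame(
        snp_id = plan$snp_id[i], gene_id = plan$gene_id[i],
        risk_allele = risk_allele, eqtl_beta = eqtl_beta,
        polarity = polarity, stringsAsFactors = FALSE))
    }
  }
  beta <- z * se
  risk_allele <- ifelse(beta >= 0, snps$alt, snps$ref)
  gwas <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
                     effect_allele = snps$alt, other_allele = snps$ref,
                     risk_allele = risk_allele,
                     beta = beta, se = se, z = z,
                     p = .floor_p(2 * pnorm(-abs(z))),
                     n = n_cases + n_controls,
                     locus_gene = locus_gene, is_causal = is_causal,
                     stringsAsFactors = FALSE)
  list(gwas = gwas, truth = truth_rows)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [generate_genotypes()],
#' [generate_expression()] and [generate_gwas_summary()] and assembling a
#' sample metadata table (disease group, disease class, simulated
#' medication flags and disease-duration category for JIA samples).
#'
#' @param config a [sim_config()].
#' @param gwas logical: also generate GWAS summary statistics.
#' @param ... passed to [generate_gwas_summary()].
#' @return list: `config`, `labels`, `metadata`, `genotypes`, `expr`,
#'   `counts`, `gwas` (or NULL), `truth`.
#' @export
simulate_cohort <- function(config, gwas = TRUE, ...) {
  labels <- sim_labels(config)
  genotypes <- generate_genotypes(config)
  ex <- generate_expression(config, genotypes, labels)
  gw <- NULL
  if (gwas) {
    gw <- generate_gwas_summary(config, ex$truth, genotypes, ...)
    ex$truth$gwas <- gw$truth
  }
  set.seed(config$seed + 5L)
  is_jia <- labels %in% c("oligoJIA", "polyJIA", "sJIA")
  metadata <- data.frame(
    sample_id = names(labels),
    group = as.character(labels),
    disease_class = ifelse(labels %in% c("CD", "UC"), "IBD",
                    ifelse(is_jia, "JIA", "control")),
    med_dmards = ifelse(is_jia, rbinom(length(labels), 1, 0.4), 0L),
    med_biologics = ifelse(is_jia, rbinom(length(labels), 1, 0.3), 0L),
    med_steroids = ifelse(is_jia, rbinom(length(labels), 1, 0.3), 0L),
    duration = ifelse(is_jia,
                      sample(c("lt180d", "180-360d", "gt360d"),
                             length(labels), replace = TRUE),
                      "at_diagnosis"),
    stringsAsFactors = FALSE)
  list(config = config, labels = labels, metadata = metadata,
       genotypes = genotypes, expr = ex$expr, counts = ex$counts,
       gwas = gw$gwas, truth = ex$truth)
}

#' Simulate a risk-gene cohort for transcriptional risk scoring
#'
#' Builds standardized expression for `n_risk_genes` risk genes plus
#' unrelated background genes, with each risk gene shifted in cases along
#' its polarity so the summed polarized z-score (the TRS) differs between
#' cases and controls by `d` pooled standard deviations.
#'
#' @param n_risk_genes genes in the score (default 39, a typical
#'   IBD-risk-gene panel size).
#' @param d planted case-control TRS difference in pooled-SD units.
#' @param n_case,n_control group sizes.
#' @param n_background_genes extra unrelated genes.
#' @param seed integer seed.
#' @return list: `expr` ([expression_matrix()]), `labels` (factor
#'   case/control named by sample), `definition` (TRS definition table with
#'   known polarities), `d_true`.
#' @export
simulate_trs_cohort <- function(n_risk_genes = 39, d = 1.1,
                                n_case = 75, n_control = 12,
                                n_background_genes = 50, seed = 1L) {
  set.seed(seed)
  n <- n_case + n_control
  labels <- setNames(factor(rep(c("case", "control"), c(n_case, n_control)),
                            levels = c("control", "case")),
                     sprintf("S%03d", seq_len(n)))
  n_genes <- n_risk_genes + n_background_genes
  ids <- sprintf("G%04d", seq_len(n_genes))
  X <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(ids, names(labels)))
  polarity <- sample(c(-1, 1), n_risk_genes, replace = TRUE)
  per_gene_shift <- d / sqrt(n_risk_genes)
  for (i in seq_len(n_risk_genes))
    X[i, labels == "case"] <- X[i, labels == "case"] +
      polarity[i] * per_gene_shift
  definition <- data.frame(gene_id = ids[seq_len(n_risk_genes)],
                           polarity = polarity,
                           snp_id = NA_character_, risk_allele = NA_character_,
                           h4 = 1, stringsAsFactors = FALSE)
  list(expr = expression_matrix(X, unit = "log_normalized"),
       labels = labels, definition = definition, d_true = d)
}
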