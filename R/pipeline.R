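#' Default pipeline configuration
#'
#' Flat, stage-sectioned configuration for [run_pipeline()]. Unknown keys
#' are errors (typo protection). All randomized stages derive their seeds
#' from the single top-level `seed`, which is recorded in the manifest.
#'
#' @param overrides named list (possibly nested) of values to override, or
#'   a path to a YAML file with the same structure.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = NULL) {
  defaults <- list(
    out_dir = "pipeline_out",
    seed = 1L,
    stages = c("simulate", "preprocess", "signatures", "eqtl",
               "interaction", "coloc", "trs"),
    simulate = list(
      n_genes = 300L, n_snps = 600L, n_eqtl = 20L, eqtl_beta = 0.8,
      maf_min = 0.1, maf_max = 0.5, missing_rate = 0.02,
      noise_sd = 1, n_modules = 7L, module_size = 20L,
      gwas_n_cases = 5000L, gwas_n_controls = 5000L, gwas_risk_or = 1.3),
    preprocess = list(
      n_factors = 5L, protect = "group",
      min_individuals = 10, min_count = 6, min_fpkm = 0.1,
      hwe_p_min = 1e-3, maf_min = 0.01, missing_max = 0.05),
    signatures = list(k = 6L, n_pc = 5L),
    eqtl = list(window = 250000, p_threshold = 1e-4, n_perms = 20L),
    interaction = list(fdr = 0.10, nominal_p = 0.02),
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                 prior_sd_eqtl = 0.15, prior_sd_gwas = 0.2),
    trs = list(h4_min = 0.5, reference = "control"))
  if (is.character(overrides) && length(overrides) == 1)
    overrides <- yaml::read_yaml(overrides)
  cfg <- defaults
  if (!is.null(overrides)) {
    check_keys <- function(ov, def, path = "") {
      bad <- setdiff(names(ov), names(def))
      if (length(bad))
        stop("unknown config key(s): ",
             paste0(path, bad, collapse = ", "))
      for (k in names(ov))
        if (is.list(ov[[k]]) && is.list(def[[k]]))
          check_keys(ov[[k]], def[[k]], paste0(path, k, "."))
    }
    check_keys(overrides, defaults)
    cfg <- modifyList(defaults, overrides)
  }
  known_stages <- defaults$stages
  if (!all(cfg$stages %in% known_stages))
    stop("unknown stage(s): ",
         paste(setdiff(cfg$stages, known_stages), collapse = ", "))
  # dependency check before anything runs
  deps <- list(preprocess = "simulate", signatures = "preprocess",
               eqtl = "preprocess", interaction = "eqtl",
               coloc = "eqtl", trs = "coloc")
  for (s in cfg$stages) {
    need <- deps[[s]]
    if (!is.null(need) && !all(need %in% cfg$stages))
      stop("stage '", s, "' requires stage(s): ",
           paste(setdiff(need, cfg$stages), collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.character(h), basename(paths))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate -> preprocess -> signatures | eqtl -> interaction -> coloc ->
#' trs), writing each stage's outputs under `out_dir` and recording a
#' manifest (parameters, seed, per-stage row counts, md5 hashes of every
#' output file). Stage outputs are pure functions of the config and seed:
#' rerunning with the same config yields byte-identical files.
#'
#' @param config a [pipeline_config()] (or overrides list / YAML path
#'   passed through it).
#' @return the manifest (invisibly); also written as
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!is(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "diseqtl",
                   version = as.character(utils::packageVersion("diseqtl")),
                   seed = config$seed,
                   parameters = unclass(config), stages = list())
  state <- new.env(parent = emptyenv())
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    message("[", name, "] running ...")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      finish()
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    res$status <- "ok"
    res$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 2)
    manifest$stages[[name]] <<- res
  }

  run_stage("simulate", function() {
    sc <- config$simulate
    groups <- c(control = 12, oligoJIA = 43, polyJIA = 46, sJIA = 26,
                CD = 60, UC = 15)
    base_cfg <- sim_config(n_samples_per_group = groups,
                           n_genes = sc$n_genes, n_snps = sc$n_snps,
                           maf_range = c(sc$maf_min, sc$maf_max),
                           n_modules = sc$n_modules,
                           module_size = sc$module_size,
                           noise_sd = sc$noise_sd,
                           missing_rate = sc$missing_rate,
                           seed = config$seed)
    plan <- auto_eqtl_plan(base_cfg, sc$n_eqtl,
                           sc$eqtl_beta * rep_len(c(1, -1), sc$n_eqtl))
    shift_plan <- data.frame(
      module = c("M01", "M01", "M01", "M02", "M02", "M02"),
      group = c("sJIA", "CD", "UC", "sJIA", "CD", "UC"),
      shift = c(1, 1, 1.2, -0.6, -0.8, -0.8))
    cfg <- sim_config(n_samples_per_group = groups,
                      n_genes = sc$n_genes, n_snps = sc$n_snps,
                      maf_range = c(sc$maf_min, sc$maf_max),
                      n_modules = sc$n_modules, module_size = sc$module_size,
                      noise_sd = sc$noise_sd, missing_rate = sc$missing_rate,
                      eqtl_plan = plan, group_shift_plan = shift_plan,
                      seed = config$seed)
    sim <- simulate_cohort(cfg, n_cases = sc$gwas_n_cases,
                           n_controls = sc$gwas_n_controls,
                           risk_or = sc$gwas_risk_or)
    state$sim <- sim
    d <- file.path(out_dir, "simulate")
    dir.create(d, showWarnings = FALSE)
    write_counts_tsv(sim$counts, file.path(d, "counts.tsv"))
    write_gene_bed(gene_anno(sim$counts), file.path(d, "genes.bed"))
    write_dosage_tsv(sim$genotypes, file.path(d, "dosages.tsv"))
    write_vcf(sim$genotypes, file.path(d, "genotypes.vcf"))
    write_gmt(sim$truth$module_genes, file.path(d, "modules.gmt"))
    write_gwas_tsv(sim$gwas, file.path(d, "gwas.tsv"))
    write.table(sim$metadata, file.path(d, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(eqtl_plan = sim$truth$eqtl_plan,
           gwas_truth = sim$truth$gwas,
           group_shift_plan = sim$truth$group_shift_plan,
           module_genes = sim$truth$module_genes),
      file.path(d, "truth.json"), auto_unbox = TRUE, digits = NA)
    list(n_samples = length(sim$labels), n_genes = nrow(sim$counts$values),
         n_snps = nrow(sim$genotypes$dosages),
         outputs = .hash_files(list.files(d, full.names = TRUE)))
  })

  run_stage("preprocess", function() {
    pc <- config$preprocess
    sim <- state$sim
    geno_qc <- qc_genotypes(sim$genotypes,
                            qc_thresholds(pc$hwe_p_min, pc$maf_min,
                                          pc$missing_max))
    filtered <- filter_expressed_genes(sim$counts, pc$min_individuals,
                                       pc$min_count, pc$min_fpkm)
    norm <- normalize_expression(filtered)
    protected <- sim$metadata[, pc$protect, drop = FALSE]
    adj <- adjust_latent_factors(norm, protected, n_factors = pc$n_factors)
    state$geno <- geno_qc; state$expr <- adj
    d <- file.path(out_dir, "preprocess")
    dir.create(d, showWarnings = FALSE)
    write.table(data.frame(gene_id = rownames(adj$values), adj$values,
                           check.names = FALSE),
                file.path(d, "expression_adjusted.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    qc_rep <- attr(geno_qc, "qc_report")
    jsonlite::write_json(list(genotype_qc = qc_rep[c("n_input", "n_kept",
                                                     "dropped")],
                              genes_kept = nrow(adj$values),
                              genes_input = nrow(sim$counts$values)),
                         file.path(d, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    list(n_genes_kept = nrow(adj$values),
         n_snps_kept = nrow(geno_qc$dosages),
         outputs = .hash_files(list.files(d, full.names = TRUE)))
  })

  run_stage("signatures", function() {
    sg <- config$signatures
    sim <- state$sim; expr <- state$expr
    scores <- btm_scores(expr, sim$truth$module_genes, groups = sim$labels)
    cl <- cluster_samples(zscore_expression(expr), k = sg$k,
                          groups = sim$labels)
    pv <- pvca(expr, data.frame(disease_class = sim$metadata$disease_class,
                                group = sim$metadata$group),
               n_pc = sg$n_pc)
    state$scores <- scores
    d <- file.path(out_dir, "signatures")
    dir.create(d, showWarnings = FALSE)
    write.table(scores, file.path(d, "module_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(cl$membership),
                file.path(d, "cluster_membership.tsv"), sep = "\t",
                quote = FALSE)
    write.table(pv, file.path(d, "pvca.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    an <- group_anova(scores, sim$labels)
    write.table(an, file.path(d, "module_anova.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(n_modules_scored = ncol(scores) - 1L,
         outputs = .hash_files(list.files(d, full.names = TRUE)))
  })

  run_stage("eqtl", function() {
    ec <- config$eqtl
    sim <- state$sim
    pairs <- build_cis_pairs(state$expr, state$geno, window = ec$window)
    cohorts <- list(
      JIA = sim$metadata$sample_id[sim$metadata$disease_class == "JIA"],
      IBD = sim$metadata$sample_id[sim$metadata$disease_class == "IBD"])
    d <- file.path(out_dir, "eqtl")
    dir.create(d, showWarnings = FALSE)
    callsets <- list()
    for (co in names(cohorts)) {
      cs <- call_eqtls(pairs,
                       subset_genotypes(state$geno, samples = cohorts[[co]]),
                       subset_expression(state$expr, samples = cohorts[[co]]),
                       p_threshold = ec$p_threshold, n_perms = ec$n_perms,
                       cohort = co, seed = config$seed + match(co, names(cohorts)))
      callsets[[co]] <- cs
      write.table(cs$peaks, file.path(d, paste0("eqtl_", co, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(cohort = co, n_egenes = nrow(cs$calls),
                                p_threshold = cs$p_threshold,
                                n_perms = cs$n_perms, empirical_fdr = cs$fdr),
                           file.path(d, paste0("fdr_", co, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    state$pairs <- pairs; state$callsets <- callsets
    list(n_cis_pairs = nrow(pairs),
         n_egenes = vapply(callsets, function(cs) nrow(cs$calls), 0),
         empirical_fdr = vapply(callsets, function(cs)
           cs$fdr %||% NA_real_, 0),
         outputs = .hash_files(list.files(d, full.names = TRUE)))
  })

  run_stage("interaction", function() {
    ic <- config$interaction
    sim <- state$sim
    pooled <- pool_cohorts(state$callsets$JIA, state$callsets$IBD,
                           tag_a = "JIA", tag_b = "IBD")
    disease <- setNames(factor(sim$metadata$disease_class,
                               levels = c("JIA", "IBD")),
                        sim$metadata$sample_id)
    disease <- disease[!is.na(disease)]
    recs <- test_interactions(pooled, state$geno, state$expr, disease)
    called <- call_interactions(recs, fdr = ic$fdr,
                                nominal_p = ic$nominal_p)
    state$interactions <- called
    d <- file.path(out_dir, "interaction")
    dir.create(d, showWarnings = FALSE)
    write.table(called$records, file.path(d, "interactions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_candidates = nrow(pooled),
         n_significant = called$n_significant,
         n_nominal = called$n_nominal,
         outputs = .hash_files(list.files(d, full.names = TRUE)))
  })

  run_stage("coloc", function() {
    cc <- config$coloc
    sim <- state$sim
    genes <- unique(c(state$callsets$JIA$calls$gene_id,
                      state$callsets$IBD$calls$gene_id))
    anno <- gene_anno(state$expr)
    rows <- lapply(genes, function(g) {
      co <- if (g %in% state$callsets$JIA$calls$gene_id) "JIA" else "IBD"
      samples <- sim$metadata$sample_id[sim$metadata$disease_class == co]
      es <- tryCatch(eqtl_summary_series(
        g, state$pairs,
        subset_genotypes(state$geno, samples = samples),
        subset_expression(state$expr, samples = samples)),
        error = function(e) NULL)
      if (is.null(es) || nrow(es) < 2) return(NULL)
      gi <- anno[anno$gene_id == g, ]
      gw <- sim$gwas[sim$gwas$pos >= gi$start - config$eqtl$window &
                     sim$gwas$pos <= gi$stop + config$eqtl$window &
                     sim$gwas$chrom == gi$chrom, , drop = FALSE]
      res <- tryCatch(colocalize(es, gw, p1 = cc$p1, p2 = cc$p2,
                                 p12 = cc$p12,
                                 prior_sd_1 = cc$prior_sd_eqtl,
                                 prior_sd_2 = cc$prior_sd_gwas),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(gene_id = g, cohort = co, n_snps = res$n_snps,
                 t(res$pp), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) tab <- data.frame()
    state$coloc <- tab
    d <- file.path(out_dir, "coloc")
    dir.create(d, showWarnings = FALSE)
    write.table(tab, file.path(d, "coloc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(n_loci = nrow(tab),
         n_h4 = if (nrow(tab)) sum(tab$PP4 >= config$trs$h4_min) else 0L,
         outputs = .hash_files(list.files(d, full.names = TRUE)))
  })

  run_stage("trs", function() {
    tc <- config$trs
    sim <- state$sim
    snps <- snp_anno(state$geno)
    eqtl_rec <- rbind(state$callsets$JIA$calls, state$callsets$IBD$calls)
    eqtl_rec <- merge(eqtl_rec,
                      snps[, c("snp_id", "ref", "alt")], by = "snp_id")
    names(eqtl_rec)[names(eqtl_rec) == "alt"] <- "effect_allele"
    names(eqtl_rec)[names(eqtl_rec) == "ref"] <- "other_allele"
    coloc_res <- state$coloc
    if (nrow(coloc_res)) names(coloc_res)[names(coloc_res) == "PP4"] <- "pp_h4"
    def <- build_trs_definition(sim$gwas, eqtl_rec,
                                coloc_results = coloc_res,
                                h4_min = tc$h4_min)
    scores <- compute_trs(state$expr, def)
    grp <- factor(sim$metadata$disease_class,
                  levels = c("control", "JIA", "IBD"))
    contrast <- trs_group_contrast(scores, grp, reference = tc$reference)
    d <- file.path(out_dir, "trs")
    dir.create(d, showWarnings = FALSE)
    write.table(def, file.path(d, "trs_definition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cbind(scores, group = as.character(grp)),
                file.path(d, "trs_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(reference = contrast$reference,
                              contrasts = contrast$contrasts,
                              anova_p = contrast$anova_p),
                         file.path(d, "trs_contrast.json"),
                         auto_unbox = TRUE, digits = NA)
    list(n_trs_genes = nrow(def),
         outputs = .hash_files(list.files(d, full.names = TRUE)))
  })

  finish()
  invisible(manifest)
}
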