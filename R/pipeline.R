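write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full two-stage TWAS pipeline on simulated data
#'
#' Desk-scale end-to-end driver: simulate panels/expression/phenotypes, write
#' them as plain-text fixtures, read them back through the package's own
#' readers, apply the TWAS (set1) and GWAS (set2) QC profiles, residualize
#' expression on batch/production factors, train cis-eQTL weights, impute
#' GReX into the test panel, compute IBS/MDS stratification covariates from
#' the GWAS variant set, run both association scans, and write comparison
#' tables. Every step is seeded from the config, so two runs with the same
#' config produce byte-identical output files.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created); fixtures under `data/`,
#'   result TSVs under `results/`
#' @param model "dpr" or "enet" weight model
#' @param cv_mode "nocv" or "cv5" training-accuracy regime
#' @param alpha family-wise level for thresholds (default 0.05)
#' @return invisible list: `paths` (named output files), `gwas`, `twas`,
#'   `weights`, `genes`, `grex`, `inflation`
#' @export
run_twas_pipeline <- function(config, out_dir, model = c("dpr", "enet"),
                              cv_mode = c("nocv", "cv5"), alpha = 0.05) {
  model <- match.arg(model)
  cv_mode <- match.arg(cv_mode)
  data_dir <- file.path(out_dir, "data")
  res_dir <- file.path(out_dir, "results")
  for (d in c(data_dir, res_dir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }

  sim <- simulate_panel(config)
  se <- simulate_expression(sim, config)
  pheno_sim <- simulate_phenotypes(se$truth, sim$test, config)
  paths <- write_fixtures(sim, sim$annotation, se$expression, pheno_sim,
                          data_dir)
  paths["factors"] <- write_tsv(se$factors, file.path(data_dir, "factors.tsv"))

  ref <- read_genotypes(paths[["ref_vcf"]])
  test <- read_genotypes(paths[["test_vcf"]], recode_minor = FALSE)
  test <- match_minor_coding(test, ref)
  annotation <- read_gene_annotation(paths[["annotation"]])
  expr <- read_expression_matrix(paths[["expression"]])
  pheno <- read_phenotypes(paths[["phenotypes"]])
  factors <- read_phenotypes(paths[["factors"]])

  qc_ref <- apply_qc_profile(ref, qc_profile("set1"))
  qc_test <- apply_qc_profile(test, qc_profile("set2"))

  expr_res <- residualize(expr, factors)
  trained <- train_weights(qc_ref$panel, expr_res, annotation,
                           model = model, cv_mode = cv_mode,
                           seed = config$seed)
  grex <- impute_grex(trained$weights, test)
  mds <- compute_ibs_mds(qc_test$panel, k = 2)

  gwas <- gwas_scan(qc_test$panel, pheno, mds, trait = "trait", alpha = alpha)
  twas <- twas_scan(grex, pheno, mds, annotation, trait = "trait",
                    alpha = alpha)

  gwas_line <- bonferroni_threshold(alpha, nrow(gwas))
  twas_line <- bonferroni_threshold(alpha, nrow(twas))
  inflation <- list(
    gwas = genomic_inflation(gwas$p_value),
    twas = if (nrow(twas) >= 10) genomic_inflation(twas$p_value)
  )

  out <- list(
    qc_ref_report = qc_ref$report, qc_test_report = qc_test$report,
    weights = trained$weights, gene_diagnostics = trained$genes,
    grex = data.frame(gene_id = rownames(grex), grex, check.names = FALSE),
    gwas_results = gwas, twas_results = twas,
    gwas_manhattan = manhattan_table(gwas, gwas_line),
    twas_manhattan = manhattan_table(twas, twas_line),
    gwas_top_hits = top_hits(gwas, 10, annotation),
    twas_top_hits = top_hits(twas, 10, annotation),
    gwas_qq = inflation$gwas$qq
  )
  for (nm in names(out)) {
    paths[nm] <- write_tsv(out[[nm]], file.path(res_dir, paste0(nm, ".tsv")))
  }
  invisible(list(paths = paths, gwas = gwas, twas = twas,
                 weights = trained$weights, genes = trained$genes,
                 grex = grex, inflation = inflation))
}
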