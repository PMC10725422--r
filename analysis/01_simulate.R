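#!/usr/bin/env Rscript
# Stage 0: generate the study-scale synthetic dataset.
#
# Emulates the study design the pipeline targets: 8 reference animals with
# both ddRAD-style genotypes and mammary-transcriptome expression, 136
# genotyped test animals with a quantitative lactation trait, 40 genes with
# ~1 Mb cis windows of 20 SNPs each, expression heritability 0.12 (the low
# bulk-tissue range), and batch-shifted expression. Writes plain-text
# fixtures (VCF / TSV) under results/data/.

library(grextwas)

out_dir <- "results/data"
cfg <- sim_config(n_ref = 8, n_test = 136, n_genes = 40, snps_per_gene = 20,
                  he2 = 0.12, pi_causal = 0.2, missing_rate = 0.02,
                  beta_trait = 0.5, seed = 42)

sim <- simulate_panel(cfg)
se <- simulate_expression(sim, cfg)
pheno <- simulate_phenotypes(se$truth, sim$test, cfg)

paths <- write_fixtures(sim, sim$annotation, se$expression, pheno, out_dir)
write.table(se$factors, file.path(out_dir, "factors.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- do.call(rbind, lapply(se$truth, function(t) {
  data.frame(gene_id = t$gene_id, variant_id = t$variant_id,
             true_weight = t$true_weights, causal = t$causal_flag)
}))
write.table(truth, file.path(out_dir, "true_weights.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d reference / %d test samples, %d genes, %d variants",
                cfg$n_ref, cfg$n_test, cfg$n_genes, nrow(sim$ref$variants)))
message(sprintf("mean missing dosage fraction: %.3f", mean(is.na(sim$ref$dosage))))
message("fixtures written under ", out_dir)
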