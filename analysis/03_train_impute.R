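#!/usr/bin/env Rscript
# Stage 2: train per-gene cis-eQTL weights on the 8-sample reference panel
# with all four regimes (DPR / elastic net, with and without fivefold CV
# accuracy estimation), compare how many genes each model can impute, and
# impute GReX into the 136 test animals with the DPR-without-CV weights.

library(grextwas)

data_dir <- "results/data"
out_dir <- "results/grex"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ref <- read_genotypes(file.path(data_dir, "ref_panel.vcf"))
test <- match_minor_coding(
  read_genotypes(file.path(data_dir, "test_panel.vcf"), recode_minor = FALSE),
  ref)
annotation <- read_gene_annotation(file.path(data_dir, "gene_annotation.tsv"))
expr <- residualize(
  read_expression_matrix(file.path(data_dir, "expression.tsv")),
  read_phenotypes(file.path(data_dir, "factors.tsv")))
ref_qc <- apply_qc_profile(ref, qc_profile("set1"))$panel

summaries <- list()
for (model in c("dpr", "enet")) {
  for (cv in c("nocv", "cv5")) {
    tr <- train_weights(ref_qc, expr, annotation, model = model,
                        cv_mode = cv, seed = 42)
    tag <- paste(model, cv, sep = "_")
    write.table(tr$weights, file.path(out_dir, paste0("weights_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summaries[[tag]] <- data.frame(
      model = toupper(model), cv_mode = cv,
      genes_trained = nrow(tr$genes),
      genes_imputable = sum(tr$genes$usable),
      mean_training_r2 = mean(tr$genes$training_r2, na.rm = TRUE)
    )
  }
}
summary_tab <- do.call(rbind, summaries)
write.table(summary_tab, file.path(out_dir, "training_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("training summary (per model x CV regime):")
print(summary_tab, row.names = FALSE)

dpr_nocv <- read.delim(file.path(out_dir, "weights_dpr_nocv.tsv"))
grex <- impute_grex(dpr_nocv, test)
write.table(data.frame(gene_id = rownames(grex), grex, check.names = FALSE),
            file.path(out_dir, "grex_dpr_nocv.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("imputed GReX for %d genes x %d test samples (DPR, no CV)",
                nrow(grex), ncol(grex)))
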