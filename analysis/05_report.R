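#!/usr/bin/env Rscript
# Stage 4: comparison products. Manhattan tables for plotting, top-10 hits
# with +-20 kb gene neighborhoods and BH-adjusted p-values, the +-1.5 Mb
# windows around the best TWAS genes, GWAS/TWAS overlap counts, and the
# extreme-weight cis-SNPs of the top TWAS genes.

library(grextwas)

data_dir <- "results/data"
out_dir <- "results/report"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

annotation <- read_gene_annotation(file.path(data_dir, "gene_annotation.tsv"))
gwas <- read.delim("results/assoc/gwas_results.tsv",
                   colClasses = c(chrom = "character"))
twas <- read.delim("results/assoc/twas_results.tsv",
                   colClasses = c(chrom = "character"))
weights <- read.delim("results/grex/weights_dpr_nocv.tsv",
                      colClasses = c(chrom = "character"))

write.table(manhattan_table(gwas, bonferroni_threshold(0.05, nrow(gwas))),
            file.path(out_dir, "gwas_manhattan.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(manhattan_table(twas, bonferroni_threshold(0.05, nrow(twas))),
            file.path(out_dir, "twas_manhattan.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

gwas_top <- top_hits(gwas, 10, annotation, flank = 20000)
twas_top <- top_hits(twas, 10, annotation, flank = 20000)
write.table(gwas_top, file.path(out_dir, "gwas_top10.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(twas_top, file.path(out_dir, "twas_top10.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("top GWAS hit: ", gwas_top$unit_id[1], " (p = ",
        signif(gwas_top$p_value[1], 3), "; near: ",
        gwas_top$neighbor_genes[1], ")")
message("top TWAS gene: ", twas_top$unit_id[1], " (p = ",
        signif(twas_top$p_value[1], 3), ")")

# +-1.5 Mb neighborhoods of the three best TWAS genes
windows <- lapply(twas_top$unit_id[1:3], function(g) {
  data.frame(hit_gene = g,
             window_gene = twas_hit_window_genes(g, annotation))
})
write.table(do.call(rbind, windows),
            file.path(out_dir, "twas_hit_windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# method overlap between the GWAS top-10 neighborhoods and TWAS top-10 genes
gwas_genes <- unique(unlist(strsplit(gwas_top$neighbor_genes, ",")))
gwas_genes <- gwas_genes[gwas_genes != ""]
venn <- shared_gene_counts(list(GWAS = gwas_genes, TWAS = twas_top$unit_id))
write.table(venn, file.path(out_dir, "method_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("method overlap (exclusive regions):")
print(venn, row.names = FALSE)

# candidate tag SNPs: extreme weights of each top TWAS gene
tags <- do.call(rbind, lapply(twas_top$unit_id[1:3], function(g) {
  tw <- top_weight_snps(weights[weights$gene_id == g, ])
  if (nrow(tw) > 0) cbind(gene_id = g, tw)
}))
write.table(tags, file.path(out_dir, "top_weight_snps.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("extreme-weight cis-SNPs written for the top 3 TWAS genes")
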