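#!/usr/bin/env Rscript
# Stage 1: read the genotype fixtures and apply the two QC profiles —
# set1 (TWAS variant set: call rate > 95%, HWE exact p >= 1e-4, MAF >= 0.01)
# and set2 (GWAS variant set: set1 thresholds plus MAF >= 0.05 and LD
# pruning at r^2 < 0.8). Writes the filtered-variant reports.

library(grextwas)

data_dir <- "results/data"
out_dir <- "results/qc"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ref <- read_genotypes(file.path(data_dir, "ref_panel.vcf"))
test <- match_minor_coding(
  read_genotypes(file.path(data_dir, "test_panel.vcf"), recode_minor = FALSE),
  ref)

qc_ref <- apply_qc_profile(ref, qc_profile("set1"))
qc_test_gwas <- apply_qc_profile(test, qc_profile("set2"))

write.table(qc_ref$report, file.path(out_dir, "set1_ref_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(qc_test_gwas$report, file.path(out_dir, "set2_test_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(qc_test_gwas$panel$variants$variant_id,
           file.path(out_dir, "set2_variants.txt"))

message(sprintf("reference panel: %d -> %d variants under set1",
                nrow(ref$variants), nrow(qc_ref$panel$variants)))
message(sprintf("test panel: %d -> %d variants under set2 (GWAS set)",
                nrow(test$variants), nrow(qc_test_gwas$panel$variants)))
print(qc_test_gwas$report, row.names = FALSE)
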