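#!/usr/bin/env Rscript
# Step 4: overlap partitioning and over-representation summaries.
#
# Partitions the per-genotype basal gene sets (the numbers behind a
# supervenn figure) and tests the shared module for over-representation of
# the planted gene classes with the hypergeometric test. With real data the
# annotation sets would come from a GMT file (read_gmt) instead of the
# simulation truth.

library(trapdiff)

cls <- utils::read.delim(file.path("results", "classification.tsv"),
                         stringsAsFactors = FALSE)
truth <- utils::read.delim(file.path("results", "data", "truth.tsv"),
                           stringsAsFactors = FALSE)

basal_sets <- lapply(split(cls, cls$genotype), function(sub)
  sub$gene_id[!is.na(sub$basal) & sub$basal != "none"])
part <- overlap_partition(basal_sets)
utils::write.table(part, file.path("results", "basal_overlap.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("basal-set overlap partition across genotypes:")
print(part, row.names = FALSE)

anno <- split(truth$gene_id, truth$class)
shared <- unique(cls$gene_id[cls$shared_module])
enr <- hypergeom_enrichment(shared, anno, truth$gene_id)
utils::write.table(enr, file.path("results", "shared_module_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("shared-module enrichment over planted classes (top rows):")
print(head(enr), row.names = FALSE)
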