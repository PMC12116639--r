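#!/usr/bin/env Rscript
# Stage 3 — normalize (size factors, RPM, FPKM), test two-group
# differential expression for isomiRs and genes, and apply the selection
# filters: FDR < 0.05 (plus > 2-fold for genes), mean RPM > 100 with the
# cumulative-95% rule for isomiRs, and the top-expressed gene universe.

library(isoshift)

scen <- "results/scenario"
samples <- read_tsv_table(file.path(scen, "samples.tsv"))
groups <- setNames(samples$group, samples$sample)
th <- filter_thresholds(top_genes = 3009L)  # all simulated genes qualify

iso_counts <- read_count_matrix("results/isomir_counts.tsv")
iso_de <- classify_de(nb_wald_de(iso_counts, groups[colnames(iso_counts)]),
                      th, apply_fold = th$fold_applies_to_isomirs)
write_tsv_table(iso_de, "results/isomir_de.tsv")
abundant <- select_abundant(to_rpm(iso_counts), th)
writeLines(abundant, "results/abundant_isomirs.txt")

gene_counts <- read_count_matrix(file.path(scen, "gene_counts.tsv"))
len <- read_tsv_table(file.path(scen, "gene_lengths.tsv"))
sf <- size_factors(gene_counts)
fpkm <- to_fpkm(sweep(gene_counts, 2, sf, "/"), setNames(len[[2]], len[[1]]))
universe <- select_top_expressed(fpkm, min(th$top_genes, nrow(fpkm)))
gene_de <- classify_de(nb_wald_de(gene_counts, groups[colnames(gene_counts)],
                                  sf = sf), th, apply_fold = TRUE)
write_tsv_table(gene_de, "results/gene_de.tsv")
writeLines(universe, "results/gene_universe.txt")

de_ab <- intersect(abundant, iso_de$feature[iso_de$direction != "ns"])
cat(sprintf("isomiRs: %d abundant of %d; DE: %d up, %d down; DE & abundant: %d\n",
            length(abundant), nrow(iso_counts),
            sum(iso_de$direction == "up"), sum(iso_de$direction == "down"),
            length(de_ab)))
cat(sprintf("genes: universe %d; DE (FDR<%.2f & >%g-fold): %d up, %d down\n",
            length(universe), th$de_fdr, th$min_fold,
            sum(gene_de$direction == "up"), sum(gene_de$direction == "down")))
truth <- jsonlite::read_json(file.path(scen, "truth.json"))
cat("Planted isomiRs among DE & abundant:",
    sum(names(truth$true_isomir_fc) %in% de_ab), "of",
    length(truth$true_isomir_fc), "\n")
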