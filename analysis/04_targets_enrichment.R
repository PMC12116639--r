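#!/usr/bin/env Rscript
# Stage 4 — assemble target sets (validated for canonical isomiRs;
# seed-filtered predicted for 5'-isoforms), then test overrepresentation of
# each DE isomiR's targets among the oppositely regulated genes (Fisher
# odds ratio), compare target vs non-target fold-change distributions (KS
# distance) with the direction-consistency rule, and run gene-set
# overrepresentation on the downregulated targets of upregulated isomiRs.

library(isoshift)

scen <- "results/scenario"
th <- filter_thresholds(top_genes = 3009L)
iso_de <- read_tsv_table("results/isomir_de.tsv")
gene_de <- read_tsv_table("results/gene_de.tsv")
universe <- readLines("results/gene_universe.txt")
abundant <- readLines("results/abundant_isomirs.txt")
de_ab <- intersect(abundant, iso_de$feature[iso_de$direction != "ns"])

ref <- read_reference(file.path(scen, "hairpins.fasta"),
                      file.path(scen, "matures.tsv"))
iso_all <- isoform_table(ref, 3L)
isomirs <- iso_all[iso_all$label %in% de_ab, ]
ts <- build_target_sets(read_tsv_table(file.path(scen, "validated_targets.tsv")),
                        read_tsv_table(file.path(scen, "predicted_targets.tsv")),
                        read_fasta(file.path(scen, "utrs.fasta")),
                        isomirs, universe)
write_tsv_table(target_sets_table(ts), "results/target_sets.tsv")

or_tab <- or_enrichment_table(ts, iso_de, gene_de, universe)
gene_lfc <- setNames(gene_de$log2FC, gene_de$feature)[universe]
ks_tab <- ks_enrichment_table(ts, iso_de, gene_lfc)
write_tsv_table(or_tab, "results/or_enrichment.tsv")
write_tsv_table(ks_tab, "results/ks_enrichment.tsv")

cat("Odds-ratio enrichment (targets among oppositely regulated genes):\n")
print(or_tab[, c("isomir", "td", "tn", "nd", "nn", "odds_ratio", "q")],
      digits = 3)
cat("KS enrichment and direction consistency:\n")
print(ks_tab, digits = 3)

selected <- ks_tab$isomir[ks_tab$q < th$de_fdr & ks_tab$consistent]
writeLines(selected, "results/selected_isomirs.txt")
cat("Selected isomiRs (KS FDR <", th$de_fdr, "and consistent):",
    paste(selected, collapse = ", "), "\n")

up_sel <- intersect(selected, iso_de$feature[iso_de$direction == "up"])
down_targets <- intersect(
  unique(unlist(lapply(ts[up_sel], `[[`, "genes"))),
  gene_de$feature[gene_de$direction == "down"])
gs <- geneset_enrichment(down_targets,
                         read_gmt(file.path(scen, "gene_sets.gmt")),
                         universe, th$de_fdr)
write_tsv_table(gs, "results/geneset_enrichment.tsv")
cat(sprintf("Gene sets enriched in %d downregulated targets: %d of %d\n",
            length(down_targets), sum(gs$enriched), nrow(gs)))
print(head(gs, 3), digits = 3)
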