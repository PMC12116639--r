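#!/usr/bin/env Rscript
# Stage 5 — triangulate candidate transcription-factor regulators: TFs
# whose regulon is overrepresented in the top up/down genes, that are
# themselves differentially expressed, and that have recorded edges to the
# DE miRNA genes (5'-isoforms mapped to their parent gene).

library(isoshift)

scen <- "results/scenario"
th <- filter_thresholds(top_genes = 3009L)
iso_de <- read_tsv_table("results/isomir_de.tsv")
gene_de <- read_tsv_table("results/gene_de.tsv")
universe <- readLines("results/gene_universe.txt")
abundant <- readLines("results/abundant_isomirs.txt")
de_ab <- intersect(abundant, iso_de$feature[iso_de$direction != "ns"])

funnel <- tf_funnel(file.path(scen, "tf_gene_edges.tsv"),
                    file.path(scen, "tf_mirna_edges.tsv"),
                    gene_de, de_ab,
                    file.path(scen, "mature_to_gene.tsv"),
                    universe, th)

cat(sprintf("TF funnel: %d regulon-enriched -> %d DE -> %d with miRNA edges\n",
            nrow(funnel$candidates), nrow(funnel$de_tfs),
            nrow(funnel$result$matrix)))
mat <- funnel$result$matrix
write_tsv_table(data.frame(tf = rownames(mat), (mat + 0),
                           check.names = FALSE),
                "results/tf_mirna_matrix.tsv")
cat("Regulator matrix (TF x miRNA gene):\n")
print(mat + 0)

truth <- jsonlite::read_json(file.path(scen, "truth.json"))
cat("Planted regulators recovered:",
    paste(intersect(names(truth$true_tf_regulators), rownames(mat)),
          collapse = ", "), "\n")
cat("Decoy TFs admitted:",
    length(setdiff(rownames(mat), names(truth$true_tf_regulators))), "\n")
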