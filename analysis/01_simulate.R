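#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study: two groups (7 control vs 8
# knockdown-like samples), small-RNA FASTQs with a 3' adapter, an mRNA
# count matrix, 3'UTRs with planted seed sites, target/edge tables and the
# machine-readable truth. Everything downstream reads only these files.

library(isoshift)

seed <- 20260923L
out <- "results/scenario"

cfg <- sim_config(rng_seed = seed)   # defaults: 20 miRNAs x 3 isoforms,
                                     # 3000 genes, depth 1e5, alpha 0.1
sc <- simulate_scenario(cfg, out)

cat("Scenario written to", out, "\n")
cat(sprintf("  %d miRNAs x %d isoforms, %d genes (+%d TF genes), %d+%d samples\n",
            cfg$n_mirnas, cfg$n_isoforms_per_mirna, cfg$n_genes,
            length(sc$truth$tf_gene_ids), cfg$n_samples_per_group[1],
            cfg$n_samples_per_group[2]))
cat("Planted isomiR effects (log2 FC):\n")
print(sc$truth$true_isomir_fc)
cat(sprintf("Planted targets per active isomiR: %s\n",
            paste(lengths(sc$truth$true_targets), collapse = ", ")))
cat(sprintf("Planted TF regulators: %s\n",
            paste(names(sc$truth$true_tf_regulators), collapse = ", ")))
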