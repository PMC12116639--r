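# End-to-end orchestration: quant -> normalize -> DE -> select -> targets ->
# enrichment -> TF triangulation, from one config list, with a
# machine-readable run report. Every stage is a pure function of its inputs;
# stage outputs are written as headered TSVs under the output directory.

#' Build a run configuration
#'
#' @param paths named list of input paths: fastq (named vector, sample ->
#'   FASTQ), hairpin_fasta, mature_tsv, gene_counts_tsv, gene_lengths_tsv,
#'   samples_tsv, utr_fasta, validated_tsv, predicted_tsv, gmt,
#'   tf_gene_tsv, tf_mirna_tsv, mature_map_tsv.
#' @param out_dir output directory.
#' @param thresholds a `filter_thresholds`.
#' @param adapter 3' adapter sequence.
#' @param window5,window3 isomiR lookup windows.
#' @param site_type seed-site type for the predicted-target filter.
#' @param min_hits TF regulon hit threshold.
#' @return validated `run_config` list.
#' @export
run_config <- function(paths, out_dir,
                       thresholds = filter_thresholds(),
                       adapter = "AGATCGGAAGAGCACACGTCT",
                       window5 = 3L, window3 = 5L,
                       site_type = "6mer", min_hits = 3L) {
  required <- c("hairpin_fasta", "mature_tsv", "gene_counts_tsv",
                "gene_lengths_tsv", "samples_tsv", "utr_fasta",
                "validated_tsv", "predicted_tsv", "gmt", "tf_gene_tsv",
                "tf_mirna_tsv", "mature_map_tsv", "fastq")
  missing <- setdiff(required, names(paths))
  if (length(missing))
    stop("run_config: missing input paths: ", paste(missing, collapse = ", "))
  files <- c(unlist(paths$fastq), unlist(paths[setdiff(required, "fastq")]))
  absent <- files[!file.exists(files)]
  if (length(absent))
    stop("run_config: input file does not exist: ", absent[1])
  cfg <- list(paths = paths, out_dir = out_dir, thresholds = thresholds,
              adapter = adapter, window5 = as.integer(window5),
              window3 = as.integer(window3), site_type = site_type,
              min_hits = as.integer(min_hits))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#' @param path YAML path with fields paths, out_dir, and optional
#'   thresholds/adapter/windows/site_type/min_hits.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- do.call(filter_thresholds, as.list(y$thresholds))
  args <- list(paths = y$paths, out_dir = y$out_dir, thresholds = th)
  for (f in c("adapter", "window5", "window3", "site_type", "min_hits"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(run_config, args)
}

isomirs_from_labels <- function(reference, labels) {
  parsed <- parse_isomir_label(labels)
  m <- reference$matures[match(parsed$mature, reference$matures$mature), ]
  if (any(is.na(m$mature)))
    stop("isomiR label not in reference: ",
         labels[which(is.na(m$mature))[1]])
  seqs <- vapply(seq_along(labels), function(i) {
    hp <- reference$hairpins[[m$hairpin[i]]]
    a <- m$start[i] + parsed$shift5[i]
    if (a < 1L || a > m$end[i])
      stop("isoform shift outside hairpin bounds: ", labels[i])
    substr(hp, a, m$end[i])
  }, character(1))
  data.frame(label = labels, mature = parsed$mature,
             shift5 = parsed$shift5, seq = seqs, stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes quantification, normalization, differential expression, the
#' abundance/universe selections, target-set assembly, the three enrichment
#' statistics with the direction-consistency rule, and the TF funnel.
#' All stage outputs are written under `config$out_dir`; internal count
#' consistency (e.g. DE isomiRs being a subset of the abundant ones) is
#' asserted at run time.
#'
#' @param config a `run_config`.
#' @return a run report list (invisible stage outputs attached as
#'   `$stages`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds

  reference <- read_reference(config$paths$hairpin_fasta,
                              config$paths$mature_tsv)
  samples <- read_tsv_table(config$paths$samples_tsv)
  groups <- setNames(samples$group, samples$sample)

  ## stage 1: quantification
  fastq <- unlist(config$paths$fastq)
  if (is.null(names(fastq)) || any(!nzchar(names(fastq))))
    names(fastq) <- sub("\\.fastq(\\.gz)?$", "", basename(fastq))
  quant <- quantify_fastq(fastq, reference, config$adapter,
                          window5 = config$window5,
                          window3 = config$window3)
  iso_counts <- quant$counts[, samples$sample, drop = FALSE]
  write_count_matrix(iso_counts, file.path(out, "isomir_counts.tsv"),
                     id_col = "isomir")
  write_tsv_table(quant$detailed, file.path(out, "isomir_counts_detailed.tsv"))

  ## stage 2: isomiR normalization + DE + abundance selection
  iso_rpm <- to_rpm(iso_counts)
  iso_de <- nb_wald_de(iso_counts, groups[colnames(iso_counts)])
  iso_de <- classify_de(iso_de, th,
                        apply_fold = th$fold_applies_to_isomirs)
  write_tsv_table(iso_de, file.path(out, "isomir_de.tsv"))
  abundant <- select_abundant(iso_rpm, th)
  de_abundant <- intersect(
    abundant, iso_de$feature[iso_de$direction != "ns"])
  stopifnot(all(de_abundant %in% abundant))

  ## stage 3: gene normalization + DE + universe
  gene_counts <- read_count_matrix(config$paths$gene_counts_tsv)
  len_tab <- read_tsv_table(config$paths$gene_lengths_tsv)
  gene_lengths <- setNames(len_tab[[2]], len_tab[[1]])
  sf <- size_factors(gene_counts)
  gene_norm <- sweep(gene_counts, 2, sf, "/")
  gene_fpkm <- to_fpkm(gene_norm, gene_lengths)
  universe <- select_top_expressed(
    gene_fpkm, min(th$top_genes, nrow(gene_fpkm)))
  gene_de <- nb_wald_de(gene_counts, groups[colnames(gene_counts)], sf = sf)
  gene_de <- classify_de(gene_de, th, apply_fold = TRUE)
  write_tsv_table(gene_de, file.path(out, "gene_de.tsv"))

  ## stage 4: target sets for the DE abundant isomiRs
  validated <- read_tsv_table(config$paths$validated_tsv)
  predicted <- read_tsv_table(config$paths$predicted_tsv)
  utrs <- read_fasta(config$paths$utr_fasta)
  isomirs <- isomirs_from_labels(reference, de_abundant)
  target_sets <- build_target_sets(validated, predicted, utrs, isomirs,
                                   universe, config$site_type)
  write_tsv_table(target_sets_table(target_sets),
                  file.path(out, "target_sets.tsv"))

  ## stage 5: enrichment
  or_tab <- or_enrichment_table(target_sets, iso_de, gene_de, universe)
  gene_lfc <- setNames(gene_de$log2FC, gene_de$feature)
  gene_lfc <- gene_lfc[universe]
  ks_tab <- ks_enrichment_table(target_sets, iso_de, gene_lfc)
  write_tsv_table(or_tab, file.path(out, "or_enrichment.tsv"))
  write_tsv_table(ks_tab, file.path(out, "ks_enrichment.tsv"))
  selected <- ks_tab$isomir[ks_tab$q < th$de_fdr & ks_tab$consistent]

  ## stage 6: gene-set enrichment of downregulated targets of up-isomiRs
  up_sel <- intersect(selected,
                      iso_de$feature[iso_de$direction == "up"])
  dn_genes <- gene_de$feature[gene_de$direction == "down"]
  down_targets <- intersect(
    unique(unlist(lapply(target_sets[up_sel], `[[`, "genes"))), dn_genes)
  gmt <- read_gmt(config$paths$gmt)
  gs_tab <- geneset_enrichment(down_targets, gmt, universe, th$de_fdr)
  write_tsv_table(gs_tab, file.path(out, "geneset_enrichment.tsv"))

  ## stage 7: TF triangulation
  funnel <- tf_funnel(config$paths$tf_gene_tsv, config$paths$tf_mirna_tsv,
                      gene_de, de_abundant, config$paths$mature_map_tsv,
                      universe, th, config$min_hits)
  tf_mat <- funnel$result$matrix
  write_tsv_table(
    data.frame(tf = rownames(tf_mat), (tf_mat + 0), check.names = FALSE),
    file.path(out, "tf_mirna_matrix.tsv"))

  report <- list(
    version = as.character(utils::packageVersion("isoshift")),
    n_samples = nrow(samples),
    isomirs_quantified = nrow(iso_counts),
    reads_unmapped = sum(quant$unmapped),
    reads_quantified = sum(quant$total),
    abundant_isomirs = length(abundant),
    de_isomirs_up = sum(iso_de$direction == "up"),
    de_isomirs_down = sum(iso_de$direction == "down"),
    de_abundant_isomirs = length(de_abundant),
    genes_in_universe = length(universe),
    de_genes_up = sum(gene_de$direction == "up" &
                        gene_de$feature %in% universe),
    de_genes_down = sum(gene_de$direction == "down" &
                          gene_de$feature %in% universe),
    targets_per_isomir = setNames(
      vapply(target_sets, function(t) length(t$genes), integer(1)),
      names(target_sets)),
    or_enriched_isomirs = sum(or_tab$q < th$de_fdr),
    ks_enriched_isomirs = sum(ks_tab$q < th$de_fdr),
    selected_isomirs = selected,
    genesets_enriched = sum(gs_tab$enriched),
    tf_candidates = nrow(funnel$candidates),
    tf_de_filtered = nrow(funnel$de_tfs),
    tf_final = nrow(tf_mat),
    unmapped_isomir_labels = funnel$unmapped,
    thresholds = unclass(th)
  )
  stopifnot(report$de_abundant_isomirs <= report$abundant_isomirs,
            report$tf_final <= report$tf_de_filtered,
            report$tf_de_filtered <= report$tf_candidates)
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report$stages <- list(quant = quant, iso_de = iso_de, iso_rpm = iso_rpm,
                        abundant = abundant, gene_de = gene_de,
                        universe = universe, target_sets = target_sets,
                        or_tab = or_tab, ks_tab = ks_tab, gs_tab = gs_tab,
                        funnel = funnel)
  invisible(report)
}
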