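# Triangulation of candidate transcription-factor regulators: (i) TFs whose
# regulon is overrepresented in the top regulated genes, (ii) of those, TFs
# that are themselves differentially expressed, (iii) of those, TFs with a
# recorded edge to the differentially expressed miRNA genes. 5'-isoform
# candidates map to their parent miRNA gene (canonical and shifted isoforms
# share a gene).

#' Load a TF->gene or TF->miRNA edge table
#'
#' Deduplicates pairs and validates non-empty ids.
#'
#' @param x data.frame or TSV path with at least two columns (TF id first,
#'   target id second).
#' @return data.frame with columns tf, target.
#' @export
load_edges <- function(x) {
  if (is.character(x)) x <- read_tsv_table(x)
  if (ncol(x) < 2) stop("edge table needs >= 2 columns")
  e <- data.frame(tf = as.character(x[[1]]), target = as.character(x[[2]]),
                  stringsAsFactors = FALSE)
  if (any(!nzchar(e$tf)) || any(!nzchar(e$target)))
    stop("empty ids in edge table")
  unique(e)
}

#' Candidate TFs by regulon overrepresentation in the top regulated genes
#'
#' Keeps TFs with at least `min_hits` regulon genes inside the union of the
#' top up- and downregulated lists, ranked by the hypergeometric
#' overrepresentation p-value against the universe.
#'
#' @param tf_gene_edges edge table (see `load_edges`); targets are genes.
#' @param top_up_genes,top_down_genes top regulated gene lists (from the DE
#'   table ranked by log2 FC).
#' @param universe analysis universe gene ids.
#' @param min_hits minimum regulon genes among the top lists (default 3).
#' @return data.frame: tf, regulon_size, hits, p (sorted by p).
#' @export
candidate_tfs <- function(tf_gene_edges, top_up_genes, top_down_genes,
                          universe, min_hits = 3L) {
  e <- load_edges(tf_gene_edges)
  if (!nrow(e)) stop("empty TF->gene edge table")
  e <- e[e$target %in% universe, ]
  top <- unique(c(top_up_genes, top_down_genes))
  top <- intersect(top, universe)
  regulons <- split(e$target, e$tf)
  rows <- lapply(names(regulons), function(tf) {
    reg <- unique(regulons[[tf]])
    hits <- length(intersect(reg, top))
    data.frame(tf = tf, regulon_size = length(reg), hits = hits,
               p = phyper(hits - 1, length(reg),
                          length(universe) - length(reg),
                          length(top), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$hits >= min_hits, , drop = FALSE]
  out[order(out$p, out$tf), ]
}

#' Keep candidate TFs that are themselves differentially expressed
#'
#' @param candidates data.frame from `candidate_tfs` (or character vector
#'   of TF ids).
#' @param de_records classified gene DE table (feature, direction columns);
#'   TF ids must appear as features to survive.
#' @return the surviving subset (same shape as `candidates`); TFs absent
#'   from the expression table are dropped with a warning.
#' @export
filter_de_tfs <- function(candidates, de_records) {
  ids <- if (is.data.frame(candidates)) candidates$tf else candidates
  absent <- setdiff(ids, de_records$feature)
  if (length(absent))
    warning("TFs absent from the expression table, dropped: ",
            paste(absent, collapse = ", "))
  de_ids <- de_records$feature[de_records$direction != "ns"]
  keep <- ids %in% de_ids
  if (is.data.frame(candidates)) candidates[keep, , drop = FALSE]
  else ids[keep]
}

#' Map mature isomiR labels to miRNA gene ids
#'
#' A mature label may map to several miRNA genes (multi-locus families);
#' unmapped labels are reported, not fatal.
#'
#' @param isomir_labels character "name|shift" labels.
#' @param mature_map data.frame (mature, mirna_gene) or TSV path.
#' @return list: mirna_genes (character), unmapped (character labels).
#' @export
map_mature_to_gene <- function(isomir_labels, mature_map) {
  if (is.character(mature_map)) mature_map <- read_tsv_table(mature_map)
  matures <- parse_isomir_label(isomir_labels)$mature
  hit <- matures %in% mature_map$mature
  genes <- unique(mature_map$mirna_gene[mature_map$mature %in% matures])
  list(mirna_genes = genes, unmapped = unique(isomir_labels[!hit]))
}

#' TF x miRNA-gene regulator matrix
#'
#' Cell TRUE iff an edge (TF, miRNA gene) exists; TFs with zero coverage
#' are dropped; rows sorted by coverage (number of candidate miRNA genes
#' regulated) descending.
#'
#' @param de_tfs TF ids surviving `filter_de_tfs` (data.frame or character).
#' @param tf_mirna_edges edge table; targets are miRNA gene ids.
#' @param candidate_mirna_genes miRNA gene ids of the candidate isomiRs.
#' @return list: matrix (TF x miRNA-gene logical), coverage (named integer).
#' @export
mirna_regulator_matrix <- function(de_tfs, tf_mirna_edges,
                                   candidate_mirna_genes) {
  ids <- if (is.data.frame(de_tfs)) de_tfs$tf else de_tfs
  e <- load_edges(tf_mirna_edges)
  e <- e[e$tf %in% ids & e$target %in% candidate_mirna_genes, ]
  mat <- matrix(FALSE, length(ids), length(candidate_mirna_genes),
                dimnames = list(ids, candidate_mirna_genes))
  if (nrow(e))
    mat[cbind(match(e$tf, ids), match(e$target, candidate_mirna_genes))] <- TRUE
  cov <- rowSums(mat)
  mat <- mat[cov > 0, , drop = FALSE]
  cov <- sort(cov[cov > 0], decreasing = TRUE)
  mat <- mat[names(cov), , drop = FALSE]
  list(matrix = mat, coverage = cov)
}

#' Run the full three-stage TF funnel
#'
#' @param tf_gene_edges,tf_mirna_edges edge tables.
#' @param gene_de classified gene DE table (feature, log2FC, direction).
#' @param isomir_labels candidate isomiR labels (the selected DE isomiRs).
#' @param mature_map mature->miRNA-gene map.
#' @param universe analysis universe gene ids.
#' @param thresholds a `filter_thresholds` (uses top_regulated).
#' @param min_hits regulon hit threshold for stage 1.
#' @return list: candidates, de_tfs, result (from
#'   `mirna_regulator_matrix`), unmapped, top_up, top_down.
#' @export
tf_funnel <- function(tf_gene_edges, tf_mirna_edges, gene_de, isomir_labels,
                      mature_map, universe,
                      thresholds = filter_thresholds(), min_hits = 3L) {
  de <- gene_de[gene_de$feature %in% universe, ]
  ord <- order(de$log2FC, decreasing = TRUE)
  top_up <- de$feature[ord][seq_len(min(thresholds$top_regulated, nrow(de)))]
  ord <- order(de$log2FC)
  top_down <- de$feature[ord][seq_len(min(thresholds$top_regulated, nrow(de)))]
  cand <- candidate_tfs(tf_gene_edges, top_up, top_down, universe, min_hits)
  de_tfs <- filter_de_tfs(cand, gene_de)
  mapping <- map_mature_to_gene(isomir_labels, mature_map)
  res <- mirna_regulator_matrix(de_tfs, tf_mirna_edges, mapping$mirna_genes)
  list(candidates = cand, de_tfs = de_tfs, result = res,
       unmapped = mapping$unmapped, top_up = top_up, top_down = top_down)
}
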