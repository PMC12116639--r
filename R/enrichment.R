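# The three enrichment statistics of the pipeline: Fisher odds-ratio target
# overrepresentation among oppositely regulated genes, the Kolmogorov-
# Smirnov distance between target and non-target fold-change distributions,
# and hallmark-style gene-set overrepresentation — plus the direction-
# consistency rule that discards isomiRs whose own fold change agrees in
# sign with their targets' shift.

#' Fisher odds-ratio overrepresentation of a target set
#'
#' Contingency over the universe: td/tn = targets among regulated /
#' non-regulated genes, nd/nn = non-targets likewise. The odds ratio is the
#' sample ratio (td/tn)/(nd/nn); the p-value is the one-sided
#' (overrepresentation) hypergeometric tail by default. "Non-regulated"
#' excludes ALL differentially expressed genes, both directions, when
#' `excluded` is given.
#'
#' @param target_set character vector of target gene ids (subset of universe).
#' @param regulated_genes regulated genes of the tested direction (subset of
#'   universe) — for an upregulated isomiR, the downregulated genes.
#' @param universe analysis universe of gene ids.
#' @param excluded genes removed from the non-regulated class (e.g. DE genes
#'   of the other direction); they drop out of the table entirely.
#' @param alternative "greater" (one-sided overrepresentation, default) or
#'   "two.sided".
#' @return list: td, tn, nd, nn, odds_ratio, p.
#' @export
fisher_or <- function(target_set, regulated_genes, universe,
                      excluded = character(0),
                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  target_set <- intersect(target_set, universe)
  regulated_genes <- intersect(regulated_genes, universe)
  nonreg <- setdiff(universe, union(regulated_genes, excluded))
  td <- length(intersect(target_set, regulated_genes))
  tn <- length(intersect(target_set, nonreg))
  nd <- length(setdiff(regulated_genes, target_set))
  nn <- length(setdiff(nonreg, target_set))
  or <- if (tn == 0 || nd == 0) {
    if (td > 0) Inf else NaN
  } else (td / tn) / (nd / nn)
  n_t <- td + tn; n_d <- td + nd; n_tot <- td + tn + nd + nn
  p <- phyper(td - 1, n_t, n_tot - n_t, n_d, lower.tail = FALSE)
  if (alternative == "two.sided") {
    # sum of hypergeometric point probabilities <= that of the observed table
    x <- seq(max(0, n_d - (n_tot - n_t)), min(n_t, n_d))
    d <- stats::dhyper(x, n_t, n_tot - n_t, n_d)
    p <- sum(d[d <= stats::dhyper(td, n_t, n_tot - n_t, n_d) * (1 + 1e-7)])
  }
  list(td = td, tn = tn, nd = nd, nn = nn, odds_ratio = or,
       p = min(p, 1))
}

#' Kolmogorov-Smirnov distance between target and non-target fold changes
#'
#' D is the supremum over the pooled sample points of the absolute
#' difference between the two empirical CDFs of log2 fold change; the
#' p-value is the asymptotic two-sided two-sample KS tail. The direction
#' flag is the sign of (median target log2 FC - median non-target log2 FC).
#'
#' @param log2fc_by_gene named numeric: log2 fold change per universe gene.
#' @param seed_target_genes gene ids forming the target partition; the
#'   remaining names of `log2fc_by_gene` form the non-target partition.
#' @return list: D, p, direction (-1/0/+1), n_targets, n_nontargets.
#' @export
ks_seed_enrichment <- function(log2fc_by_gene, seed_target_genes) {
  if (any(!is.finite(log2fc_by_gene))) stop("non-finite log2 fold change")
  x <- log2fc_by_gene[names(log2fc_by_gene) %in% seed_target_genes]
  y <- log2fc_by_gene[!names(log2fc_by_gene) %in% seed_target_genes]
  if (!length(x) || !length(y)) stop("a fold-change partition is empty")
  pooled <- sort(unique(c(x, y)))
  # counts of values <= each pooled point, via binary search on sorted data
  ex <- findInterval(pooled, sort(x)) / length(x)
  ey <- findInterval(pooled, sort(y)) / length(y)
  D <- max(abs(ex - ey))
  ne <- length(x) * length(y) / (length(x) + length(y))
  p <- ks_asymptotic_p(sqrt(ne) * D)
  list(D = D, p = p,
       direction = sign(median(x) - median(y)),
       n_targets = length(x), n_nontargets = length(y))
}

# two-sided asymptotic KS tail: P(sup |B| > t) = 2 sum (-1)^(k-1) exp(-2 k^2 t^2)
ks_asymptotic_p <- function(t) {
  if (t < 0.05) return(1)  # series region where the tail is 1 to >10 digits
  k <- seq_len(1000)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Direction consistency of an isomiR with its targets
#'
#' TRUE iff the isomiR's own fold change is opposite in sign to the shift
#' of its targets' fold-change distribution (repression logic). A zero
#' median difference is inconsistent by convention.
#'
#' @param isomir_log2fc the isomiR's log2 fold change.
#' @param ks_result output of `ks_seed_enrichment` (uses `$direction`).
#' @return logical.
#' @export
direction_consistent <- function(isomir_log2fc, ks_result) {
  flag <- ks_result$direction
  if (flag == 0) return(FALSE)
  sign(isomir_log2fc) == -flag
}

#' Per-isomiR odds-ratio enrichment table (opposite-direction rule)
#'
#' For each isomiR, tests its target set against the oppositely regulated
#' genes (up-isomiR vs down-genes and vice versa); BH FDR across the tested
#' isomiRs.
#'
#' @param target_sets named list from `build_target_sets`.
#' @param isomir_de classified isomiR DE table (needs feature, log2FC,
#'   direction).
#' @param gene_de classified gene DE table (needs feature, direction).
#' @param universe analysis universe gene ids.
#' @return data.frame: isomir, isomir_direction, td, tn, nd, nn,
#'   odds_ratio, p, q.
#' @export
or_enrichment_table <- function(target_sets, isomir_de, gene_de, universe) {
  gene_de <- gene_de[gene_de$feature %in% universe, ]
  up_genes <- gene_de$feature[gene_de$direction == "up"]
  dn_genes <- gene_de$feature[gene_de$direction == "down"]
  labs <- intersect(names(target_sets),
                    isomir_de$feature[isomir_de$direction != "ns"])
  rows <- lapply(labs, function(lab) {
    dir <- isomir_de$direction[isomir_de$feature == lab]
    reg <- if (dir == "up") dn_genes else up_genes
    other <- if (dir == "up") up_genes else dn_genes
    fo <- fisher_or(target_sets[[lab]]$genes, reg, universe,
                    excluded = other)
    data.frame(isomir = lab, isomir_direction = dir, td = fo$td,
               tn = fo$tn, nd = fo$nd, nn = fo$nn,
               odds_ratio = fo$odds_ratio, p = fo$p,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(isomir = character(0), isomir_direction = character(0),
                      td = integer(0), tn = integer(0), nd = integer(0),
                      nn = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Per-isomiR KS enrichment table with the direction-consistency flag
#'
#' @param target_sets named list from `build_target_sets`.
#' @param isomir_de classified isomiR DE table.
#' @param gene_log2fc named numeric: gene log2 FC over the universe.
#' @return data.frame: isomir, isomir_direction, distance, p, q,
#'   target_shift (-1/0/+1), consistent.
#' @export
ks_enrichment_table <- function(target_sets, isomir_de, gene_log2fc) {
  labs <- intersect(names(target_sets),
                    isomir_de$feature[isomir_de$direction != "ns"])
  labs <- labs[vapply(labs, function(l)
    length(target_sets[[l]]$genes) > 0, logical(1))]
  rows <- lapply(labs, function(lab) {
    ks <- ks_seed_enrichment(gene_log2fc, target_sets[[lab]]$genes)
    lfc <- isomir_de$log2FC[isomir_de$feature == lab]
    data.frame(isomir = lab,
               isomir_direction =
                 isomir_de$direction[isomir_de$feature == lab],
               distance = ks$D, p = ks$p, target_shift = ks$direction,
               consistent = direction_consistent(lfc, ks),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(isomir = character(0), isomir_direction = character(0),
                      distance = numeric(0), p = numeric(0), q = numeric(0),
                      target_shift = numeric(0), consistent = logical(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[, c("isomir", "isomir_direction", "distance", "p", "q",
          "target_shift", "consistent")]
}

#' Gene-set overrepresentation of the downregulated targets
#'
#' One-sided Fisher overrepresentation of `down_targets` inside each gene
#' set against the universe; BH FDR across sets; q < `fdr` flags a set
#' enriched.
#'
#' @param down_targets gene ids (e.g. downregulated targets of the selected
#'   isomiRs).
#' @param geneset_collection named list of gene-id vectors (e.g. from
#'   `read_gmt`).
#' @param universe analysis universe gene ids.
#' @param fdr enrichment FDR threshold.
#' @return data.frame: set, n_set, overlap, odds_ratio, p, q, enriched.
#' @export
geneset_enrichment <- function(down_targets, geneset_collection, universe,
                               fdr = 0.05) {
  if (!length(geneset_collection)) stop("empty gene-set collection")
  down_targets <- intersect(down_targets, universe)
  rows <- lapply(names(geneset_collection), function(nm) {
    set <- intersect(geneset_collection[[nm]], universe)
    fo <- fisher_or(set, down_targets, universe)
    data.frame(set = nm, n_set = length(set), overlap = fo$td,
               odds_ratio = fo$odds_ratio, p = fo$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$enriched <- out$q < fdr
  out[order(out$p), ]
}
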