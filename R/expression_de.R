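# Normalization (median-of-ratios size factors, RPM, FPKM), a simplified
# negative-binomial Wald test for two-group differential expression with
# Benjamini-Hochberg FDR, and the abundance / top-expression selection
# filters applied downstream.

#' Median-of-ratios size factors
#'
#' For each sample, the median over features (restricted to features with
#' nonzero counts in every sample) of the ratio of its count to the
#' feature's geometric mean across samples.
#'
#' @param counts feature x sample count matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) stop("size factors undefined: no feature is nonzero in all samples")
  lg <- log(counts[ok, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2, median)
}

#' Reads-per-million transform
#'
#' @param counts feature x sample count matrix (column sums > 0).
#' @return matrix with every column summing to 1e6.
#' @export
to_rpm <- function(counts) {
  counts <- as.matrix(counts)
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("zero column total in count matrix")
  sweep(counts, 2, cs, "/") * 1e6
}

#' FPKM transform of size-normalized counts
#'
#' fpkm_ij = normalized_ij / (length_i / 1e3) / (colsum(normalized)_j / 1e6).
#'
#' @param norm_counts size-normalized feature x sample matrix.
#' @param gene_lengths named vector of feature lengths (nt); every row of
#'   `norm_counts` must have a length.
#' @return FPKM matrix.
#' @export
to_fpkm <- function(norm_counts, gene_lengths) {
  norm_counts <- as.matrix(norm_counts)
  len <- gene_lengths[rownames(norm_counts)]
  if (any(is.na(len))) stop("missing gene length for: ",
                            rownames(norm_counts)[which(is.na(len))[1]])
  if (any(len <= 0)) stop("non-positive gene length")
  cs <- colSums(norm_counts)
  if (any(cs <= 0)) stop("zero column total")
  sweep(norm_counts / (len / 1e3), 2, cs / 1e6, "/")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (monotone, order-preserving); wraps the standard
#' adjustment with an explicit NaN guard.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p))) stop("NaN/NA p-values not allowed")
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

# method-of-moments dispersion per feature, with an optional 1/mu trend fit
# across features; per-feature estimates at n = 7/8 are too noisy for a
# stable Wald denominator, the trend borrows strength across features
mom_dispersion <- function(norm_counts, groups, inv_s_mean, floor = 1e-8,
                           trend = TRUE) {
  g <- unique(groups)
  y1 <- norm_counts[, groups == g[1], drop = FALSE]
  y2 <- norm_counts[, groups == g[2], drop = FALSE]
  n1 <- ncol(y1); n2 <- ncol(y2)
  v <- ((n1 - 1) * apply(y1, 1, var) + (n2 - 1) * apply(y2, 1, var)) /
    (n1 + n2 - 2)
  mbar <- (n1 * rowMeans(y1) + n2 * rowMeans(y2)) / (n1 + n2)
  raw <- (v - mbar * inv_s_mean) / mbar^2
  raw[!is.finite(raw)] <- NA
  alpha <- pmax(raw, floor)
  if (trend && sum(is.finite(raw) & mbar > 0) >= 50) {
    use <- which(is.finite(raw) & mbar > 1)
    fit <- lm(raw[use] ~ I(1 / mbar[use]))
    a0 <- max(coef(fit)[1], 0)
    a1 <- max(coef(fit)[2], 0)
    alpha <- pmax(a0 + a1 / pmax(mbar, 1e-8), floor)
  }
  alpha[is.na(alpha)] <- floor
  alpha
}

#' Two-group negative-binomial Wald differential expression
#'
#' A deliberately simple NB test: counts are normalized by median-of-ratios
#' size factors; per-group means are compared on the log2 scale with a
#' pseudocount; the Wald standard error uses a method-of-moments dispersion
#' (a 1/mu trend fitted across features by default, per-feature optionally)
#' floored at `alpha_floor`; p-values are two-sided normal; q-values are
#' Benjamini-Hochberg. log2 FC is group2 vs group1.
#'
#' @param counts feature x sample count matrix.
#' @param groups character/factor of length ncol(counts) with two levels;
#'   the first level encountered is the reference (group1).
#' @param sf optional precomputed size factors.
#' @param pseudocount added to both group means before the log ratio.
#' @param alpha_floor dispersion floor.
#' @param trend_dispersion fit the cross-feature dispersion trend (default)
#'   or use per-feature estimates.
#' @return data.frame: feature, baseMean, log2FC, SE, p, q.
#' @export
nb_wald_de <- function(counts, groups, sf = NULL, pseudocount = 0.5,
                       alpha_floor = 1e-8, trend_dispersion = TRUE) {
  counts <- as.matrix(counts)
  lv <- if (is.factor(groups)) levels(droplevels(groups)) else
    unique(as.character(groups))
  groups <- as.character(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 2) stop("each group needs >= 2 samples")
  if (is.null(sf)) sf <- size_factors(counts)
  y <- sweep(counts, 2, sf, "/")
  i1 <- groups == lv[1]; i2 <- groups == lv[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, i2, drop = FALSE])
  inv_s_mean <- mean(1 / sf)
  alpha <- mom_dispersion(y, groups, inv_s_mean, alpha_floor,
                          trend_dispersion)
  # Var(mean of K_ij / s_j) with NB Var(K) = mu s + alpha (mu s)^2
  var_mean <- function(m, idx, n)
    (m * sum(1 / sf[idx]) + alpha * m^2 * n) / n^2
  v1 <- var_mean(m1, i1, n1)
  v2 <- var_mean(m2, i2, n2)
  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  se <- sqrt(v1 / (m1 + pseudocount)^2 + v2 / (m2 + pseudocount)^2) / log(2)
  se[se == 0 | !is.finite(se)] <- NA
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))
  p[is.na(p)] <- 1
  data.frame(feature = rownames(counts),
             baseMean = rowMeans(y), log2FC = lfc, SE = se,
             p = p, q = bh_fdr(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter thresholds for the selection steps
#'
#' @param de_fdr FDR threshold for differential expression (default 0.05).
#' @param min_fold minimum fold change for DE genes (default 2).
#' @param min_mean_rpm isomiR abundance threshold, mean RPM (default 100).
#' @param cum_fraction cumulative share of total isomiR expression covered
#'   by the selected top isomiRs (default 0.95).
#' @param top_genes number of most-expressed genes kept as the analysis
#'   universe (default 10000).
#' @param top_regulated length of the top up/down gene lists for the TF
#'   step (default 500).
#' @param fold_applies_to_isomirs whether the >2-fold rule also applies to
#'   isomiRs (default FALSE: genes only).
#' @return a validated `filter_thresholds` list.
#' @export
filter_thresholds <- function(de_fdr = 0.05, min_fold = 2,
                              min_mean_rpm = 100, cum_fraction = 0.95,
                              top_genes = 10000L, top_regulated = 500L,
                              fold_applies_to_isomirs = FALSE) {
  th <- list(de_fdr = de_fdr, min_fold = min_fold,
             min_mean_rpm = min_mean_rpm, cum_fraction = cum_fraction,
             top_genes = as.integer(top_genes),
             top_regulated = as.integer(top_regulated),
             fold_applies_to_isomirs = isTRUE(fold_applies_to_isomirs))
  stopifnot(th$de_fdr > 0, th$min_fold > 0, th$min_mean_rpm > 0,
            th$cum_fraction > 0, th$cum_fraction <= 1,
            th$top_genes > 0, th$top_regulated > 0)
  class(th) <- "filter_thresholds"
  th
}

#' Select abundant isomiRs (RPM threshold + cumulative-95% rule)
#'
#' Step 1 keeps isomiRs with mean RPM above `min_mean_rpm`; step 2 ranks
#' them by mean RPM (descending, ties by label) and selects the smallest
#' prefix whose cumulative share of the TOTAL mean RPM over all isomiRs
#' reaches `cum_fraction`.
#'
#' @param rpm isomiR x sample RPM matrix.
#' @param thresholds a `filter_thresholds`.
#' @return character vector of selected isomiR labels (ranked).
#' @export
select_abundant <- function(rpm, thresholds = filter_thresholds()) {
  rpm <- as.matrix(rpm)
  if (nrow(rpm) == 0) stop("empty RPM matrix")
  mean_rpm <- rowMeans(rpm)
  total <- sum(mean_rpm)
  kept <- mean_rpm[mean_rpm > thresholds$min_mean_rpm]
  if (!length(kept)) return(character(0))
  ord <- order(-kept, names(kept))
  kept <- kept[ord]
  share <- cumsum(kept) / total
  n_sel <- which(share >= thresholds$cum_fraction)[1]
  if (is.na(n_sel)) n_sel <- length(kept)
  names(kept)[seq_len(n_sel)]
}

#' Select the top-n expressed genes by mean FPKM
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param n number of genes to keep (ties broken by label).
#' @return character vector of gene ids.
#' @export
select_top_expressed <- function(fpkm, n) {
  fpkm <- as.matrix(fpkm)
  if (n > nrow(fpkm)) stop("n exceeds number of genes")
  mean_fpkm <- rowMeans(fpkm)
  ord <- order(-mean_fpkm, rownames(fpkm))
  rownames(fpkm)[ord][seq_len(n)]
}

#' Classify DE features from a DE table
#'
#' Applies the FDR threshold, and the fold-change rule when requested
#' (always for genes; for isomiRs only if the thresholds say so).
#'
#' @param de data.frame from `nb_wald_de`.
#' @param thresholds a `filter_thresholds`.
#' @param apply_fold whether the >`min_fold` rule applies.
#' @return data.frame `de` with an added `direction` column
#'   ("up"/"down"/"ns").
#' @export
classify_de <- function(de, thresholds = filter_thresholds(),
                        apply_fold = TRUE) {
  sig <- de$q < thresholds$de_fdr
  if (apply_fold) sig <- sig & abs(de$log2FC) > log2(thresholds$min_fold)
  de$direction <- ifelse(!sig, "ns", ifelse(de$log2FC > 0, "up", "down"))
  de
}
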