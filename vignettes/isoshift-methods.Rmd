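---
title: "isoshift: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isoshift: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isoshift` analyses miRNA 5′-isoforms (isomiRs): sequence variants of a
mature miRNA whose 5′ end is shifted relative to the canonical form. The
5′ end defines the seed (nucleotides 2–7/8), so a 5′ shift changes the
seed and with it the target repertoire. This vignette explains each model
in the chain, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Quantification model

Reads are single-end small-RNA reads carrying a 3′ sequencing adapter
(default `AGATCGGAAGAGCACACGTCT`). Trimming removes everything from the
leftmost full adapter occurrence, or from the longest adapter *prefix* of
at least `min_overlap = 3` nt anchored at the read's 3′ end; reads without
adapter evidence pass through whole, and trimmed reads shorter than
`min_len = 16` nt are discarded. The 3-nt floor keeps the false-trim rate
of random suffixes at 4^-3 per read end while still catching short
read-through; 16 nt is the shortest insert that can still be an
unambiguous miRNA fragment.

Annotation is exact-match only. An index maps every hairpin substring
reachable as (mature start + shift5 … mature end + shift3), with
`shift5 ∈ [-3, +3]` and `shift3 ∈ [-5, +5]` by default, to its isomiR
identity. Windows are generous relative to the ±1 shifts that dominate
real data, and configurable. Positive `shift5` means the 5′ end moved
3′-ward, i.e. the isoform is *shortened*, matching the `name|+1` label
convention. A read matching k distinct reference loci contributes 1/k to
each, so total mapped weight plus unmapped reads equals the read count
exactly — an invariant the tests assert. Counts are reported per
`mature|shift5` label; 3′-shift variants collapse into the same label
because the 3′ end does not affect the seed, and the per-(5′,3′) breakdown
is kept in a detailed table. Mismatches and non-templated 3′ additions are
out of scope by design: exact matching keeps the annotation equal to a
brute-force substring search, which is the correctness oracle the
acceptance tests use.

## Normalization and differential expression

Size factors are plain median-of-ratios: for sample j, the median over
features with nonzero counts everywhere of count_ij divided by the
feature's geometric mean. One subtlety the tests document: scaling one
sample's counts by c scales its factor *relative to any other sample* by
c, while the raw factor absorbs c^((n-1)/n) because the per-feature
geometric means move too.

RPM divides each column by its total × 10^6 (identical whether applied to
raw or size-normalized counts, since the transform renormalizes columns).
FPKM divides size-normalized counts by gene length in kb and by the
column total in millions.

The DE test is a deliberately simple two-group negative-binomial Wald
test, not a re-implementation of any published package:

* per-group means m1, m2 of size-normalized counts;
* log2 FC = log2((m2 + 0.5)/(m1 + 0.5)) — the 0.5 pseudocount bounds the
  statistic for features absent in one group;
* dispersion α by method of moments, v = μ·E[1/s] + α·μ², with a 1/μ
  trend (α(μ) = a0 + a1/μ, non-negative least squares on per-feature
  estimates) fitted across features and used as the working value,
  floored at 10^-8. Per-feature moment estimates at n = 7/8 are far too
  noisy to sit in a Wald denominator; borrowing strength through the
  trend is what makes the normal reference distribution honest. The
  per-feature option remains available (`trend_dispersion = FALSE`);
* Wald z = log2FC/SE with the delta-method SE, two-sided normal p, BH q.

Correctness is claimed through calibration, not parity: under the
generator's null (7 vs 8 samples, 2000 features, dispersion 0.1, ten
seeds) the fraction of p < 0.05 must land in [0.03, 0.07], and planted
|log2 FC| = 1.5 at mean 500 must be recovered (q < 0.05 and > 2-fold) for
at least 80% of affected features — both are acceptance tests. Shrinkage,
covariates, outlier handling and independent filtering are non-goals.

## Selection filters

* DE calls use FDR < 0.05; genes must additionally change more than
  2-fold. By default the fold rule does *not* apply to isomiRs
  (`filter_thresholds(fold_applies_to_isomirs = )` to change): the fold
  requirement is stated for genes, and applying it to isomiRs as well is
  a stricter, flagged variant.
* Abundant isomiRs: mean RPM > 100 (arithmetic mean over all samples,
  both groups pooled), then the smallest prefix of the RPM-ranked
  survivors whose cumulative share of the total mean RPM *over all
  isomiRs* reaches 95%. Using the all-isomiR total (not the thresholded
  subset) is intentional — "95% of total expression" means total. Ties
  break lexicographically for determinism.
* Analysis universe: the top 10,000 genes by mean FPKM (or all genes when
  fewer are simulated).

## Seeds, sites and target sets

The seed of an isoform is taken on the *isoform*, positions 2–7 (6mer) or
2–8 (7mer-m8), after applying the 5′ shift — so a `|+1` isoform's 6mer
equals positions 3–8 of the canonical mature, which is checked
exhaustively in the tests. Sites are seed reverse complements in DNA on
the UTR sense strand (7mer-A1 = 6mer site followed by A); overlapping
occurrences all count.

Canonical isomiRs take validated-table targets intersected with the
universe, with no seed filter (validated interactions stand on their own
evidence). Non-canonical isomiRs take predicted-table targets intersected
with the universe *and* with genes whose UTR contains the shifted seed's
site. The seed is always re-derived from the shifted isoform and
re-scanned, regardless of how the source table was indexed; the 6mer is
the default filter site, with the 7-nt variants behind a flag.

## Enrichment statistics

**Odds ratio.** For each DE isomiR the target set is tested against the
*oppositely* regulated genes — downregulated genes for an upregulated
isomiR and vice versa — since repression is the expected sign. With td/tn
targets among regulated/non-regulated and nd/nn non-targets likewise,
OR = (td/tn)/(nd/nn) (the sample ratio, reported as +Inf when tn or nd is
zero with td > 0), and p is the one-sided hypergeometric tail
(overrepresentation; two-sided by flag). "Non-regulated" excludes DE
genes of *both* directions, so the comparison class is genuinely
unregulated. BH is applied within the per-isomiR OR family.

**KS distance.** D is the supremum over pooled sample points of the
absolute difference between the target and non-target ECDFs of log2 fold
change, computed exactly by sorting (the tests compare it against a
double-loop oracle). The p-value is the asymptotic two-sided two-sample
tail, 2·Σ(-1)^(k-1)·exp(-2k²·ne·D²) with ne = n1·n2/(n1+n2), summed to
1000 terms and clamped to [0, 1]; gene universes are large enough that
exact small-sample KS is unnecessary. The default non-target class is
"all remaining universe genes" (a flag could restrict it further); the
partition choice matters little at universe scale.

**Direction consistency.** An isomiR is kept only if the sign of its own
log2 FC is opposite to the sign of (median target FC − median non-target
FC); a zero median difference counts as inconsistent. This excludes the
pathological case of a downregulated isomiR whose targets also go down —
there the association cannot be the isomiR's own repression.

**Gene sets.** The downregulated targets of the selected upregulated
isomiRs are tested for overrepresentation in each gene set (one-sided
Fisher against the universe, BH across sets, enriched at q < 0.05).

## TF triangulation

Three stages, each a strict subset of the previous: (1) TFs whose regulon
hits the union of the top-500 up- and top-500 downregulated genes (ranked
by log2 FC) at least `min_hits = 3` times, ranked by hypergeometric
overrepresentation — a local-edge-table stand-in for interactive regulon
enrichment tools, whose exact scoring is not public; (2) TFs whose own
gene is DE (a regulator that moves expression downstream should itself
respond); (3) TFs with at least one edge to the candidate miRNA genes,
where 5′-isoform labels map to their parent miRNA gene via an explicit
mature→gene table (a mature may map to several loci; unmapped labels are
reported, not fatal). Up/down lists are analyzed jointly by default;
candidate coverage sorts the final matrix.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the study conditions the pipeline is
designed for: two groups of 7 and 8 samples; negative-binomial counts
(var = μ + αμ², α = 0.1 — mid-range for bulk tissue RNA-seq); log-normal
baseline abundances (gene means around 300 with σ_log = 1.2, spanning
roughly three orders of magnitude); a minority of isomiRs (4 up, 2 down
by default, including one `|+1` and one `|-1` isoform) and of genes
planted at |log2 FC| ≥ 1, since features below 2-fold are by definition
outside the pipeline's DE class; 3% of genes as targets per active
isomiR, each target UTR carrying 1–2 exact seed sites and every
non-target UTR rejection-sampled to carry none; reads of 50 nt built as
isoform + adapter + random padding at 10^5 reads per sample; and decoy
rows in every relation table at a 20% Bernoulli rate, enough to exercise
specificity without overwhelming power at n = 7/8. Planted TFs regulate
strongly-moved genes and the active miRNA genes and are themselves
planted DE; decoy TFs each fail exactly one funnel stage, which is what
makes "no decoy admitted" a meaningful exact check.

Deliberately not emulated: sequencing errors and quality variation,
non-templated 3′ additions, multi-mapping to a genome, batch effects,
library-preparation biases, compositional coupling beyond renormalization
of proportions, and correlated UTR composition. Passing tests therefore
demonstrate the *inference chain* is correct under its stated model — not
that the model captures every failure mode of real libraries; with real
data, adapter quality, error tolerance and the exact-match assumption
are the places to look first.

## Numerical choices and degenerate inputs

* Determinism throughout: one seed drives a scenario; identical configs
  produce byte-identical files; selection ties break lexicographically.
* Size factors are undefined (an error) when no feature is nonzero in
  every sample; RPM/FPKM reject zero column totals and missing lengths.
* OR degeneracies: +Inf when td > 0 with an empty margin, NaN for an
  empty table; KS requires both partitions non-empty; BH rejects NA.
* The lookup index silently clips shift windows that run outside a
  hairpin; isoform extension past the hairpin 5′ end is an error.
* Problem sizes in the bundled analyses and acceptance run — 20 miRNAs ×
  3 isoforms, 3000 genes, 10^5 reads × 15 samples, 10–20 seed replicates
  for calibration properties — were chosen so the full chain and its
  calibration checks complete in a few minutes on a laptop while keeping
  every statistic in its well-powered regime.

## Orchestration

`run_pipeline()` executes the stages in dependency order from one
validated config (paths checked before any compute), writes every stage
table as headered TSV plus a JSON run report with per-stage counts, and
asserts internal consistency (DE ∩ abundant ⊆ abundant; funnel
monotonicity) at run time. Stages are pure functions of their inputs, so
a rerun under the same config is byte-identical — the tests assert this —
and any stage can be re-run from the written upstream tables; no
content-hash caching layer is used, as every stage is cheap at desk
scale. The numbered scripts under `analysis/` present the same chain as a
narrative, file-driven workflow.

## Known limitations

* Exact-match quantification undercounts isoforms with sequencing errors
  or non-templated additions; counts are a lower bound in real data.
* The DE test has no shrinkage: at very low counts its fold-change
  estimates are noisy (the pseudocount only bounds them), and the
  trended dispersion can misfit collections with strongly mean-dependent
  biology.
* The KS p-value is asymptotic; for very small target sets (< ~10 genes)
  it is approximate, though the BH step and the direction rule dominate
  selection there.
* TF regulon enrichment is a minimal hypergeometric model over a single
  edge table; it does not model edge sign/mode, motif evidence, or
  regulon activity.
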