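# Synthetic-data generator: every input the pipeline consumes, with planted
# truth. Emulates a two-group small-RNA + mRNA study (7 vs 8 samples,
# negative-binomial counts, a minority of isomiRs/genes carrying >= 2-fold
# planted effects, exact seed sites planted in target 3'UTRs, and TF edge
# tables consistent with the planted regulators).

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the pipeline is built for: two groups of 7 and 8 samples,
#' negative-binomial counts, and a minority of features carrying planted
#' effects of at least 2-fold (|log2 FC| >= 1).
#'
#' @param n_mirnas number of miRNA hairpins in the reference.
#' @param n_isoforms_per_mirna number of 5'-isoforms per mature (canonical
#'   first, then shifts +1, -1, +2, -2, ...).
#' @param n_genes number of protein-coding genes (TF genes are appended on
#'   top of these).
#' @param n_samples_per_group integer pair: control and treatment group sizes.
#' @param depth_smallrna small-RNA reads per sample.
#' @param nb_dispersion negative-binomial dispersion alpha (var = mu + alpha mu^2).
#' @param planted_isomir_effects named numeric, isomiR label -> log2 FC.
#'   `NULL` plants a default program (see `plan_truth`).
#' @param planted_gene_effects named numeric, gene id -> log2 FC. `NULL`
#'   lets `plan_truth` derive gene effects from the isomiR program.
#' @param target_fraction fraction of genes carrying a planted seed site per
#'   active isomiR.
#' @param decoy_rate Bernoulli rate of decoy rows in target/edge tables.
#' @param rng_seed integer seed; identical configs give byte-identical outputs.
#' @param n_up_isomirs,n_down_isomirs sizes of the default planted program.
#' @param isomir_effect_size |log2 FC| of default planted isomiR effects.
#' @param n_extra_de_genes independently regulated genes outside the target
#'   programs (feed the top-regulated lists and TF regulons).
#' @param n_tfs,n_decoy_tfs planted true regulator TFs and decoy TFs.
#' @param mature_len_range,utr_len_range,gene_length_range length ranges (nt).
#' @param gene_mean_log,gene_mean_sdlog log-normal parameters of gene means.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_mirnas = 20L,
                       n_isoforms_per_mirna = 3L,
                       n_genes = 3000L,
                       n_samples_per_group = c(7L, 8L),
                       depth_smallrna = 1e5,
                       nb_dispersion = 0.1,
                       planted_isomir_effects = NULL,
                       planted_gene_effects = NULL,
                       target_fraction = 0.03,
                       decoy_rate = 0.2,
                       rng_seed = 1L,
                       n_up_isomirs = 4L,
                       n_down_isomirs = 2L,
                       isomir_effect_size = 1.5,
                       n_extra_de_genes = 200L,
                       n_tfs = 3L,
                       n_decoy_tfs = 6L,
                       mature_len_range = c(20L, 24L),
                       utr_len_range = c(250L, 600L),
                       gene_length_range = c(500L, 4000L),
                       gene_mean_log = log(300),
                       gene_mean_sdlog = 1.2) {
  cfg <- list(
    n_mirnas = as.integer(n_mirnas),
    n_isoforms_per_mirna = as.integer(n_isoforms_per_mirna),
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    depth_smallrna = depth_smallrna,
    nb_dispersion = nb_dispersion,
    planted_isomir_effects = planted_isomir_effects,
    planted_gene_effects = planted_gene_effects,
    target_fraction = target_fraction,
    decoy_rate = decoy_rate,
    rng_seed = as.integer(rng_seed),
    n_up_isomirs = as.integer(n_up_isomirs),
    n_down_isomirs = as.integer(n_down_isomirs),
    isomir_effect_size = isomir_effect_size,
    n_extra_de_genes = as.integer(n_extra_de_genes),
    n_tfs = as.integer(n_tfs),
    n_decoy_tfs = as.integer(n_decoy_tfs),
    mature_len_range = as.integer(mature_len_range),
    utr_len_range = as.integer(utr_len_range),
    gene_length_range = as.integer(gene_length_range),
    gene_mean_log = gene_mean_log,
    gene_mean_sdlog = gene_mean_sdlog
  )
  stopifnot(
    cfg$n_mirnas >= 1L, cfg$n_isoforms_per_mirna >= 1L, cfg$n_genes >= 1L,
    length(cfg$n_samples_per_group) == 2L, all(cfg$n_samples_per_group >= 1L),
    cfg$depth_smallrna >= 1, cfg$nb_dispersion > 0,
    cfg$target_fraction >= 0, cfg$target_fraction <= 1,
    cfg$decoy_rate >= 0, cfg$decoy_rate <= 1
  )
  for (eff in list(cfg$planted_isomir_effects, cfg$planted_gene_effects)) {
    if (!is.null(eff) && any(eff != 0 & abs(eff) < 1))
      stop("planted effects must be 0 or |log2 FC| >= 1 (at least 2-fold)")
  }
  if (cfg$isomir_effect_size < 1)
    stop("isomir_effect_size must be >= 1 (at least 2-fold)")
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# many random DNA strings of given lengths, one RNG stream, vectorized
random_dna_vec <- function(lengths) {
  tot <- sum(lengths)
  if (tot == 0) return(rep("", length(lengths)))
  long <- paste(sample(c("A", "C", "G", "T"), tot, replace = TRUE),
                collapse = "")
  ends <- cumsum(lengths)
  substring(long, ends - lengths + 1L, ends)
}

#' Generate a synthetic miRNA reference (hairpins + mature coordinates)
#'
#' Each hairpin is a random DNA sequence embedding one mature miRNA at
#' recorded coordinates, with flanks long enough that every 5'/3' shift
#' window exists. Mature 16-nt prefixes are guaranteed pairwise distinct
#' (bounded rejection sampling) so exact-lookup quantification is
#' unambiguous at the canonical end.
#'
#' @param n_mirnas number of hairpins.
#' @param mature_len_range inclusive range of mature lengths (nt).
#' @param flank flank length on each side of the mature within the hairpin.
#' @param seed optional RNG seed.
#' @param max_tries retries per mature before an ambiguous-reference error.
#' @return a `mirna_reference`: list with `hairpins` (named character) and
#'   `matures` (data.frame: mature, hairpin, mirna_gene, start, end; 1-based
#'   inclusive coordinates on the hairpin).
#' @export
make_reference <- function(n_mirnas, mature_len_range = c(20L, 24L),
                           flank = 12L, seed = NULL, max_tries = 1000L) {
  stopifnot(n_mirnas >= 1L, flank >= 5L)
  if (!is.null(seed)) set.seed(seed)
  prefixes <- character(0)
  hairpins <- character(n_mirnas)
  rows <- vector("list", n_mirnas)
  for (i in seq_len(n_mirnas)) {
    len <- sample(seq(mature_len_range[1], mature_len_range[2]), 1L)
    mature_seq <- NULL
    for (try in seq_len(max_tries)) {
      cand <- random_dna(len)
      if (!(substr(cand, 1L, 16L) %in% prefixes)) { mature_seq <- cand; break }
    }
    if (is.null(mature_seq))
      stop("ambiguous reference: could not draw a unique 16-nt mature prefix")
    prefixes <- c(prefixes, substr(mature_seq, 1L, 16L))
    arm <- if (i %% 2L == 0L) "3p" else "5p"
    mature <- sprintf("miR-S%d-%s", i, arm)
    gene <- sprintf("mir-s%d", i)
    hp_name <- sprintf("hp-s%d", i)
    hairpins[i] <- paste0(random_dna(flank), mature_seq, random_dna(flank))
    names(hairpins)[i] <- hp_name
    rows[[i]] <- data.frame(mature = mature, hairpin = hp_name,
                            mirna_gene = gene, start = flank + 1L,
                            end = flank + len, stringsAsFactors = FALSE)
  }
  ref <- list(hairpins = hairpins, matures = do.call(rbind, rows))
  class(ref) <- "mirna_reference"
  ref
}

#' Enumerate the isoforms of a reference
#'
#' Canonical first, then shifts +1, -1, +2, -2, ... up to
#' `n_isoforms_per_mirna` per mature. Sequences are hairpin substrings with
#' the 5' end moved by the shift (3' end canonical).
#'
#' @param reference a `mirna_reference`.
#' @param n_isoforms isoforms per mature.
#' @return data.frame: label, mature, mirna_gene, shift5, seq (DNA).
#' @export
isoform_table <- function(reference, n_isoforms = 3L) {
  shifts <- c(0L, 1L, -1L, 2L, -2L, 3L, -3L)[seq_len(n_isoforms)]
  out <- lapply(seq_len(nrow(reference$matures)), function(i) {
    m <- reference$matures[i, ]
    hp <- reference$hairpins[[m$hairpin]]
    data.frame(
      label = isomir_label(m$mature, shifts),
      mature = m$mature, mirna_gene = m$mirna_gene, shift5 = shifts,
      seq = vapply(shifts, function(s) {
        a <- m$start + s
        if (a < 1L || a > m$end)
          stop("isoform shift outside hairpin bounds for ", m$mature)
        substr(hp, a, m$end)
      }, character(1)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Plant the ground truth for a scenario
#'
#' Fills in any planted maps the config leaves `NULL`: a default isomiR
#' program (a minority of isomiRs up/down at `isomir_effect_size`, including
#' one +1 and one -1 5'-isoform to exercise seed shifting), repressed target
#' genes (log2 FC opposite in sign to their isomiR), independently regulated
#' genes, and a TF layer (true regulators + decoys that fail exactly one
#' funnel stage each).
#'
#' @param reference a `mirna_reference`.
#' @param config a `sim_config`.
#' @return a `truth` list: true_isomir_fc, true_gene_fc, true_targets,
#'   true_tf_regulators, decoy_tfs, gene_ids, tf_gene_ids, true_enriched_set.
#' @export
plan_truth <- function(reference, config) {
  iso <- isoform_table(reference, config$n_isoforms_per_mirna)
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  tf_ids <- sprintf("TFS%02d", seq_len(config$n_tfs + config$n_decoy_tfs))

  iso_fc <- config$planted_isomir_effects
  if (is.null(iso_fc)) {
    n_up <- config$n_up_isomirs
    n_dn <- config$n_down_isomirs
    if (n_up + n_dn > config$n_mirnas)
      stop("more planted isomiRs than miRNAs")
    matures <- unique(iso$mature)
    picked <- sample(matures, n_up + n_dn)
    lab <- character(0)
    for (k in seq_along(picked)) {
      # mostly canonical isoforms; one +1 among ups, one -1 among downs,
      # when the isoform window allows it
      shift <- 0L
      if (k == n_up && config$n_isoforms_per_mirna >= 2L) shift <- 1L
      if (k == n_up + n_dn && n_dn > 0L &&
          config$n_isoforms_per_mirna >= 3L) shift <- -1L
      lab <- c(lab, isomir_label(picked[k], shift))
    }
    iso_fc <- setNames(
      c(rep(config$isomir_effect_size, n_up),
        rep(-config$isomir_effect_size, n_dn)), lab)
  }
  missing <- setdiff(names(iso_fc), iso$label)
  if (length(missing))
    stop("planted isomiR not generatable from reference: ",
         paste(missing, collapse = ", "))

  active <- names(iso_fc)[iso_fc != 0]
  n_targets <- max(1L, round(config$target_fraction * config$n_genes))
  pool <- sample(gene_ids)
  true_targets <- list()
  used <- 0L
  for (lab in active) {
    take <- pool[seq(used + 1L, min(used + n_targets, length(pool)))]
    used <- used + length(take)
    true_targets[[lab]] <- take
  }

  gene_fc <- config$planted_gene_effects
  if (is.null(gene_fc)) {
    gene_fc <- setNames(numeric(0), character(0))
    for (lab in active) {
      g <- true_targets[[lab]]
      gene_fc[g] <- -sign(iso_fc[[lab]]) * 1
    }
    free <- setdiff(gene_ids, names(gene_fc))
    n_extra <- min(config$n_extra_de_genes, length(free))
    extra <- sample(free, n_extra)
    gene_fc[extra] <- sample(c(-1, 1), n_extra, TRUE) *
      runif(n_extra, 1, 2.2)
  }

  # TF layer: true TFs regulate strong planted DE genes and the active
  # miRNA genes; decoys fail exactly one funnel stage each.
  strong <- names(gene_fc)[abs(gene_fc) >= 1]
  active_mirna_genes <- unique(
    iso$mirna_gene[iso$label %in% active])
  tf_regulon_size <- 12L
  true_tfs <- tf_ids[seq_len(config$n_tfs)]
  decoy_ids <- setdiff(tf_ids, true_tfs)
  half <- ceiling(length(decoy_ids) / 2)
  decoy_not_de <- decoy_ids[seq_len(half)]
  decoy_no_edge <- decoy_ids[-seq_len(half)]

  tf_regulators <- lapply(true_tfs, function(tf) list(
    genes = sample(strong, min(tf_regulon_size, length(strong))),
    mirna_genes = active_mirna_genes))
  names(tf_regulators) <- true_tfs
  decoy_regulons <- lapply(decoy_ids, function(tf)
    sample(strong, min(tf_regulon_size, length(strong))))
  names(decoy_regulons) <- decoy_ids

  tf_fc <- setNames(rep(0, length(tf_ids)), tf_ids)
  tf_fc[true_tfs] <- sample(c(-1, 1), length(true_tfs), TRUE) * 1.5
  tf_fc[decoy_no_edge] <- sample(c(-1, 1), length(decoy_no_edge), TRUE) * 1.5
  gene_fc <- c(gene_fc, tf_fc[tf_fc != 0])

  # one gene set enriched in the repressed targets of up-isomiRs
  dn_targets <- unlist(true_targets[names(true_targets) %in%
                                      names(iso_fc)[iso_fc > 0]],
                       use.names = FALSE)
  enriched_set <- if (length(dn_targets))
    sample(dn_targets, min(40L, length(dn_targets))) else character(0)

  truth <- list(
    true_isomir_fc = iso_fc,
    true_gene_fc = gene_fc,
    true_targets = true_targets,
    true_tf_regulators = tf_regulators,
    decoy_tfs = list(not_de = decoy_not_de, no_mirna_edge = decoy_no_edge),
    decoy_regulons = decoy_regulons,
    gene_ids = gene_ids,
    tf_gene_ids = tf_ids,
    active_mirna_genes = active_mirna_genes,
    true_enriched_set = enriched_set
  )
  class(truth) <- "sim_truth"
  truth
}

#' Simulate small-RNA FASTQ reads per sample
#'
#' Per-isoform baseline proportions (log-normal miRNA weights times a
#' decaying isoform profile, canonical dominant) are scaled in group 2 by
#' the planted log2 fold changes and renormalized. Each read is the isoform
#' sequence followed by the 3' adapter, padded with random bases or
#' truncated to the read length; per-sample isoform tallies are multinomial
#' at the configured depth and are returned as the planted truth.
#'
#' @param reference a `mirna_reference`.
#' @param config a `sim_config`.
#' @param truth a `sim_truth` (for the planted isomiR effects).
#' @param out_dir directory receiving one FASTQ per sample.
#' @param adapter 3' adapter sequence appended to every read.
#' @param read_len total read length (nt).
#' @return list: fastq (named paths), tallies (isoform x sample integer
#'   matrix), proportions (per-group expected proportions), groups, samples.
#' @export
simulate_smallrna_reads <- function(reference, config, truth, out_dir,
                                    adapter = "AGATCGGAAGAGCACACGTCT",
                                    read_len = 50L) {
  iso <- isoform_table(reference, config$n_isoforms_per_mirna)
  n1 <- config$n_samples_per_group[1]
  n2 <- config$n_samples_per_group[2]
  samples <- c(sprintf("ctrl%02d", seq_len(n1)), sprintf("trt%02d", seq_len(n2)))
  groups <- setNames(rep(c("group1", "group2"), c(n1, n2)), samples)

  mirna_w <- setNames(rlnorm(config$n_mirnas, 0, 1.2),
                      unique(iso$mature))
  iso_w <- c(1, 0.25, 0.12, 0.05, 0.03, 0.02, 0.01)[
    match(iso$shift5, c(0L, 1L, -1L, 2L, -2L, 3L, -3L))]
  base <- mirna_w[iso$mature] * iso_w
  p1 <- base / sum(base)
  scale2 <- rep(1, nrow(iso))
  idx <- match(names(truth$true_isomir_fc), iso$label)
  scale2[idx] <- 2^truth$true_isomir_fc
  p2 <- base * scale2 / sum(base * scale2)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tallies <- matrix(0L, nrow(iso), length(samples),
                    dimnames = list(iso$label, samples))
  fastq <- setNames(character(length(samples)), samples)
  for (j in seq_along(samples)) {
    p <- if (groups[j] == "group1") p1 else p2
    n <- rmultinom(1, config$depth_smallrna, p)[, 1]
    tallies[, j] <- n
    core <- paste0(iso$seq, adapter)
    reads <- rep(core, n)
    pad_n <- pmax(0L, read_len - nchar(reads))
    reads <- substr(paste0(reads, random_dna_vec(pad_n)), 1L, read_len)
    fastq[j] <- file.path(out_dir, paste0(samples[j], ".fastq"))
    write_fastq(reads, fastq[j],
                ids = paste0(samples[j], ":", seq_along(reads)))
  }
  list(fastq = fastq, tallies = tallies,
       proportions = list(group1 = setNames(p1, iso$label),
                          group2 = setNames(p2, iso$label)),
       groups = groups, samples = samples)
}

nb_draw <- function(n, mu, dispersion) {
  if (any(mu <= 0)) stop("non-positive negative-binomial mean")
  if (dispersion <= 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate the gene count matrix and gene lengths
#'
#' Negative-binomial counts (var = mu + alpha mu^2) with log-normal baseline
#' means; group-2 means scaled by 2^(planted log2 FC). Planted target genes
#' of active isomiRs carry fold changes opposite in sign to their isomiR
#' (repression emulation) — that assignment lives in the truth object.
#'
#' @param config a `sim_config`.
#' @param truth a `sim_truth`; `truth$true_gene_fc` drives group-2 means.
#' @return list: counts (gene x sample integer matrix), lengths (named),
#'   groups, samples.
#' @export
simulate_gene_counts <- function(config, truth) {
  gene_ids <- c(truth$gene_ids, truth$tf_gene_ids)
  n1 <- config$n_samples_per_group[1]
  n2 <- config$n_samples_per_group[2]
  samples <- c(sprintf("ctrl%02d", seq_len(n1)), sprintf("trt%02d", seq_len(n2)))
  groups <- setNames(rep(c("group1", "group2"), c(n1, n2)), samples)
  mu <- rlnorm(length(gene_ids), config$gene_mean_log, config$gene_mean_sdlog)
  names(mu) <- gene_ids
  lfc <- setNames(rep(0, length(gene_ids)), gene_ids)
  lfc[names(truth$true_gene_fc)] <- truth$true_gene_fc
  counts <- matrix(0L, length(gene_ids), length(samples),
                   dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    m <- if (groups[j] == "group1") mu else mu * 2^lfc
    counts[, j] <- nb_draw(length(m), m, config$nb_dispersion)
  }
  lengths <- setNames(
    sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
           length(gene_ids), replace = TRUE), gene_ids)
  list(counts = counts, lengths = lengths, groups = groups, samples = samples)
}

count_overlapping <- function(seq, site) {
  # lookahead regex so overlapping occurrences all count
  m <- gregexpr(paste0("(?=", site, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

#' Generate 3'UTRs and all relation tables (targets, gene sets, TF edges)
#'
#' Every planted target's UTR receives at least one exact seed site (the
#' DNA reverse complement of the isoform's 6-mer seed); UTRs of all other
#' genes are rejection-sampled to contain no site of any active isomiR.
#' Validated/predicted target tables, a GMT gene-set collection, TF->gene
#' and TF->miRNA edge tables, and the mature->miRNA-gene map list exactly
#' the planted relations plus Bernoulli-sampled decoy rows.
#'
#' @param reference a `mirna_reference`.
#' @param config a `sim_config`.
#' @param truth a `sim_truth`.
#' @param out_dir directory for the emitted files.
#' @return list of paths: utr_fasta, validated_tsv, predicted_tsv, gmt,
#'   tf_gene_tsv, tf_mirna_tsv, mature_map_tsv; plus `utrs` in memory.
#' @export
make_utrs_and_tables <- function(reference, config, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  iso <- isoform_table(reference, config$n_isoforms_per_mirna)
  gene_ids <- c(truth$gene_ids, truth$tf_gene_ids)
  active <- names(truth$true_isomir_fc)[truth$true_isomir_fc != 0]
  active_sites <- setNames(vapply(active, function(lab) {
    s <- iso$seq[iso$label == lab]
    revcomp_dna(substr(s, 2L, 7L))
  }, character(1)), active)

  target_of <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
  for (lab in names(truth$true_targets))
    target_of[truth$true_targets[[lab]]] <- lab

  min_len <- config$utr_len_range[1]
  if (min_len < 12L) stop("UTR too short to host a seed site")
  utrs <- setNames(character(length(gene_ids)), gene_ids)
  for (g in gene_ids) {
    len <- sample(seq(config$utr_len_range[1], config$utr_len_range[2]), 1L)
    repeat {
      u <- random_dna(len)
      if (all(vapply(active_sites, function(s)
        count_overlapping(u, s) == 0L, logical(1)))) break
    }
    lab <- target_of[[g]]
    if (!is.na(lab)) {
      site <- active_sites[[lab]]
      others <- active_sites[names(active_sites) != lab &
                               active_sites != site]
      repeat {
        u2 <- u
        for (k in seq_len(sample(1:2, 1L))) {
          pos <- sample(len - nchar(site) + 1L, 1L)
          substr(u2, pos, pos + nchar(site) - 1L) <- site
        }
        ok <- count_overlapping(u2, site) >= 1L &&
          all(vapply(others, function(s)
            count_overlapping(u2, s) == 0L, logical(1)))
        if (ok) { u <- u2; break }
      }
    }
    utrs[g] <- u
  }

  # target tables: planted relations + decoy rows pointing at siteless genes
  canonical <- active[parse_isomir_label(active)$shift5 == 0L]
  noncanon <- setdiff(active, canonical)
  make_rows <- function(labels) {
    rows <- list()
    for (lab in labels) {
      tg <- truth$true_targets[[lab]]
      rows[[lab]] <- data.frame(mirna_label = lab, gene_id = tg,
                                stringsAsFactors = FALSE)
      n_dec <- rbinom(1L, length(tg), config$decoy_rate)
      if (n_dec > 0L) {
        pool <- setdiff(gene_ids, unlist(truth$true_targets))
        dec <- sample(pool, min(n_dec, length(pool)))
        rows[[paste0(lab, ".decoy")]] <- data.frame(
          mirna_label = lab, gene_id = dec, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(mirna_label = character(0), gene_id = character(0))
  }
  validated <- make_rows(canonical)
  predicted <- make_rows(noncanon)
  rownames(validated) <- rownames(predicted) <- NULL

  # gene sets: one planted-enriched set + random sets
  sets <- list(HALLMARK_PLANTED = truth$true_enriched_set)
  for (k in seq_len(9L))
    sets[[sprintf("HALLMARK_RANDOM_%02d", k)]] <- sample(gene_ids, 50L)

  # TF edge tables
  tf_gene <- do.call(rbind, c(
    lapply(names(truth$true_tf_regulators), function(tf)
      data.frame(tf = tf, gene_id = truth$true_tf_regulators[[tf]]$genes,
                 stringsAsFactors = FALSE)),
    lapply(names(truth$decoy_regulons), function(tf)
      data.frame(tf = tf, gene_id = truth$decoy_regulons[[tf]],
                 stringsAsFactors = FALSE))))
  n_noise <- rbinom(1L, nrow(tf_gene), config$decoy_rate)
  if (n_noise > 0L) {
    tf_gene <- rbind(tf_gene, data.frame(
      tf = sample(truth$tf_gene_ids, n_noise, TRUE),
      gene_id = sample(truth$gene_ids, n_noise, TRUE)))
  }
  tf_gene <- unique(tf_gene)

  tf_mirna <- do.call(rbind, lapply(names(truth$true_tf_regulators),
    function(tf) data.frame(
      tf = tf, mirna_gene = truth$true_tf_regulators[[tf]]$mirna_genes,
      stringsAsFactors = FALSE)))
  # decoy TF->miRNA edges only for TFs that are not DE (so the funnel's
  # exactness on truth is preserved by construction)
  extra <- truth$decoy_tfs$not_de
  if (length(extra) && length(truth$active_mirna_genes)) {
    n_dec <- rbinom(1L, length(extra), config$decoy_rate)
    if (n_dec > 0L) {
      tf_mirna <- rbind(tf_mirna, data.frame(
        tf = sample(extra, n_dec, TRUE),
        mirna_gene = sample(truth$active_mirna_genes, n_dec, TRUE)))
    }
  }
  tf_mirna <- unique(tf_mirna)

  mature_map <- unique(reference$matures[, c("mature", "mirna_gene")])

  paths <- list(
    utr_fasta = file.path(out_dir, "utrs.fasta"),
    validated_tsv = file.path(out_dir, "validated_targets.tsv"),
    predicted_tsv = file.path(out_dir, "predicted_targets.tsv"),
    gmt = file.path(out_dir, "gene_sets.gmt"),
    tf_gene_tsv = file.path(out_dir, "tf_gene_edges.tsv"),
    tf_mirna_tsv = file.path(out_dir, "tf_mirna_edges.tsv"),
    mature_map_tsv = file.path(out_dir, "mature_to_gene.tsv")
  )
  write_fasta(utrs, paths$utr_fasta)
  write_tsv_table(validated, paths$validated_tsv)
  write_tsv_table(predicted, paths$predicted_tsv)
  write_gmt(sets, paths$gmt)
  write_tsv_table(tf_gene, paths$tf_gene_tsv)
  write_tsv_table(tf_mirna, paths$tf_mirna_tsv)
  write_tsv_table(mature_map, paths$mature_map_tsv)
  c(paths, list(utrs = utrs, gene_sets = sets))
}

#' Write a reference to FASTA + mature-coordinate TSV
#' @param reference a `mirna_reference`.
#' @param out_dir output directory.
#' @return list of paths: hairpin_fasta, mature_tsv.
#' @export
write_reference <- function(reference, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(hairpin_fasta = file.path(out_dir, "hairpins.fasta"),
                mature_tsv = file.path(out_dir, "matures.tsv"))
  write_fasta(reference$hairpins, paths$hairpin_fasta)
  write_tsv_table(reference$matures, paths$mature_tsv)
  paths
}

#' Read a reference from FASTA + mature-coordinate TSV
#' @param hairpin_fasta,mature_tsv paths as written by `write_reference`.
#' @return a `mirna_reference`.
#' @export
read_reference <- function(hairpin_fasta, mature_tsv) {
  ref <- list(hairpins = read_fasta(hairpin_fasta),
              matures = read_tsv_table(mature_tsv))
  with(ref$matures, stopifnot(
    start >= 1L, end >= start, end <= nchar(ref$hairpins[hairpin])))
  class(ref) <- "mirna_reference"
  ref
}

#' Generate a complete synthetic scenario
#'
#' Runs every generator stage under one seed and writes all pipeline inputs
#' plus a machine-readable truth JSON into `out_dir`.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory.
#' @return list: config, reference, truth, reads, genes, tables, paths.
#' @export
simulate_scenario <- function(config, out_dir) {
  set.seed(config$rng_seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reference <- make_reference(config$n_mirnas, config$mature_len_range)
  truth <- plan_truth(reference, config)
  reads <- simulate_smallrna_reads(reference, config, truth,
                                   file.path(out_dir, "reads"))
  genes <- simulate_gene_counts(config, truth)
  tables <- make_utrs_and_tables(reference, config, truth, out_dir)
  ref_paths <- write_reference(reference, out_dir)

  paths <- c(ref_paths, tables[!names(tables) %in% c("utrs", "gene_sets")])
  paths$gene_counts_tsv <- file.path(out_dir, "gene_counts.tsv")
  paths$gene_lengths_tsv <- file.path(out_dir, "gene_lengths.tsv")
  paths$samples_tsv <- file.path(out_dir, "samples.tsv")
  paths$truth_json <- file.path(out_dir, "truth.json")
  write_count_matrix(genes$counts, paths$gene_counts_tsv, id_col = "gene_id")
  write_tsv_table(data.frame(gene_id = names(genes$lengths),
                             length = unname(genes$lengths)),
                  paths$gene_lengths_tsv)
  write_tsv_table(data.frame(sample = names(reads$groups),
                             group = unname(reads$groups)),
                  paths$samples_tsv)
  jsonlite::write_json(truth_to_json(truth), paths$truth_json,
                       auto_unbox = TRUE, digits = NA)
  list(config = config, reference = reference, truth = truth, reads = reads,
       genes = genes, tables = tables, paths = paths)
}

truth_to_json <- function(truth) {
  list(
    true_isomir_fc = as.list(truth$true_isomir_fc),
    true_gene_fc = as.list(truth$true_gene_fc),
    true_targets = truth$true_targets,
    true_tf_regulators = truth$true_tf_regulators,
    decoy_tfs = truth$decoy_tfs,
    active_mirna_genes = truth$active_mirna_genes,
    true_enriched_set = truth$true_enriched_set
  )
}
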