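# Generator correctness: reference construction, read simulation, count
# simulation moments, and UTR/table planting, against construction oracles.

test_that("reference embeds matures at recorded coordinates with distinct prefixes", {
  ref <- make_reference(50, seed = 3L)
  m <- ref$matures
  for (i in seq_len(nrow(m))) {
    hp <- ref$hairpins[[m$hairpin[i]]]
    mat <- substr(hp, m$start[i], m$end[i])
    expect_gte(nchar(mat), 20L)
    expect_lte(nchar(mat), 24L)
    expect_gte(nchar(hp), nchar(mat) + 10L)
  }
  expect_equal(anyDuplicated(m$mature), 0L)
  # exhaustive pairwise comparison of 16-nt prefixes
  pre <- vapply(seq_len(nrow(m)), function(i)
    substr(ref$hairpins[[m$hairpin[i]]], m$start[i], m$start[i] + 15L),
    character(1))
  for (i in seq_len(49)) for (j in seq(i + 1, 50))
    expect_false(pre[i] == pre[j])
})

test_that("identical config and seed give byte-identical generator outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 5L)
  simulate_scenario(cfg, d1)
  simulate_scenario(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("reads are isoform + adapter + padding at fixed length, depth conserved", {
  d <- withr::local_tempdir()
  sc <- small_scenario(seed = 21L, dir = d)
  adapter <- "AGATCGGAAGAGCACACGTCT"
  iso <- isoform_table(sc$reference, sc$config$n_isoforms_per_mirna)
  for (s in sc$reads$samples[c(1, 9)]) {
    reads <- read_fastq_seqs(sc$reads$fastq[[s]])
    expect_equal(length(reads), sc$config$depth_smallrna)  # conservation
    expect_true(all(nchar(reads) == 50L))
    expect_equal(unname(colSums(sc$reads$tallies)[s]),
                 sc$config$depth_smallrna)
    # spot-check structure on the first 50 reads
    for (r in head(reads, 50)) {
      hit <- iso$seq[startsWith(r, paste0(iso$seq, adapter))]
      expect_equal(length(hit), 1L)
    }
  }
})

test_that("a degenerate single-isoform profile yields only that isoform's reads", {
  d <- withr::local_tempdir()
  set.seed(1)
  ref <- make_reference(1, seed = 2L)
  cfg <- sim_config(n_mirnas = 1, n_isoforms_per_mirna = 1,
                    n_samples_per_group = c(2L, 2L), depth_smallrna = 100,
                    rng_seed = 1L)
  truth <- list(true_isomir_fc = setNames(numeric(0), character(0)))
  out <- simulate_smallrna_reads(ref, cfg, truth, d)
  mature <- with(ref$matures, substr(ref$hairpins[[hairpin]], start, end))
  reads <- read_fastq_seqs(out$fastq[[1]])
  expect_equal(length(reads), 100L)
  expect_true(all(startsWith(reads, mature)))
})

test_that("empirical read proportions sit within 3 binomial SEs of truth", {
  d <- withr::local_tempdir()
  set.seed(8)
  ref <- make_reference(3, seed = 8L)
  cfg <- sim_config(n_mirnas = 3, n_isoforms_per_mirna = 1,
                    n_samples_per_group = c(1L, 1L), depth_smallrna = 1e5,
                    rng_seed = 8L)
  truth <- list(true_isomir_fc = setNames(numeric(0), character(0)))
  out <- simulate_smallrna_reads(ref, cfg, truth, d)
  p <- out$proportions$group1
  emp <- out$tallies[, 1] / sum(out$tallies[, 1])
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(emp - p) <= 3 * se + 1e-12))
})

test_that("gene counts match the negative-binomial moments and planted ratios", {
  set.seed(4)
  # Poisson limit: dispersion -> 0 at mean 100
  x <- isoshift:::nb_draw(1e4, 100, 1e-14)
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
  # planted log2 FC = -1 halves the group-2 mean
  cfg <- sim_config(n_genes = 1, n_samples_per_group = c(200L, 200L),
                    nb_dispersion = 0.05,
                    planted_gene_effects = c(g0001 = -1),
                    planted_isomir_effects = setNames(numeric(0), character(0)),
                    n_tfs = 1L, n_decoy_tfs = 1L, rng_seed = 4L)
  ref <- make_reference(2, seed = 4L)
  truth <- plan_truth(ref, cfg)
  g <- simulate_gene_counts(cfg, truth)
  m1 <- mean(g$counts["g0001", g$groups == "group1"])
  m2 <- mean(g$counts["g0001", g$groups == "group2"])
  expect_lt(abs(m2 / m1 - 0.5), 0.12)
})

test_that("with no planted effects, log-scale t-statistics are near standard normal", {
  set.seed(12)
  cfg <- sim_config(n_genes = 1500, n_samples_per_group = c(7L, 8L),
                    nb_dispersion = 0.05,
                    planted_gene_effects = setNames(numeric(0), character(0)),
                    planted_isomir_effects = setNames(numeric(0), character(0)),
                    n_tfs = 1L, n_decoy_tfs = 1L, rng_seed = 12L)
  ref <- make_reference(2, seed = 12L)
  truth <- plan_truth(ref, cfg)
  g <- simulate_gene_counts(cfg, truth)
  lx <- log(g$counts[seq_len(1500), ] + 1)
  tt <- apply(lx, 1, function(v)
    t.test(v[g$groups == "group2"], v[g$groups == "group1"])$statistic)
  expect_lt(abs(mean(tt)), 0.1)
  expect_lt(abs(sd(tt) - 1), 0.15)
})

test_that("planted target UTRs carry the exact reverse-complement seed site", {
  sc <- small_scenario(seed = 31L)
  iso <- isoform_table(sc$reference, 3L)
  utrs <- sc$tables$utrs
  active <- names(sc$truth$true_isomir_fc)
  for (lab in active) {
    seq <- iso$seq[iso$label == lab]
    site <- oracle_revcomp(substr(seq, 2, 7))     # independent revcomp
    tg <- sc$truth$true_targets[[lab]]
    for (g in tg)
      expect_gte(oracle_overlap_count(utrs[[g]], site), 1L)
    non <- setdiff(names(utrs), unlist(sc$truth$true_targets))
    for (g in head(non, 40))
      expect_equal(oracle_overlap_count(utrs[[g]], site), 0L)
  }
})

test_that("decoy rate 0 reduces the relation tables to exactly the planted truth", {
  d <- withr::local_tempdir()
  cfg2 <- small_sim_config(seed = 41L, decoy_rate = 0)
  sc <- simulate_scenario(cfg2, d)
  pred <- read_tsv_table(sc$paths$predicted_tsv)
  noncanon <- names(sc$truth$true_isomir_fc)[
    parse_isomir_label(names(sc$truth$true_isomir_fc))$shift5 != 0]
  expect_setequal(unique(pred$mirna_label), noncanon)
  for (lab in noncanon)
    expect_setequal(pred$gene_id[pred$mirna_label == lab],
                    sc$truth$true_targets[[lab]])
  # and the TF->gene table reduces to exactly the truth + decoy regulons
  tfg <- read_tsv_table(sc$paths$tf_gene_tsv)
  truth_edges <- do.call(rbind, c(
    lapply(names(sc$truth$true_tf_regulators), function(tf)
      data.frame(tf = tf, gene_id = sc$truth$true_tf_regulators[[tf]]$genes)),
    lapply(names(sc$truth$decoy_regulons), function(tf)
      data.frame(tf = tf, gene_id = sc$truth$decoy_regulons[[tf]]))))
  expect_setequal(paste(tfg$tf, tfg$gene_id),
                  paste(truth_edges$tf, truth_edges$gene_id))
})

test_that("config invariants reject sub-2-fold planted effects", {
  expect_error(sim_config(planted_gene_effects = c(g1 = 0.5)),
               "2-fold")
  expect_error(sim_config(nb_dispersion = 0))
  expect_error(sim_config(isomir_effect_size = 0.3), ">= 1")
})
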