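# Independent oracles used across the suite. Each recomputes a quantity by
# the most literal method available (brute force, enumeration, a different
# library) and never reuses the package's own code path.

# naive isomiR annotation: per read, loop every mature and every shift pair
# within the windows, slice the hairpin afresh and compare
oracle_annotate <- function(read, reference, window5 = 3L, window3 = 5L) {
  hits <- list()
  m <- reference$matures
  for (i in seq_len(nrow(m))) {
    hp <- reference$hairpins[[m$hairpin[i]]]
    for (s5 in seq(-window5, window5)) {
      a <- m$start[i] + s5
      b <- a + nchar(read) - 1L          # end forced by the read length
      s3 <- b - m$end[i]
      if (a < 1L || b > nchar(hp) || b < a) next
      if (s3 < -window3 || s3 > window3) next
      if (substr(hp, a, b) == read)
        hits[[length(hits) + 1L]] <- c(mature = m$mature[i],
                                       shift5 = s5, shift3 = s3)
    }
  }
  hits
}

# Benjamini-Hochberg by its step-up definition: sort ascending, p(i)*n/i,
# then running minimum from the largest rank down
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in seq(n - 1L, 1L)) if (n > 1L) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# one-sided (overrepresentation) hypergeometric p by explicit tail summation
oracle_hyper_p <- function(td, tn, nd, nn) {
  n_t <- td + tn; n_d <- td + nd; n_tot <- td + tn + nd + nn
  xs <- seq(td, min(n_t, n_d))
  sum(choose(n_t, xs) * choose(n_tot - n_t, n_d - xs) / choose(n_tot, n_d))
}

# two-sample KS distance by a double loop over pooled evaluation points
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  d <- 0
  for (t in pts) {
    fx <- sum(x <= t) / length(x)
    fy <- sum(y <= t) / length(y)
    d <- max(d, abs(fx - fy))
  }
  d
}

# overlapping substring count via lookahead regex
oracle_overlap_count <- function(seq, site) {
  m <- gregexpr(paste0("(?=", site, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

# reverse complement through Biostrings
oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# random DNA for fixtures (independent of the generator's internals)
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# a small complete scenario shared by the heavier tests
small_sim_config <- function(seed = 11L, ...) {
  sim_config(n_mirnas = 8L, n_isoforms_per_mirna = 3L, n_genes = 600L,
             n_samples_per_group = c(7L, 8L), depth_smallrna = 1e4,
             n_up_isomirs = 3L, n_down_isomirs = 1L,
             n_extra_de_genes = 60L, n_tfs = 2L, n_decoy_tfs = 4L,
             target_fraction = 0.05, rng_seed = seed, ...)
}

small_scenario <- function(seed = 11L, dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  simulate_scenario(small_sim_config(seed), dir)
}
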