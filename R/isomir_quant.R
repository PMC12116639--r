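# Adapter trimming and exact-lookup isomiR quantification. A read is
# annotated by exact match against every hairpin window reachable from a
# mature's recorded ends within the 5'/3' shift windows; counts are keyed by
# the "name|shift" convention (5' shift only; 3' variants collapse into the
# same label and are retained in a detailed table).

#' Trim the 3' adapter from small-RNA reads
#'
#' Removes everything from the leftmost full occurrence of the adapter, or
#' from the longest adapter prefix (>= `min_overlap` nt) anchored at the
#' read's 3' end. Reads with no adapter evidence are returned whole; reads
#' shorter than `min_len` after trimming are rejected (`NA`).
#'
#' @param reads character vector of read sequences (DNA; U is converted to T).
#' @param adapter adapter sequence (default the standard small-RNA 3' adapter).
#' @param min_overlap minimum terminal adapter-prefix length (>= 3).
#' @param min_len minimum trimmed length to keep a read.
#' @return character vector, `NA` where rejected, with attribute `status`
#'   (one of trimmed/untrimmed/too_short per read).
#' @export
trim_adapter <- function(reads, adapter = "AGATCGGAAGAGCACACGTCT",
                         min_overlap = 3L, min_len = 16L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (min_overlap < 3L) stop("min_overlap must be >= 3")
  if (any(!nzchar(reads))) stop("empty read")
  reads <- rna_to_dna(reads)
  out <- reads
  status <- rep("untrimmed", length(reads))

  hit <- regexpr(adapter, reads, fixed = TRUE)
  full <- which(hit > 0)
  out[full] <- substr(reads[full], 1L, hit[full] - 1L)
  status[full] <- "trimmed"

  # terminal adapter-prefix matches, longest first (leftmost cut)
  rest <- which(hit < 0)
  if (length(rest)) {
    for (k in seq(min(nchar(adapter) - 1L, max(nchar(reads[rest]))),
                  min_overlap)) {
      pre <- substr(adapter, 1L, k)
      len <- nchar(reads[rest])
      tail_k <- substr(reads[rest], len - k + 1L, len)
      m <- which(len >= k & tail_k == pre)
      if (length(m)) {
        out[rest[m]] <- substr(reads[rest[m]], 1L, len[m] - k)
        status[rest[m]] <- "trimmed"
        rest <- rest[-m]
        if (!length(rest)) break
      }
    }
  }
  short <- nchar(out) < min_len
  out[short] <- NA_character_
  status[short] <- "too_short"
  attr(out, "status") <- status
  out
}

#' Build the exact-lookup isomiR index
#'
#' Maps every hairpin substring reachable as (mature start + shift5 ...
#' mature end + shift3) within the windows to its isomiR identity. Identical
#' substrings arising from different mature loci map to all of them. Windows
#' running outside a hairpin are clipped (those shifts are skipped).
#'
#' @param reference a `mirna_reference`.
#' @param window5 maximum |5' shift| (default 3).
#' @param window3 maximum |3' shift| (default 5).
#' @return an `isomir_index`: list(entries, map, window5, window3) where
#'   `entries` is a data.frame (seq, mature, shift5, shift3) and `map`
#'   indexes entry rows by sequence.
#' @export
build_lookup <- function(reference, window5 = 3L, window3 = 5L) {
  stopifnot(window5 >= 0L, window3 >= 0L)
  m <- reference$matures
  rows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    hp <- reference$hairpins[[m$hairpin[i]]]
    grid <- expand.grid(shift5 = seq(-window5, window5),
                        shift3 = seq(-window3, window3))
    a <- m$start[i] + grid$shift5
    b <- m$end[i] + grid$shift3
    keep <- a >= 1L & b <= nchar(hp) & b >= a
    grid <- grid[keep, , drop = FALSE]
    rows[[i]] <- data.frame(
      seq = substring(hp, a[keep], b[keep]),
      mature = m$mature[i], shift5 = grid$shift5, shift3 = grid$shift3,
      stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, rows)
  idx <- list(entries = entries,
              map = split(seq_len(nrow(entries)), entries$seq),
              window5 = window5, window3 = window3)
  class(idx) <- "isomir_index"
  idx
}

#' Quantify isomiRs from trimmed reads
#'
#' Each mapped read contributes total weight 1, split 1/k across the k
#' matching mature loci. Counts are aggregated by "mature|shift5" label
#' (3' variants collapsed); the per-(shift5, shift3) breakdown is retained
#' in a detailed table. Unmapped reads are counted, never errors.
#'
#' @param reads_by_sample named list: sample -> character vector of trimmed
#'   read sequences (NAs are dropped).
#' @param index an `isomir_index`.
#' @return list: counts (isomiR x sample matrix, possibly fractional),
#'   detailed (data.frame label/mature/shift5/shift3/sample/count),
#'   unmapped (per-sample count), total (per-sample reads quantified).
#' @export
quantify <- function(reads_by_sample, index) {
  stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
  samples <- names(reads_by_sample)
  detail <- list()
  unmapped <- setNames(numeric(length(samples)), samples)
  total <- setNames(numeric(length(samples)), samples)
  for (s in samples) {
    seqs <- reads_by_sample[[s]]
    seqs <- rna_to_dna(seqs[!is.na(seqs)])
    total[s] <- length(seqs)
    tab <- table(seqs)
    rows_per_seq <- index$map[names(tab)]
    found <- !vapply(rows_per_seq, is.null, logical(1))
    unmapped[s] <- sum(tab[!found])
    if (any(found)) {
      n_loci <- lengths(rows_per_seq[found])
      e <- index$entries[unlist(rows_per_seq[found]), , drop = FALSE]
      e$count <- rep(as.numeric(tab[found]) / n_loci, n_loci)
      e$sample <- s
      detail[[s]] <- e
    }
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(seq = character(0), mature = character(0),
               shift5 = integer(0), shift3 = integer(0),
               count = numeric(0), sample = character(0))
  detail$label <- isomir_label(detail$mature, detail$shift5)

  counts <- matrix(0, 0, length(samples), dimnames = list(NULL, samples))
  if (nrow(detail)) {
    agg <- aggregate(count ~ label + sample, detail, sum)
    labels <- sort(unique(agg$label))
    counts <- matrix(0, length(labels), length(samples),
                     dimnames = list(labels, samples))
    counts[cbind(match(agg$label, labels), match(agg$sample, samples))] <-
      agg$count
  }
  detailed <- detail[, c("label", "mature", "shift5", "shift3", "seq",
                         "sample", "count")]
  rownames(detailed) <- NULL
  list(counts = counts, detailed = detailed, unmapped = unmapped,
       total = total)
}

#' Quantify isomiRs straight from FASTQ files
#'
#' Convenience wrapper: read each FASTQ, trim the 3' adapter, and run
#' `quantify` against the reference lookup.
#'
#' @param fastq_paths named character vector: sample -> FASTQ path.
#' @param reference a `mirna_reference`.
#' @param adapter 3' adapter sequence.
#' @param min_overlap,min_len see `trim_adapter`.
#' @param window5,window3 see `build_lookup`.
#' @return as `quantify`, plus `n_too_short` per sample.
#' @export
quantify_fastq <- function(fastq_paths, reference,
                           adapter = "AGATCGGAAGAGCACACGTCT",
                           min_overlap = 3L, min_len = 16L,
                           window5 = 3L, window3 = 5L) {
  index <- build_lookup(reference, window5, window3)
  too_short <- setNames(numeric(length(fastq_paths)), names(fastq_paths))
  reads <- lapply(names(fastq_paths), function(s) {
    tr <- trim_adapter(read_fastq_seqs(fastq_paths[[s]]), adapter,
                       min_overlap, min_len)
    too_short[s] <<- sum(attr(tr, "status") == "too_short")
    tr
  })
  names(reads) <- names(fastq_paths)
  out <- quantify(reads, index)
  out$n_too_short <- too_short
  out
}
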