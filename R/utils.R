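#' @importFrom stats median pnorm phyper rbinom rmultinom rnbinom rpois runif
#'   rlnorm setNames p.adjust lm coef var sd quantile aggregate
#' @importFrom utils read.delim write.table head
NULL

# -- alphabet helpers ---------------------------------------------------------

#' Convert a sequence between DNA and RNA alphabets
#'
#' @param x character vector of sequences.
#' @return character vector in the target alphabet (upper case).
#' @export
dna_to_rna <- function(x) chartr("acgtT", "ACGUU", toupper(x))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("acguU", "ACGTT", toupper(x))

#' Reverse complement of DNA sequences
#'
#' Plain character implementation (the site-pattern derivation uses it);
#' file-level sequence I/O goes through Biostrings.
#'
#' @param x character vector of DNA sequences (ACGT).
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  bad <- grepl("[^ACGTacgt]", x)
  if (any(bad)) stop("non-ACGT symbol in sequence: ", x[which(bad)[1]])
  vapply(x, function(s) {
    comp <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# -- isomiR labels ------------------------------------------------------------

#' Render and parse "name|shift" isomiR labels
#'
#' The label convention annotates a mature miRNA with its signed 5'-end shift
#' in the 5'->3' direction: `|0` is the canonical form, `|+1` an isoform
#' shortened by one nucleotide at the 5' end, `|-1` one extended by one.
#'
#' @param mature mature miRNA name(s).
#' @param shift5 integer 5' shift(s); positive means shortened at the 5' end.
#' @return `isomir_label`: character labels. `parse_isomir_label`: a
#'   data.frame with columns `mature` and `shift5`.
#' @examples
#' isomir_label("miR-203a-3p", c(0, 1, -1))
#' @export
isomir_label <- function(mature, shift5) {
  shift5 <- as.integer(shift5)
  paste0(mature, "|", ifelse(shift5 == 0L, "0", sprintf("%+d", shift5)))
}

#' @rdname isomir_label
#' @param label character vector of "name|shift" labels.
#' @export
parse_isomir_label <- function(label) {
  pos <- regexpr("\\|[+-]?[0-9]+$", label)
  if (any(pos < 0)) stop("malformed isomiR label: ", label[which(pos < 0)[1]])
  data.frame(
    mature = substr(label, 1L, pos - 1L),
    shift5 = as.integer(sub("\\+", "", substring(label, pos + 1L))),
    stringsAsFactors = FALSE
  )
}

# -- tabular / sequence file I/O ---------------------------------------------

#' Read and write headered TSV tables
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_table`: a data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV (first column = feature id)
#' @param path file path.
#' @return numeric matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_count_matrix
#' @param m matrix with rownames.
#' @param id_col name for the feature-id column.
#' @export
write_count_matrix <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write_tsv_table(df, path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTQ sequences (qualities discarded)
#' @param path FASTQ path (gz accepted).
#' @return character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write reads as FASTQ with constant quality
#' @param seqs character vector of read sequences.
#' @param path output path.
#' @param ids read identifiers (default read1..readN).
#' @param qual_char single quality character (Phred+33).
#' @export
write_fastq <- function(seqs, path, ids = NULL, qual_char = "I") {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  quals <- vapply(nchar(seqs), function(n)
    paste(rep(qual_char, n), collapse = ""), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path GMT path.
#' @param sets named list of character vectors (gene ids).
#' @param descriptions optional per-set description strings.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[`, character(1), 1L))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}
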