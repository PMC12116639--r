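# Seed derivation for canonical and 5'-shifted isoforms, 3'UTR site
# scanning, and target-set assembly. The seed of a 5'-isoform is taken on
# the ISOFORM (post-shift), not the canonical mature, which is what makes
# 5'-shifted isomiRs retarget.

#' Sequence of a 5'-shifted isoform
#'
#' shift5 = +k drops the k leading nucleotides; shift5 = -k prepends the k
#' hairpin nucleotides upstream of the mature start (hairpin context
#' required).
#'
#' @param mature_seq mature sequence (RNA or DNA alphabet; preserved).
#' @param shift5 signed 5' shift.
#' @param hairpin hairpin sequence, required when `shift5 < 0`.
#' @param mature_start 1-based start of the mature on the hairpin.
#' @return isoform sequence in the input alphabet.
#' @export
isoform_sequence <- function(mature_seq, shift5, hairpin = NULL,
                             mature_start = NULL) {
  shift5 <- as.integer(shift5)
  if (shift5 == 0L) return(mature_seq)
  if (shift5 > 0L) {
    if (shift5 >= nchar(mature_seq)) stop("shift exceeds mature length")
    return(substring(mature_seq, shift5 + 1L))
  }
  if (is.null(hairpin) || is.null(mature_start))
    stop("5' extension requires hairpin context")
  a <- mature_start + shift5
  if (a < 1L) stop("extension runs past the hairpin 5' end")
  ext <- substr(hairpin, a, mature_start - 1L)
  if (grepl("U", mature_seq, fixed = TRUE)) ext <- dna_to_rna(ext)
  paste0(ext, mature_seq)
}

#' Seed of an isoform
#'
#' Positions 2-7 (6mer) or 2-8 (7mer-m8), 1-based on the isoform itself.
#'
#' @param isoform_seq isoform sequence (length >= 8).
#' @param kind "6mer" or "7mer-m8".
#' @return seed sequence in the RNA alphabet.
#' @export
seed_of <- function(isoform_seq, kind = c("6mer", "7mer-m8")) {
  kind <- match.arg(kind)
  if (nchar(isoform_seq) < 8L) stop("isoform too short for a seed")
  dna_to_rna(substr(isoform_seq, 2L, if (kind == "6mer") 7L else 8L))
}

#' DNA site pattern(s) matched by a seed on the UTR sense strand
#'
#' The site is the reverse complement of the seed in the DNA alphabet; the
#' 7mer-A1 variant is the 6mer site followed by an A on the UTR.
#'
#' @param seed seed sequence (RNA alphabet, from `seed_of`).
#' @param site_type "6mer", "7mer-m8" (pass a 7-nt seed), or "7mer-A1".
#' @return character vector of DNA site strings.
#' @export
site_patterns <- function(seed, site_type = c("6mer", "7mer-m8", "7mer-A1")) {
  site_type <- match.arg(site_type)
  if (grepl("[^ACGUacgu]", seed)) stop("non-ACGU symbol in seed: ", seed)
  core <- revcomp_dna(rna_to_dna(seed))
  switch(site_type,
         "6mer" = core,
         "7mer-m8" = core,
         "7mer-A1" = paste0(core, "A"))
}

#' Count seed-site occurrences in 3'UTRs
#'
#' Overlapping occurrences all count; a gene is "seed-containing" iff the
#' count is >= 1 for any supplied site string.
#'
#' @param utrs named character vector of UTR sequences (DNA, sense strand).
#' @param sites character vector of DNA site strings.
#' @return named integer vector: total site count per gene.
#' @export
scan_utr <- function(utrs, sites) {
  set <- Biostrings::DNAStringSet(utrs)
  counts <- rep(0L, length(utrs))
  for (s in sites)
    counts <- counts + Biostrings::vcountPattern(s, set)
  setNames(as.integer(counts), names(utrs))
}

#' Assemble validated and seed-filtered predicted target sets
#'
#' Canonical isomiRs ("|0") take their validated-table rows intersected
#' with the analysis universe. Non-canonical isomiRs take predicted-table
#' rows intersected with the universe AND with seed-containing genes — the
#' seed being re-derived on the shifted isoform and re-scanned against the
#' UTRs. Validated targets are not seed-filtered.
#'
#' @param validated_table data.frame (mirna_label, gene_id): validated
#'   targets keyed by canonical labels ("name|0") or bare mature names.
#' @param predicted_table data.frame (mirna_label, gene_id).
#' @param utrs named character vector of 3'UTR sequences (DNA).
#' @param isomirs data.frame of the isomiRs to process: label and isoform
#'   `seq` columns (e.g. from `isoform_table`).
#' @param universe character vector of analysis-universe gene ids.
#' @param site_type seed-site type for the presence filter (default 6mer).
#' @return named list: label -> list(genes, provenance); isomiRs with no
#'   table entry get an empty set.
#' @export
build_target_sets <- function(validated_table, predicted_table, utrs,
                              isomirs, universe,
                              site_type = c("6mer", "7mer-m8", "7mer-A1")) {
  site_type <- match.arg(site_type)
  parsed <- parse_isomir_label(isomirs$label)
  out <- vector("list", nrow(isomirs))
  names(out) <- isomirs$label
  for (i in seq_len(nrow(isomirs))) {
    lab <- isomirs$label[i]
    if (parsed$shift5[i] == 0L) {
      rows <- validated_table$mirna_label %in% c(lab, parsed$mature[i])
      genes <- intersect(unique(validated_table$gene_id[rows]), universe)
      out[[i]] <- list(genes = genes, provenance = "validated")
    } else {
      rows <- predicted_table$mirna_label == lab
      genes <- intersect(unique(predicted_table$gene_id[rows]), universe)
      if (length(genes)) {
        kind <- if (site_type == "7mer-m8") "7mer-m8" else "6mer"
        seed <- seed_of(isomirs$seq[i], kind)
        sites <- site_patterns(seed, site_type)
        hit <- scan_utr(utrs[genes], sites)
        genes <- genes[hit >= 1L]
      }
      out[[i]] <- list(genes = genes, provenance = "predicted+seed")
    }
  }
  out
}

#' Flatten target sets to a TSV-ready table
#' @param target_sets output of `build_target_sets`.
#' @return data.frame: mirna_label, gene_id, provenance.
#' @export
target_sets_table <- function(target_sets) {
  rows <- lapply(names(target_sets), function(lab) {
    ts <- target_sets[[lab]]
    if (!length(ts$genes)) return(NULL)
    data.frame(mirna_label = lab, gene_id = ts$genes,
               provenance = ts$provenance, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(mirna_label = character(0), gene_id = character(0),
                      provenance = character(0)))
  do.call(rbind, rows)
}
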