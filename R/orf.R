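# Six-frame ORF discovery on transcript contigs.
#
# Coordinate conventions: nucleotide spans are 0-based half-open on the
# forward strand; residue positions elsewhere in the package are 1-based
# inclusive. An ORF span covers the translated residues only; when has_stop
# is TRUE the stop codon is the codon immediately following the span (on the
# reading strand).

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read transcript contigs from a FASTA file
#'
#' @param path FASTA file of nucleotide contigs.
#' @return named character vector of upper-case sequences.
#' @export
read_contigs <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Translate a codon, tolerating ambiguous bases
#'
#' A codon containing 'N' translates to 'X'; stop codons return '*'.
#' @param codon 3-character nucleotide string.
#' @return single-character amino acid, 'X' or '*'.
#' @keywords internal
translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) "X" else aa
}

#' Find open reading frames in all six frames
#'
#' Enumerates every ORF that begins with a literal ATG, translating up to the
#' first in-frame stop codon (or the end of the readable frame when no stop
#' occurs, recorded via `has_stop = FALSE`). Each ATG yields one ORF, so
#' nested starts sharing a stop are all reported; downstream evidence decides
#' which is the real precursor start.
#'
#' @param sequence nucleotide string restricted to A/C/G/T/N.
#' @param contig_id identifier carried into the output.
#' @param min_protein_len minimum protein length (residues, >= 1) to report.
#' @return data.frame with columns `contig_id`, `frame` (+1..+3 forward,
#'   -1..-3 reverse), `nt_start`, `nt_end` (0-based half-open, forward
#'   strand, translated residues only), `protein`, `has_stop`.
#' @export
find_orfs <- function(sequence, contig_id = "contig", min_protein_len = 40L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            min_protein_len >= 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty contig sequence")
  if (grepl("[^ACGTN]", sequence)) {
    stop("contig '", contig_id, "' contains non-nucleotide characters")
  }
  L <- nchar(sequence)
  revcomp <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sequence)))

  out <- list()
  for (strand in c(1L, -1L)) {
    seq_use <- if (strand == 1L) sequence else revcomp
    for (offset in 0:2) {
      starts <- seq.int(offset + 1L, L, by = 3L)
      starts <- starts[starts + 2L <= L]
      if (!length(starts)) next
      codons <- substring(seq_use, starts, starts + 2L)
      aas <- vapply(codons, translate_codon, character(1L), USE.NAMES = FALSE)
      is_start <- codons == "ATG"
      is_stop <- aas == "*"
      for (i in which(is_start)) {
        stop_after <- which(is_stop & seq_along(codons) > i)
        # translated codons run from the ATG to just before the stop (or
        # frame end); protein excludes the stop
        if (length(stop_after)) {
          j <- stop_after[1L] - 1L
          has_stop <- TRUE
        } else {
          j <- length(codons)
          has_stop <- FALSE
        }
        n_res <- j - i + 1L
        if (n_res < min_protein_len) next
        protein <- paste(aas[i:j], collapse = "")
        s_local <- starts[i] - 1L            # 0-based on reading strand
        e_local <- starts[j] + 2L            # half-open
        if (strand == 1L) {
          nt_start <- s_local; nt_end <- e_local
        } else {
          nt_start <- L - e_local; nt_end <- L - s_local
        }
        out[[length(out) + 1L]] <- data.frame(
          contig_id = contig_id,
          frame = strand * (offset + 1L),
          nt_start = nt_start, nt_end = nt_end,
          protein = protein, has_stop = has_stop,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      protein = character(), has_stop = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$nt_start, res$frame, res$nt_end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find ORFs across a set of contigs
#'
#' @param contigs named character vector of contig sequences.
#' @inheritParams find_orfs
#' @return combined data.frame (see [find_orfs()]).
#' @export
find_orfs_set <- function(contigs, min_protein_len = 40L) {
  stopifnot(!is.null(names(contigs)))
  res <- lapply(names(contigs), function(id) {
    find_orfs(contigs[[id]], id, min_protein_len)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
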