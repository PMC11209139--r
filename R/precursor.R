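# Precursor segmentation: signal peptide / propeptide / mature peptide.

#' Read a signal-peptide annotation table
#'
#' Expects a TSV with columns `precursor_id`, `cleavage_after` (1-based index
#' of the last signal-peptide residue) and `probability`.
#'
#' @param path TSV file path.
#' @return data.frame with validated columns.
#' @export
read_signal_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("precursor_id", "cleavage_after", "probability")
  if (!all(need %in% names(tab))) {
    stop("signal annotation table must have columns: ",
         paste(need, collapse = ", "))
  }
  stopifnot(all(tab$cleavage_after >= 1L),
            all(tab$probability >= 0 & tab$probability <= 1))
  tab
}

#' Segment a precursor protein into signal, propeptide and mature spans
#'
#' The signal peptide runs from residue 1 to the annotated cleavage position.
#' With a propeptide cleavage site, the propeptide runs from the residue after
#' the signal to the cleavage position (the basic residue stays on the
#' propeptide side) and the mature peptide is the remainder; without one, the
#' mature peptide starts directly C-terminal to the signal peptide.
#'
#' @param protein full precursor amino-acid string.
#' @param id precursor identifier.
#' @param signal_end 1-based index of the last signal-peptide residue; must be
#'   < protein length.
#' @param cleavage_pos optional 1-based index of the last propeptide residue
#'   (the basic residue of the cleavage motif); must satisfy
#'   `signal_end < cleavage_pos < nchar(protein)`.
#' @param has_stop logical, ORF terminated by a stop codon.
#' @param has_signal logical, signal-peptide annotation accepted.
#' @param tpm expression level (transcripts per million), optional.
#' @return object of class `lampyritox_precursor`: a list with the protein,
#'   1-based inclusive spans, flags, cysteine positions within the mature
#'   peptide, tpm and a `functional_class` slot filled by annotation.
#' @export
segment_precursor <- function(protein, id, signal_end, cleavage_pos = NULL,
                              has_stop = TRUE, has_signal = TRUE,
                              tpm = NA_real_) {
  n <- nchar(protein)
  stopifnot(n > 0L, signal_end >= 1L, signal_end < n)
  if (!is.null(cleavage_pos)) {
    if (cleavage_pos <= signal_end || cleavage_pos >= n) {
      stop("cleavage position ", cleavage_pos,
           " must lie strictly between signal end (", signal_end,
           ") and protein end (", n, ")")
    }
  }
  signal_span <- c(1L, as.integer(signal_end))
  if (is.null(cleavage_pos)) {
    propeptide_span <- NULL
    mature_span <- c(signal_end + 1L, n)
  } else {
    propeptide_span <- c(signal_end + 1L, as.integer(cleavage_pos))
    mature_span <- c(cleavage_pos + 1L, n)
  }
  mature <- substr(protein, mature_span[1L], mature_span[2L])
  cys <- which(strsplit(mature, "", fixed = TRUE)[[1L]] == "C")
  structure(list(
    id = id, protein = protein,
    signal_span = signal_span, propeptide_span = propeptide_span,
    mature_span = mature_span,
    has_stop = isTRUE(has_stop), has_signal = isTRUE(has_signal),
    cysteine_positions = cys, tpm = tpm,
    functional_class = NA_character_
  ), class = "lampyritox_precursor")
}

#' @export
print.lampyritox_precursor <- function(x, ...) {
  cat("Precursor", x$id, "(", nchar(x$protein), "aa )\n")
  cat("  signal:    ", span_str(x$signal_span), " ",
      signal_peptide(x), "\n", sep = "")
  if (!is.null(x$propeptide_span)) {
    cat("  propeptide:", span_str(x$propeptide_span), " ",
        propeptide(x), "\n", sep = "")
  }
  cat("  mature:    ", span_str(x$mature_span), " ",
      mature_peptide(x), "\n", sep = "")
  cat("  cysteines in mature:", length(x$cysteine_positions),
      " stop:", x$has_stop, " signal:", x$has_signal, "\n")
  invisible(x)
}

span_str <- function(s) paste0("[", s[1L], ",", s[2L], "]")

#' Extract segment sequences from a precursor record
#' @param rec a `lampyritox_precursor`.
#' @return amino-acid string of the segment.
#' @export
mature_peptide <- function(rec) {
  substr(rec$protein, rec$mature_span[1L], rec$mature_span[2L])
}

#' @rdname mature_peptide
#' @export
signal_peptide <- function(rec) {
  substr(rec$protein, rec$signal_span[1L], rec$signal_span[2L])
}

#' @rdname mature_peptide
#' @export
propeptide <- function(rec) {
  if (is.null(rec$propeptide_span)) return("")
  substr(rec$protein, rec$propeptide_span[1L], rec$propeptide_span[2L])
}

#' Post-signal region (propeptide + mature peptide)
#' @param rec a `lampyritox_precursor`.
#' @return amino-acid string following the signal peptide.
#' @export
post_signal <- function(rec) {
  substr(rec$protein, rec$signal_span[2L] + 1L, nchar(rec$protein))
}

#' Completeness report for a precursor
#'
#' A precursor is "complete" when its protein starts with methionine, its ORF
#' ends at a stop codon, and it carries an accepted signal-peptide
#' annotation. Reports flags without mutating the record.
#'
#' @param rec a `lampyritox_precursor`.
#' @param signal_probability probability from the signal annotation, compared
#'   against `min_signal_prob`; pass `NA` when no annotation exists.
#' @param min_signal_prob acceptance threshold for the signal probability.
#' @return list with logical flags `starts_with_M`, `has_stop`, `has_signal`
#'   and the conjunction `complete`.
#' @export
validate_precursor <- function(rec, signal_probability = NA_real_,
                               min_signal_prob = 0.5) {
  has_signal <- rec$has_signal &&
    (is.na(signal_probability) || signal_probability >= min_signal_prob)
  if (!is.na(signal_probability) && signal_probability < min_signal_prob) {
    has_signal <- FALSE
  }
  flags <- list(
    starts_with_M = substr(rec$protein, 1L, 1L) == "M",
    has_stop = isTRUE(rec$has_stop),
    has_signal = isTRUE(has_signal)
  )
  flags$complete <- all(unlist(flags))
  flags
}

#' Canonical cysteine-framework signature
#'
#' Encodes the spacing pattern of cysteines as e.g. `"C-x2-C-x3-C-C"`: `xN`
#' is a gap of N non-cysteine residues, adjacent cysteines are joined
#' directly. Two sequences share a framework exactly when their cysteine
#' counts and all inter-cysteine gaps agree; residues outside the cysteine
#' scaffold do not matter.
#'
#' @param seq amino-acid string.
#' @return framework string; empty string when the sequence has no cysteine.
#' @examples
#' cysteine_framework("ANCGLCPVFCKLGFHCTANGQRCC")
#' @export
cysteine_framework <- function(seq) {
  pos <- which(strsplit(seq, "", fixed = TRUE)[[1L]] == "C")
  if (!length(pos)) return("")
  if (length(pos) == 1L) return("C")
  gaps <- diff(pos) - 1L
  parts <- "C"
  for (g in gaps) {
    parts <- c(parts, if (g > 0L) paste0("x", g) else NULL, "C")
  }
  paste(parts, collapse = "-")
}
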