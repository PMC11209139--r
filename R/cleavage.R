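# Propeptide cleavage-site scanning and processing-product enumeration.
#
# Venom precursor maturation removes the propeptide by proteolysis
# C-terminal to basic residues. Three motif classes are recognised, in
# priority order when they overlap at a position:
#   quadruplet - processing quadruplet motif: R at the cleavage position with
#                a glutamate two, three or four residues upstream (E at
#                -2/-3/-4 counting the R as -1), e.g. "VVER";
#   dibasic    - KR, RR, KK or RK, cleavage after the second residue;
#   monobasic  - a single R with no basic neighbour.

DIBASIC_PAIRS <- c("KR", "RR", "KK", "RK")

#' Scan a post-signal region for candidate cleavage sites
#'
#' Returns every candidate site; all are reported because downstream MALDI
#' mass evidence, not the scan, arbitrates which site is used in vivo.
#' Positions are 1-based indices into `post_signal_seq` of the last motif
#' residue; cleavage occurs C-terminal to that residue and the basic residue
#' stays on the propeptide-side fragment.
#'
#' @param post_signal_seq amino-acid string following the signal peptide.
#' @return data.frame with columns `position`, `motif_kind`
#'   (quadruplet/dibasic/monobasic) and `motif_seq`, sorted by position.
#' @examples
#' scan_cleavage_sites("EPVVERANCGLC")  # quadruplet at the R of "VVER"
#' @export
scan_cleavage_sites <- function(post_signal_seq) {
  stopifnot(is.character(post_signal_seq), length(post_signal_seq) == 1L,
            nzchar(post_signal_seq))
  aa <- strsplit(post_signal_seq, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  out <- list()
  for (i in seq_len(n)) {
    kind <- NULL
    if (aa[i] == "R" && i > 1L) {
      upstream <- aa[max(1L, i - 3L):(i - 1L)]
      if (any(upstream == "E")) kind <- "quadruplet"
    }
    if (is.null(kind) && i > 1L &&
        paste0(aa[i - 1L], aa[i]) %in% DIBASIC_PAIRS) {
      kind <- "dibasic"
    }
    if (is.null(kind) && aa[i] == "R") {
      prev_basic <- i > 1L && aa[i - 1L] %in% c("K", "R")
      next_basic <- i < n && aa[i + 1L] %in% c("K", "R")
      if (!prev_basic && !next_basic) kind <- "monobasic"
    }
    if (is.null(kind)) next
    motif_len <- switch(kind, quadruplet = 4L, dibasic = 2L, monobasic = 1L)
    motif <- paste(aa[max(1L, i - motif_len + 1L):i], collapse = "")
    out[[length(out) + 1L]] <- data.frame(
      position = i, motif_kind = kind, motif_seq = motif,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(position = integer(), motif_kind = character(),
                      motif_seq = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$position), , drop = FALSE]
}

#' Enumerate candidate processing products of a precursor
#'
#' For each candidate cleavage site the mature peptide (residues after the
#' site to the C-terminus) is emitted; when at least one site exists the
#' propeptide-bearing intermediate (the whole post-signal region) is emitted
#' once as well. Without any site the post-signal region itself is the
#' mature peptide. Disulfide counts follow the all-cysteines-paired
#' assumption.
#'
#' @param rec a `lampyritox_precursor`.
#' @param sites data.frame from [scan_cleavage_sites()] run on
#'   `post_signal(rec)` (positions in post-signal coordinates), or NULL to
#'   scan internally.
#' @param amidated logical, apply the C-terminal amidation delta to products.
#' @return data.frame of products: `precursor_id`, `label`, `site_position`,
#'   `motif_kind`, `sequence`, `n_disulfides`, `amidated`.
#' @export
enumerate_products <- function(rec, sites = NULL, amidated = FALSE) {
  ps <- post_signal(rec)
  if (is.null(sites)) sites <- scan_cleavage_sites(ps)
  if (nrow(sites) && any(sites$position >= nchar(ps))) {
    # a site at the final residue would leave an empty mature peptide
    sites <- sites[sites$position < nchar(ps), , drop = FALSE]
  }
  rows <- list()
  add <- function(label, seqs, site_pos = NA_integer_,
                  motif = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      precursor_id = rec$id, label = label, site_position = site_pos,
      motif_kind = motif, sequence = seqs,
      n_disulfides = default_disulfides(seqs),
      amidated = amidated, stringsAsFactors = FALSE)
  }
  if (nrow(sites) == 0L) {
    add("mature", ps)
  } else {
    for (k in seq_len(nrow(sites))) {
      mature <- substr(ps, sites$position[k] + 1L, nchar(ps))
      add("mature", mature, sites$position[k], sites$motif_kind[k])
    }
    add("propeptide_mature_intermediate", ps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round-trip cleavage annotations through TSV
#'
#' @param annotations data.frame with `precursor_id`, `position`,
#'   `motif_kind`, `motif_seq`.
#' @param path output TSV path.
#' @export
write_cleavage_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cleavage_annotations
#' @export
read_cleavage_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
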