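# Independent oracles and small fixture builders shared across the suite.

# --- elemental-composition mass oracle ---------------------------------
# Residue formulas (residue = amino acid minus water) and monoisotopic
# atomic masses; summing atom-by-atom is an independent route to the
# peptide mass that never touches the package's residue table.
ATOM_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
               O = 15.9949146196, S = 31.97207100)
RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

oracle_peptide_mass <- function(seq) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1L]]
  atoms <- Reduce(`+`, RESIDUE_FORMULA[aa])
  atoms[["H"]] <- atoms[["H"]] + 2  # water
  atoms[["O"]] <- atoms[["O"]] + 1
  sum(atoms * ATOM_MASS[names(atoms)])
}

random_peptide <- function(min_len = 5L, max_len = 120L) {
  n <- sample(min_len:max_len, 1L)
  paste(sample(names(RESIDUE_FORMULA), n, replace = TRUE), collapse = "")
}

# --- brute-force six-frame ORF oracle ----------------------------------
# Enumerates every ATG start in every frame on both strands, walking codon
# by codon; completely independent of the vectorised scanner.
oracle_orfs <- function(sequence, min_protein_len = 1L) {
  code <- Biostrings::GENETIC_CODE
  tr1 <- function(codon) {
    if (grepl("N", codon, fixed = TRUE)) return("X")
    unname(code[codon])
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  L <- nchar(sequence)
  rc <- paste(rev(comp[strsplit(sequence, "")[[1L]]]), collapse = "")
  out <- list()
  for (strand in c(1L, -1L)) {
    s_use <- if (strand == 1L) sequence else rc
    for (start in seq_len(L - 2L)) {
      if (substr(s_use, start, start + 2L) != "ATG") next
      prot <- ""
      pos <- start
      has_stop <- FALSE
      while (pos + 2L <= L) {
        aa <- tr1(substr(s_use, pos, pos + 2L))
        if (aa == "*") { has_stop <- TRUE; break }
        prot <- paste0(prot, aa)
        pos <- pos + 3L
      }
      if (nchar(prot) < min_protein_len) next
      e_local <- start - 1L + 3L * nchar(prot)
      s0 <- start - 1L
      out[[length(out) + 1L]] <- data.frame(
        frame = strand * ((start - 1L) %% 3L + 1L),
        nt_start = if (strand == 1L) s0 else L - e_local,
        nt_end = if (strand == 1L) e_local else L - s0,
        protein = prot, has_stop = has_stop, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), nt_start = integer(),
                      nt_end = integer(), protein = character(),
                      has_stop = logical()))
  }
  res <- do.call(rbind, out)
  res[order(res$nt_start, res$frame, res$nt_end), , drop = FALSE]
}

# --- brute-force best-hit oracle ---------------------------------------
oracle_best_hit <- function(hits) {
  if (nrow(hits) == 0L) return(NULL)
  ord <- order(hits$evalue, hits$subject_id)
  top <- hits[ord[seq_len(min(10L, nrow(hits)))], , drop = FALSE]
  best <- NULL
  best_key <- NULL
  for (i in seq_len(nrow(top))) {
    acc <- min(1, (top$alignment_length[i] / top$query_length[i]) *
                 (top$alignment_length[i] / top$subject_length[i]))
    key <- list(acc = acc, ev = top$evalue[i], id = top$subject_id[i])
    better <- is.null(best_key) ||
      key$acc > best_key$acc ||
      (key$acc == best_key$acc && key$ev < best_key$ev) ||
      (key$acc == best_key$acc && key$ev == best_key$ev &&
         key$id < best_key$id)
    if (better) { best <- top[i, , drop = FALSE]; best_key <- key }
  }
  best
}

random_hit_list <- function(n) {
  data.frame(
    query_id = "q",
    subject_id = sprintf("s%03d", sample.int(999, n)),
    alignment_length = sample(10:200, n, replace = TRUE),
    query_length = sample(50:250, n, replace = TRUE),
    subject_length = sample(50:250, n, replace = TRUE),
    evalue = signif(10^runif(n, -30, 0), 3),
    stringsAsFactors = FALSE)
}

# --- exhaustive disulfide-pairing oracle -------------------------------
# Enumerates all disjoint pairings over the admissible-pair set and picks
# max count, then min total distance.
oracle_pairing <- function(dmat, threshold) {
  n <- nrow(dmat)
  best <- list(count = -1L, total = Inf, pairs = NULL)
  rec <- function(avail, pairs, total) {
    if (length(avail) < 2L) {
      cnt <- if (is.null(pairs)) 0L else nrow(pairs)
      if (cnt > best$count || (cnt == best$count && total < best$total)) {
        best <<- list(count = cnt, total = total, pairs = pairs)
      }
      return()
    }
    i <- avail[1L]
    rec(avail[-1L], pairs, total)
    for (j in avail[-1L]) {
      if (dmat[i, j] <= threshold) {
        rec(setdiff(avail[-1L], j),
            rbind(pairs, data.frame(i = i, j = j)), total + dmat[i, j])
      }
    }
  }
  rec(seq_len(n), NULL, 0)
  best
}

# --- Table of printed toxin precursors ---------------------------------
toxin_precursor_table <- function() {
  utils::read.delim(
    system.file("extdata", "lampyris_toxin_precursors.tsv",
                package = "lampyritox"),
    stringsAsFactors = FALSE, check.names = FALSE)
}

# --- shared synthetic bundle (generated once per run) ------------------
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "lampyritox-shared-bundle")
      truth <- generate_cohort(synthetic_truth(2024L), dir)
      cache <<- list(dir = dir, truth = truth)
    }
    cache
  }
})
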