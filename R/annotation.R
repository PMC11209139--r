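# Homology-based functional classification, quality filtering, rational
# toxin naming, and per-class expression aggregation.

#' Parse a tabular BLAST result (outfmt-6 style plus qlen/slen)
#'
#' Expects the 12 standard columns followed by `qlen`, `slen` and optionally
#' `stitle` (subject description), tab-separated, no header. Rows whose
#' numeric fields fail to parse are skipped with a warning. Hits worse than
#' the database's E-value threshold are kept but flagged `sub_threshold`.
#'
#' @param path TSV path.
#' @param database "toxprot" or "metazoa"; selects the E-value threshold.
#' @param evalue_threshold override for the threshold (defaults: metazoa
#'   1e-5, toxprot 1e-2).
#' @return data.frame of hits with a `database` and `sub_threshold` column.
#' @export
parse_blast_tab <- function(path, database = c("toxprot", "metazoa"),
                            evalue_threshold = NULL) {
  database <- match.arg(database)
  if (is.null(evalue_threshold)) {
    evalue_threshold <- if (database == "metazoa") 1e-5 else 1e-2
  }
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore", "query_length", "subject_length",
            "subject_description")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(setNames(
      c(replicate(2, character(), simplify = FALSE),
        replicate(12, numeric(), simplify = FALSE),
        list(character())), cols))
    out$database <- character(); out$sub_threshold <- logical()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_skipped <- 0L
  rows <- lapply(fields, function(f) {
    if (length(f) < 14L) return(NULL)
    num <- suppressWarnings(as.numeric(f[3:14]))
    if (anyNA(num) || num[11L] < 0 || any(num[c(2L, 12L)] <= 0)) return(NULL)
    data.frame(query_id = f[1L], subject_id = f[2L],
               percent_identity = num[1L], alignment_length = num[2L],
               mismatches = num[3L], gap_opens = num[4L],
               qstart = num[5L], qend = num[6L],
               sstart = num[7L], send = num[8L],
               evalue = num[9L], bitscore = num[10L],
               query_length = num[11L], subject_length = num[12L],
               subject_description = if (length(f) >= 15L) f[15L] else "",
               stringsAsFactors = FALSE)
  })
  n_skipped <- sum(vapply(rows, is.null, logical(1L)))
  if (n_skipped > 0L) {
    warning(n_skipped, " malformed BLAST row(s) skipped in ", path)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  out$database <- database
  out$sub_threshold <- out$evalue > evalue_threshold
  rownames(out) <- NULL
  out
}

#' Accordance between alignment, query and subject lengths
#'
#' The product of the two alignment-length fractions,
#' `(alen / qlen) * (alen / slen)`, capped at 1. It is symmetric in query and
#' subject and reaches 1 only for full-length mutual coverage, quantifying
#' the joint agreement of all three lengths.
#'
#' @param alignment_length,query_length,subject_length positive lengths
#'   (residues); vectorised.
#' @return accordance fraction in [0, 1].
#' @export
accordance <- function(alignment_length, query_length, subject_length) {
  if (any(alignment_length <= 0 | query_length <= 0 | subject_length <= 0)) {
    stop("lengths must be positive")
  }
  pmin(1, (alignment_length / query_length) *
         (alignment_length / subject_length))
}

#' Select the best BLAST hit by the ten-lowest-E accordance rule
#'
#' Among the (at most) ten hits with the lowest E-values, the hit with the
#' highest accordance wins; ties are broken by lower E-value, then by
#' lexicographic subject id.
#'
#' @param hits data.frame of hits for a single query and database (see
#'   [parse_blast_tab()]); sub-threshold hits should be excluded beforehand
#'   if desired.
#' @return single-row data.frame, or NULL for empty input.
#' @export
select_best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  ord <- order(hits$evalue, hits$subject_id)
  top <- hits[ord[seq_len(min(10L, nrow(hits)))], , drop = FALSE]
  acc <- accordance(top$alignment_length, top$query_length,
                    top$subject_length)
  pick <- order(-acc, top$evalue, top$subject_id)[1L]
  out <- top[pick, , drop = FALSE]
  out$accordance <- acc[pick]
  rownames(out) <- NULL
  out
}

#' Default classification keyword tables
#'
#' Reads the editable keyword configuration shipped with the package
#' (`inst/extdata/class_keywords.tsv`): one row per (class, keyword) pair.
#' Keywords are matched case-insensitively against BLAST subject descriptions
#' and InterPro domain descriptions. The `toxin_domain` class lists InterPro
#' terms that count as direct toxin-domain evidence.
#'
#' @param path optional path to an alternative keyword TSV.
#' @return named list of character vectors, one per class.
#' @export
default_keyword_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_keywords.tsv",
                        package = "lampyritox")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(tab$keyword, tab$class)
}

match_any_keyword <- function(text, keywords) {
  if (!length(text) || !length(keywords)) return(FALSE)
  text <- tolower(paste(text, collapse = " "))
  any(vapply(tolower(keywords),
             function(k) grepl(k, text, fixed = TRUE), logical(1L)))
}

#' Classify a precursor from homology and domain evidence
#'
#' A precursor is a putative neurotoxin when toxin-similarity evidence exists
#' (a Tox-Prot best hit passing its E-value threshold, or an InterPro term
#' from the toxin-domain list) and its mature peptide carries at least four
#' cysteines. Whether the mature neutral mass falls in the 3-12 kDa range
#' typical of these peptides is reported as a consistency flag, never used
#' as a gate. Hydrolase, odorant-binding and housekeeping classes come from
#' keyword matches on descriptions; a precursor with no passing hit and no
#' domain term is "novel" (cysteine-rich novel compounds are flagged as
#' candidates).
#'
#' @param rec a `lampyritox_precursor`.
#' @param toxprot_best,metazoa_best best-hit rows from [select_best_hit()]
#'   (NULL when absent); pass threshold-filtered hits.
#' @param interpro_terms character vector of InterPro domain descriptions.
#' @param keywords keyword tables from [default_keyword_tables()].
#' @param config a [filter_config()] (supplies the E-value thresholds).
#' @return list: `precursor_id`, `functional_class`, `best_hit`,
#'   `interpro_terms`, `n_cysteines`, `size_consistent`,
#'   `cysteine_rich_candidate`, `toxin_name` (NA until named).
#' @export
classify <- function(rec, toxprot_best = NULL, metazoa_best = NULL,
                     interpro_terms = character(),
                     keywords = default_keyword_tables(),
                     config = filter_config()) {
  mature <- mature_peptide(rec)
  n_cys <- count_cysteines(mature)
  mature_mass <- tryCatch(peptide_monoisotopic_mass(mature),
                          error = function(e) NA_real_)
  size_ok <- !is.na(mature_mass) && mature_mass >= 3000 && mature_mass <= 12000

  tox_pass <- !is.null(toxprot_best) &&
    toxprot_best$evalue <= config$evalue_toxprot
  met_pass <- !is.null(metazoa_best) &&
    metazoa_best$evalue <= config$evalue_metazoa
  toxin_domain <- match_any_keyword(interpro_terms, keywords$toxin_domain)

  descr <- c(if (met_pass) metazoa_best$subject_description,
             interpro_terms)
  cls <- if ((tox_pass || toxin_domain) && n_cys >= 4L) {
    "putative_neurotoxin"
  } else if (match_any_keyword(descr, keywords$peptidase)) {
    "peptidase"
  } else if (match_any_keyword(descr, keywords$carboxylesterase)) {
    "carboxylesterase"
  } else if (match_any_keyword(descr, keywords$glycosidase)) {
    "glycosidase"
  } else if (match_any_keyword(descr, keywords$odorant_binding)) {
    "odorant_binding"
  } else if (match_any_keyword(descr, keywords$housekeeping)) {
    "housekeeping"
  } else if (!tox_pass && !met_pass && !length(interpro_terms)) {
    "novel"
  } else {
    "other"
  }
  best <- if (tox_pass) toxprot_best else if (met_pass) metazoa_best else NULL
  list(precursor_id = rec$id, functional_class = cls, best_hit = best,
       interpro_terms = interpro_terms, n_cysteines = n_cys,
       size_consistent = size_ok,
       cysteine_rich_candidate = cls == "novel" && n_cys >= 4L,
       toxin_name = NA_character_)
}

#' Transcript-to-proteome coverage from PSM spans
#'
#' Percentage of precursor residues covered by the union of peptide-spectrum
#' match spans.
#'
#' @param protein_length precursor length in residues.
#' @param psms data.frame with 1-based inclusive `span_start`, `span_end`.
#' @return coverage percentage in [0, 100].
#' @export
compute_coverage <- function(protein_length, psms) {
  stopifnot(protein_length >= 1L)
  if (is.null(psms) || nrow(psms) == 0L) return(0)
  covered <- logical(protein_length)
  for (i in seq_len(nrow(psms))) {
    s <- max(1L, psms$span_start[i])
    e <- min(protein_length, psms$span_end[i])
    if (s <= e) covered[s:e] <- TRUE
  }
  100 * sum(covered) / protein_length
}

#' Quality-filter configuration
#'
#' Thresholds of the precursor quality gates: minimum transcript-proteome
#' coverage (percent), minimum best PSM score (-10lgP), and per-database
#' BLAST E-value ceilings. All thresholds are inclusive ("at least").
#'
#' @param min_coverage minimum coverage percent (default 7).
#' @param min_score minimum best -10lgP (default 30).
#' @param evalue_metazoa,evalue_toxprot E-value thresholds (1e-5, 1e-2).
#' @return list of class `lampyritox_filter_config`.
#' @export
filter_config <- function(min_coverage = 7, min_score = 30,
                          evalue_metazoa = 1e-5, evalue_toxprot = 1e-2) {
  stopifnot(min_coverage > 0, min_score > 0,
            evalue_metazoa > 0, evalue_toxprot > 0)
  structure(list(min_coverage = min_coverage, min_score = min_score,
                 evalue_metazoa = evalue_metazoa,
                 evalue_toxprot = evalue_toxprot),
            class = "lampyritox_filter_config")
}

#' Apply the precursor quality gates
#'
#' Four inclusive gates: the precursor is complete (starts with M and the ORF
#' has a stop codon), carries a signal peptide, its transcript-proteome
#' coverage is at least `min_coverage` percent, and its best supporting PSM
#' score (-10lgP) is at least `min_score`. Every rejection lists its failed
#' gates.
#'
#' @param records list of `lampyritox_precursor` objects.
#' @param psms data.frame with `precursor_id`, `span_start`, `span_end`,
#'   `score`.
#' @param config a [filter_config()].
#' @return list with `kept` (records), `rejected` (records),
#'   `report` (data.frame: id, per-gate logicals, coverage, best_score,
#'   kept, reasons).
#' @export
apply_filters <- function(records, psms, config = filter_config()) {
  rows <- lapply(records, function(rec) {
    v <- validate_precursor(rec)
    p <- psms[psms$precursor_id == rec$id, , drop = FALSE]
    cov <- compute_coverage(nchar(rec$protein), p)
    best <- if (nrow(p)) max(p$score) else -Inf
    gates <- c(complete = v$starts_with_M && v$has_stop,
               signal = v$has_signal,
               coverage = cov >= config$min_coverage,
               score = best >= config$min_score)
    data.frame(precursor_id = rec$id,
               complete = gates[["complete"]], signal = gates[["signal"]],
               coverage_ok = gates[["coverage"]], score_ok = gates[["score"]],
               coverage = cov,
               best_score = ifelse(is.finite(best), best, NA_real_),
               kept = all(gates),
               reasons = paste(names(gates)[!gates], collapse = ","),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(kept = records[report$kept],
       rejected = records[!report$kept],
       report = report)
}

#' Sequence identity between two peptides
#'
#' Identity fraction derived from the Levenshtein edit distance:
#' `1 - dist / max(length)`. Used for grouping toxin isoforms, where members
#' are near-identical and the approximation is tight.
#'
#' @param a,b amino-acid strings.
#' @return identity fraction in [0, 1].
#' @export
seq_identity <- function(a, b) {
  d <- utils::adist(a, b)[1L, 1L]
  1 - d / max(nchar(a), nchar(b))
}

#' Group mature peptides into toxin families
#'
#' Two peptides join a family when they share an identical cysteine
#' framework and at least `min_identity` sequence identity; families are the
#' connected components of that relation (single linkage).
#'
#' @param ids character vector of precursor ids.
#' @param matures character vector of mature peptides, parallel to `ids`.
#' @param min_identity identity threshold (default 0.5).
#' @return integer vector of family indices (1-based, order of first
#'   appearance), named by id.
#' @export
cluster_families <- function(ids, matures, min_identity = 0.5) {
  n <- length(ids)
  stopifnot(length(matures) == n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  fw <- vapply(matures, cysteine_framework, character(1L))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (fw[i] == fw[j] && nzchar(fw[i]) &&
          seq_identity(matures[i], matures[j]) >= min_identity) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  fam <- match(roots, unique(roots))
  names(fam) <- ids
  fam
}

#' Rational toxin name
#'
#' Builds names following rational venom nomenclature: an activity prefix
#' ("U-" while the activity is unknown), the toxin family name
#' ("Lampyristoxin"), the species code plus family number, and an isoform
#' letter (a, b, c, ... by descending expression) when the family has
#' several members. Novel compounds without database hits are named
#' "NLVC n" (Novel-Lampyris-Venom-Compound).
#'
#' @param family_index integer family number.
#' @param species_code two-letter species code (default "Ln").
#' @param isoform_rank 1-based rank of the isoform within its family,
#'   ordered by descending tpm (ties by precursor id).
#' @param activity_known logical; FALSE adds the "U-" prefix.
#' @param multi_isoform logical; append the isoform letter (TRUE for
#'   families with more than one member).
#' @param novel logical; name as "NLVC {family_index}" instead.
#' @return character name.
#' @examples
#' assign_toxin_name(1, isoform_rank = 1)  # "U-Lampyristoxin-Ln1a"
#' @export
assign_toxin_name <- function(family_index, species_code = "Ln",
                              isoform_rank = 1L, activity_known = FALSE,
                              multi_isoform = TRUE, novel = FALSE) {
  if (novel) return(paste("NLVC", family_index))
  stopifnot(isoform_rank >= 1L, isoform_rank <= 26L)
  paste0(if (!activity_known) "U-" else "",
         "Lampyristoxin-", species_code, family_index,
         if (multi_isoform) letters[isoform_rank] else "")
}

#' Aggregate expression by functional class
#'
#' @param results data.frame with `precursor_id` and `functional_class`.
#' @param tpm named numeric vector of expression levels (tpm) by precursor
#'   id; ids with missing tpm are counted but excluded from the sum, with a
#'   warning.
#' @return data.frame `functional_class`, `n_precursors`, `sum_tpm`, sorted
#'   by summed tpm descending.
#' @export
aggregate_expression <- function(results, tpm) {
  if (nrow(results) == 0L) {
    return(data.frame(functional_class = character(),
                      n_precursors = integer(), sum_tpm = numeric()))
  }
  vals <- tpm[results$precursor_id]
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " precursor(s) without tpm excluded from sums")
  }
  cls <- split(seq_len(nrow(results)), results$functional_class)
  out <- do.call(rbind, lapply(names(cls), function(k) {
    idx <- cls[[k]]
    data.frame(functional_class = k, n_precursors = length(idx),
               sum_tpm = sum(vals[idx], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$sum_tpm, out$functional_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
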