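# End-to-end orchestration: contigs -> precursors -> products -> masses ->
# quality filters -> classification/naming -> MALDI matching -> disulfides.

#' Pipeline configuration
#'
#' Collects the input paths and tunable parameters of a full pipeline run.
#' All thresholds are inclusive.
#'
#' @param contigs FASTA of transcript contigs.
#' @param signal signal-peptide annotation TSV (precursor_id,
#'   cleavage_after, probability).
#' @param psm PSM evidence TSV (precursor_id, span_start, span_end, score,
#'   approach).
#' @param expression expression TSV (precursor_id, tpm).
#' @param blast_toxprot,blast_metazoa tabular BLAST results.
#' @param interpro InterPro TSV (precursor_id, accession, description).
#' @param spectra_index TSV listing spectra (spectrum_id, specimen_id, path
#'   relative to the index file).
#' @param pdb_dir directory of per-precursor PDB models (optional).
#' @param filter a [filter_config()].
#' @param min_protein_len ORF length floor (residues).
#' @param match_tol mass-match tolerance (Da).
#' @param cluster_tol cross-spectrum clustering tolerance (Da).
#' @param mz_window MALDI acquisition window (Da).
#' @param min_fraction reproducibility fraction of spectra.
#' @param disulfide_threshold SG-SG bridge cutoff (Angstrom).
#' @param amidated apply C-terminal amidation to products.
#' @param species_code species code for toxin names.
#' @param out_dir optional report output directory.
#' @return list of class `lampyritox_config`.
#' @export
pipeline_config <- function(contigs, signal, psm, expression,
                            blast_toxprot = NULL, blast_metazoa = NULL,
                            interpro = NULL, spectra_index = NULL,
                            pdb_dir = NULL, filter = filter_config(),
                            min_protein_len = 40L,
                            match_tol = 0.5, cluster_tol = 0.3,
                            mz_window = c(800, 4500), min_fraction = 0.5,
                            disulfide_threshold = 2.5, amidated = FALSE,
                            species_code = "Ln", out_dir = NULL) {
  cfg <- list(contigs = contigs, signal = signal, psm = psm,
              expression = expression, blast_toxprot = blast_toxprot,
              blast_metazoa = blast_metazoa, interpro = interpro,
              spectra_index = spectra_index, pdb_dir = pdb_dir,
              filter = filter, min_protein_len = min_protein_len,
              match_tol = match_tol, cluster_tol = cluster_tol,
              mz_window = mz_window, min_fraction = min_fraction,
              disulfide_threshold = disulfide_threshold,
              amidated = amidated, species_code = species_code,
              out_dir = out_dir)
  mandatory <- c("contigs", "signal", "psm", "expression")
  for (m in mandatory) {
    if (!file.exists(cfg[[m]])) stop("missing mandatory input: ", cfg[[m]])
  }
  structure(cfg, class = "lampyritox_config")
}

# pick the precursor ORF for a contig: complete ORFs first, then longest
pick_orf <- function(orfs) {
  if (nrow(orfs) == 0L) return(NULL)
  ord <- order(-orfs$has_stop, -nchar(orfs$protein), orfs$nt_start)
  orfs[ord[1L], , drop = FALSE]
}

#' Run the full annotation pipeline
#'
#' Executes every stage on the configured inputs and returns (and optionally
#' writes) a report bundle: a per-precursor table mirroring the classic
#' toxin-table layout (name, best hit, tpm, PTM, predicted [M+H]+ values,
#' MALDI match flag), a per-class aggregation of counts and summed
#' expression, and gate-by-gate filter counts. All orderings are fixed
#' (summed tpm descending, then id) so reruns are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return list with `records`, `sites`, `products`, `filter_report`,
#'   `kept`, `annotations`, `toxin_table`, `class_table`, `gate_counts`,
#'   `consensus`, `matches`, `bridges`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lampyritox_config"))
  contigs <- read_contigs(config$contigs)
  signal <- read_signal_annotations(config$signal)
  psms <- utils::read.delim(config$psm, stringsAsFactors = FALSE)
  expr <- utils::read.delim(config$expression, stringsAsFactors = FALSE)
  tpm <- stats::setNames(expr$tpm, expr$precursor_id)

  # --- precursor reconstruction ---------------------------------------
  records <- list()
  sites <- list()
  products <- list()
  for (i in seq_len(nrow(signal))) {
    id <- signal$precursor_id[i]
    if (!id %in% names(contigs)) next
    orfs <- find_orfs(contigs[[id]], id, config$min_protein_len)
    orf <- pick_orf(orfs)
    if (is.null(orf) || nchar(orf$protein) <= signal$cleavage_after[i]) next
    rec <- segment_precursor(
      orf$protein, id, signal$cleavage_after[i],
      has_stop = orf$has_stop,
      has_signal = signal$probability[i] >= 0.5,
      tpm = if (id %in% names(tpm)) tpm[[id]] else NA_real_)
    records[[id]] <- rec
    sites[[id]] <- scan_cleavage_sites(post_signal(rec))
    products[[id]] <- product_mass_table(
      enumerate_products(rec, sites[[id]], amidated = config$amidated))
  }

  # --- quality gates ---------------------------------------------------
  filt <- apply_filters(records, psms, config$filter)
  kept <- filt$kept
  kept_ids <- vapply(kept, function(r) r$id, character(1L))

  # --- homology evidence ----------------------------------------------
  read_hits <- function(path, db) {
    if (is.null(path) || !file.exists(path) || file.size(path) == 0L) {
      return(NULL)
    }
    parse_blast_tab(path, db)
  }
  tox_hits <- read_hits(config$blast_toxprot, "toxprot")
  met_hits <- read_hits(config$blast_metazoa, "metazoa")
  ipr <- if (!is.null(config$interpro) && file.exists(config$interpro)) {
    utils::read.delim(config$interpro, stringsAsFactors = FALSE)
  } else NULL

  best_for <- function(hits, id) {
    if (is.null(hits)) return(NULL)
    h <- hits[hits$query_id == id & !hits$sub_threshold, , drop = FALSE]
    select_best_hit(h)
  }
  keywords <- default_keyword_tables()
  annotations <- lapply(kept, function(rec) {
    terms <- if (!is.null(ipr)) {
      ipr$description[ipr$precursor_id == rec$id]
    } else character()
    classify(rec, best_for(tox_hits, rec$id), best_for(met_hits, rec$id),
             terms, keywords, config$filter)
  })
  names(annotations) <- kept_ids

  # --- family clustering and rational names ----------------------------
  classes <- vapply(annotations, function(a) a$functional_class,
                    character(1L))
  ntx_ids <- kept_ids[classes == "putative_neurotoxin"]
  if (length(ntx_ids)) {
    matures <- vapply(records[ntx_ids], mature_peptide, character(1L))
    fam <- cluster_families(ntx_ids, matures)
    fam_tpm <- tapply(vapply(records[ntx_ids],
                             function(r) ifelse(is.na(r$tpm), 0, r$tpm),
                             numeric(1L)), fam, sum)
    fam_rank <- stats::setNames(rank(-fam_tpm, ties.method = "first"),
                                names(fam_tpm))
    for (f in unique(fam)) {
      members <- ntx_ids[fam == f]
      mt <- vapply(records[members],
                   function(r) ifelse(is.na(r$tpm), 0, r$tpm), numeric(1L))
      ord <- order(-mt, members)
      for (k in seq_along(ord)) {
        id <- members[ord[k]]
        annotations[[id]]$toxin_name <- assign_toxin_name(
          fam_rank[[as.character(f)]], config$species_code, k,
          activity_known = FALSE, multi_isoform = length(members) > 1L)
      }
    }
  }
  nov_ids <- kept_ids[vapply(annotations,
                             function(a) isTRUE(a$cysteine_rich_candidate),
                             logical(1L))]
  for (k in seq_along(sort(nov_ids))) {
    annotations[[sort(nov_ids)[k]]]$toxin_name <-
      assign_toxin_name(k, novel = TRUE)
  }

  # --- MALDI consensus and matching ------------------------------------
  consensus <- NULL
  matches <- NULL
  if (!is.null(config$spectra_index) && file.exists(config$spectra_index)) {
    idx <- utils::read.delim(config$spectra_index, stringsAsFactors = FALSE)
    base <- dirname(config$spectra_index)
    lists <- lapply(seq_len(nrow(idx)), function(i) {
      load_peaklist(file.path(base, idx$path[i]), idx$spectrum_id[i],
                    idx$specimen_id[i], config$mz_window)
    })
    consensus <- flag_reproducible(
      cluster_peaks(lists, config$cluster_tol), config$min_fraction)
    kept_products <- do.call(rbind, products[kept_ids])
    if (!is.null(kept_products) && nrow(kept_products)) {
      matches <- match_masses(kept_products, consensus, config$match_tol,
                              "da", config$mz_window)
    }
  }
  if (is.null(matches)) {
    matches <- data.frame(precursor_id = character(), label = character(),
                          sequence = character(), theoretical_mh = numeric(),
                          peak_mz = numeric(), delta_da = numeric(),
                          delta_ppm = numeric(), occurrence = integer(),
                          reproducible = logical(), ambiguous = logical())
  }

  # --- disulfide assignment from structures ----------------------------
  bridges <- list()
  if (!is.null(config$pdb_dir) && dir.exists(config$pdb_dir)) {
    for (id in kept_ids) {
      path <- file.path(config$pdb_dir, paste0(id, ".pdb"))
      if (!file.exists(path)) next
      model <- parse_structure(path, id)
      asg <- assign_bridges(sg_distance_matrix(model),
                            config$disulfide_threshold)
      asg$reconciled <- reconcile(
        asg, default_disulfides(mature_peptide(records[[id]])))
      bridges[[id]] <- asg
    }
  }

  # --- report tables ---------------------------------------------------
  toxin_table <- do.call(rbind, lapply(kept_ids, function(id) {
    a <- annotations[[id]]
    rec <- records[[id]]
    prods <- products[[id]]
    m <- matches[matches$precursor_id == id, , drop = FALSE]
    mature_prods <- prods[prods$label == "mature", , drop = FALSE]
    mh_shown <- if (nrow(m)) {
      sort(unique(round(m$theoretical_mh, 2)))
    } else {
      round(mature_prods$theoretical_mh[
        which.max(nchar(mature_prods$sequence))], 2)
    }
    best <- a$best_hit
    data.frame(
      precursor_id = id,
      name = ifelse(is.na(a$toxin_name), id, a$toxin_name),
      functional_class = a$functional_class,
      best_hit = if (!is.null(best)) best$subject_description else "",
      best_hit_id = if (!is.null(best)) best$subject_id else "",
      percent_identity = if (!is.null(best)) best$percent_identity
        else NA_real_,
      tpm = rec$tpm,
      ptm = ifelse(default_disulfides(mature_peptide(rec)) > 0, "C-C", ""),
      predicted_mh = paste(mh_shown[!is.na(mh_shown)], collapse = "/"),
      n_cysteines = a$n_cysteines,
      size_consistent = a$size_consistent,
      maldi_match = ifelse(any(m$reproducible %in% TRUE), "+", "-"),
      stringsAsFactors = FALSE)
  }))
  if (!is.null(toxin_table)) {
    toxin_table <- toxin_table[order(-ifelse(is.na(toxin_table$tpm), 0,
                                             toxin_table$tpm),
                                     toxin_table$precursor_id), ,
                               drop = FALSE]
    rownames(toxin_table) <- NULL
  }
  ann_df <- data.frame(
    precursor_id = kept_ids,
    functional_class = classes, stringsAsFactors = FALSE)
  class_table <- aggregate_expression(ann_df, tpm)
  gate_counts <- c(total = nrow(filt$report),
                   complete = sum(filt$report$complete),
                   signal = sum(filt$report$signal),
                   coverage = sum(filt$report$coverage_ok),
                   score = sum(filt$report$score_ok),
                   kept = sum(filt$report$kept))

  out <- list(records = records, sites = sites, products = products,
              filter_report = filt$report, kept = kept,
              annotations = annotations, toxin_table = toxin_table,
              class_table = class_table, gate_counts = gate_counts,
              consensus = consensus, matches = matches, bridges = bridges)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(toxin_table)) wt(toxin_table, "toxin_table.tsv")
    wt(class_table, "class_table.tsv")
    wt(filt$report, "filter_report.tsv")
    if (nrow(matches)) {
      wt(matches[, setdiff(names(matches), "members")], "matches.tsv")
    }
    jsonlite::write_json(
      list(toxin_table = toxin_table, class_table = class_table,
           gate_counts = as.list(gate_counts)),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
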