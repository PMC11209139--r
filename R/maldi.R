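# MALDI-TOF peak-list handling: loading, cross-spectrum consensus building,
# reproducibility flagging, and theoretical-mass matching.

#' Load a peak list from TSV
#'
#' @param path TSV with columns `mz` and `intensity`.
#' @param spectrum_id,specimen_id identifiers for the spectrum and the animal
#'   it was extracted from.
#' @param acquisition_range numeric length-2 m/z window of the acquisition.
#' @return object of class `lampyritox_peaklist`: list with `spectrum_id`,
#'   `specimen_id`, `peaks` (data.frame mz, intensity, sorted ascending) and
#'   `acquisition_range`. Rows with negative intensity are dropped with a
#'   warning; unsorted input is sorted.
#' @export
load_peaklist <- function(path, spectrum_id, specimen_id,
                          acquisition_range = c(800, 4500)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    tab <- data.frame(mz = numeric(), intensity = numeric())
  }
  stopifnot(all(c("mz", "intensity") %in% names(tab)))
  bad <- tab$intensity < 0
  if (any(bad)) {
    warning(sum(bad), " peak(s) with negative intensity dropped in ",
            spectrum_id)
    tab <- tab[!bad, , drop = FALSE]
  }
  tab <- tab[order(tab$mz), c("mz", "intensity"), drop = FALSE]
  rownames(tab) <- NULL
  structure(list(spectrum_id = spectrum_id, specimen_id = specimen_id,
                 peaks = tab, acquisition_range = acquisition_range),
            class = "lampyritox_peaklist")
}

#' Write a peak list to TSV
#' @param peaklist a `lampyritox_peaklist` or data.frame with mz, intensity.
#' @param path output path.
#' @export
write_peaklist <- function(peaklist, path) {
  peaks <- if (inherits(peaklist, "lampyritox_peaklist")) {
    peaklist$peaks
  } else peaklist
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build cross-spectrum consensus peaks
#'
#' Single-linkage clustering of all peaks pooled across spectra: peaks whose
#' m/z values chain within `tol_da` of their neighbour fall in one cluster.
#' Each spectrum contributes at most one member per cluster (the peak nearest
#' the intensity-weighted cluster mean wins); the occurrence count is the
#' number of distinct spectra represented. The result is independent of the
#' order in which spectra are supplied.
#'
#' @param lists list of `lampyritox_peaklist` objects.
#' @param tol_da single-linkage tolerance in Da (default 0.3).
#' @return data.frame of consensus peaks: `consensus_mz` (intensity-weighted
#'   mean of kept members), `occurrence`, `n_spectra`, `members` (list column
#'   of data.frames spectrum_id/mz/intensity), sorted by consensus m/z.
#' @export
cluster_peaks <- function(lists, tol_da = 0.3) {
  stopifnot(tol_da > 0)
  n_spectra <- length(lists)
  pool <- do.call(rbind, lapply(lists, function(pl) {
    if (nrow(pl$peaks) == 0L) return(NULL)
    data.frame(spectrum_id = pl$spectrum_id, mz = pl$peaks$mz,
               intensity = pl$peaks$intensity, stringsAsFactors = FALSE)
  }))
  empty <- data.frame(consensus_mz = numeric(), occurrence = integer(),
                      n_spectra = integer())
  if (is.null(pool) || nrow(pool) == 0L) {
    empty$members <- list()
    return(empty)
  }
  pool <- pool[order(pool$mz, pool$spectrum_id), , drop = FALSE]
  # 1D single linkage: a gap > tol_da between consecutive sorted m/z values
  # separates clusters
  cl <- cumsum(c(1, diff(pool$mz) > tol_da))
  out <- lapply(split(pool, cl), function(members) {
    wmean <- sum(members$mz * members$intensity) / sum(members$intensity)
    if (!is.finite(wmean)) wmean <- mean(members$mz)
    # one member per spectrum: nearest to the weighted mean wins
    keep <- unlist(lapply(split(seq_len(nrow(members)), members$spectrum_id),
                          function(idx) idx[which.min(abs(members$mz[idx] - wmean))]))
    members <- members[sort(keep), , drop = FALSE]
    wmean <- sum(members$mz * members$intensity) / sum(members$intensity)
    if (!is.finite(wmean)) wmean <- mean(members$mz)
    rownames(members) <- NULL
    data.frame(consensus_mz = wmean,
               occurrence = length(unique(members$spectrum_id)),
               n_spectra = n_spectra,
               members = I(list(members)))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$consensus_mz), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag reproducible consensus peaks
#'
#' A consensus signal is reproducible when it occurs in at least
#' `ceiling(min_fraction * n_spectra)` spectra — with the default 0.5 and 13
#' spectra that means at least 7.
#'
#' @param peaks data.frame from [cluster_peaks()].
#' @param min_fraction required fraction of spectra, in (0, 1].
#' @return the input with a logical `reproducible` column added.
#' @export
flag_reproducible <- function(peaks, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * peaks$n_spectra)
  peaks$reproducible <- peaks$occurrence >= need
  peaks
}

#' Match theoretical product masses against observed ions
#'
#' Each product whose theoretical [M+H]+ lies inside the m/z window is
#' compared against every peak; all pairs within tolerance are reported (a
#' product can match several peaks and vice versa; such matches are flagged
#' ambiguous). Products outside the window are not searched, mirroring the
#' instrument's acquisition range.
#'
#' @param products data.frame with `precursor_id`, `label`, `sequence`,
#'   `theoretical_mh` (see [product_mass_table()]).
#' @param peaks either a consensus data.frame from [cluster_peaks()] /
#'   [flag_reproducible()] or a single `lampyritox_peaklist`.
#' @param tol matching tolerance; Da when `tol_unit = "da"` (default 0.5),
#'   parts-per-million when `tol_unit = "ppm"`.
#' @param tol_unit "da" or "ppm".
#' @param mz_window numeric length-2 acquisition window (default 800-4500).
#' @return data.frame of matches: product identifiers, `peak_mz`,
#'   `delta_da`, `delta_ppm`, `occurrence`/`reproducible` when available,
#'   `ambiguous`.
#' @export
match_masses <- function(products, peaks, tol = 0.5, tol_unit = c("da", "ppm"),
                         mz_window = c(800, 4500)) {
  tol_unit <- match.arg(tol_unit)
  stopifnot(tol > 0)
  if (inherits(peaks, "lampyritox_peaklist")) {
    peaks <- data.frame(consensus_mz = peaks$peaks$mz,
                        occurrence = 1L, n_spectra = 1L,
                        reproducible = NA)
  }
  cols <- c("precursor_id", "label", "sequence", "theoretical_mh")
  stopifnot(all(cols %in% names(products)))
  rows <- list()
  for (i in seq_len(nrow(products))) {
    mh <- products$theoretical_mh[i]
    if (is.na(mh) || mh < mz_window[1L] || mh > mz_window[2L]) next
    tol_da <- if (tol_unit == "da") tol else tol * mh / 1e6
    if (nrow(peaks) == 0L) next
    hits <- which(abs(peaks$consensus_mz - mh) <= tol_da)
    for (j in hits) {
      rows[[length(rows) + 1L]] <- data.frame(
        precursor_id = products$precursor_id[i],
        label = products$label[i],
        sequence = products$sequence[i],
        theoretical_mh = mh,
        peak_mz = peaks$consensus_mz[j],
        delta_da = peaks$consensus_mz[j] - mh,
        delta_ppm = (peaks$consensus_mz[j] - mh) / mh * 1e6,
        occurrence = if ("occurrence" %in% names(peaks))
          peaks$occurrence[j] else NA_integer_,
        reproducible = if ("reproducible" %in% names(peaks))
          peaks$reproducible[j] else NA,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(precursor_id = character(), label = character(),
                      sequence = character(), theoretical_mh = numeric(),
                      peak_mz = numeric(), delta_da = numeric(),
                      delta_ppm = numeric(), occurrence = integer(),
                      reproducible = logical(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  prod_key <- paste(res$precursor_id, res$label, res$sequence)
  res$ambiguous <- prod_key %in% prod_key[duplicated(prod_key)] |
    res$peak_mz %in% res$peak_mz[duplicated(res$peak_mz)]
  rownames(res) <- NULL
  res
}
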