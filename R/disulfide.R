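# Disulfide-bridge assignment from predicted-structure coordinates.
#
# A covalent disulfide has an S-S bond length of about 2.05 Angstrom; the
# default assignment threshold of 2.5 A accepts modelling error around that
# value while a wider "proximal" tier (<= 4.5 A) is reported for cysteine
# pairs that are close but not bonded, and never counted as a bridge.

#' Parse a PDB structure file
#'
#' Reads a PDB file (via bio3d), extracting the residue sequence, the SG
#' (gamma sulfur) atoms of all cysteines, and the B-factor column as
#' per-residue confidence when present (predicted models store pLDDT
#' there). Cysteines lacking an SG atom are reported with a warning and
#' cannot be assigned to bridges.
#'
#' @param path PDB file path.
#' @param model_id identifier (defaults to the file name).
#' @return list of class `lampyritox_structure`: `model_id`, `residues`
#'   (data.frame resno, resid), `sg` (data.frame resno, x, y, z),
#'   `confidence` (named per-residue vector from B-factors of CA atoms),
#'   `unassignable_cys` (resno of cysteines without SG).
#' @export
parse_structure <- function(path, model_id = NULL) {
  if (is.null(model_id)) {
    model_id <- tools::file_path_sans_ext(basename(path))
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  ca <- at[at$elety == "CA", , drop = FALSE]
  residues <- data.frame(resno = ca$resno, resid = ca$resid,
                         stringsAsFactors = FALSE)
  confidence <- stats::setNames(ca$b, ca$resno)
  cys_res <- residues$resno[residues$resid == "CYS"]
  sg <- at[at$elety == "SG" & at$resid == "CYS", , drop = FALSE]
  sg <- data.frame(resno = sg$resno, x = sg$x, y = sg$y, z = sg$z)
  sg <- sg[!duplicated(sg$resno), , drop = FALSE]  # at most one SG per CYS
  missing_sg <- setdiff(cys_res, sg$resno)
  if (length(missing_sg)) {
    warning("cysteine(s) without SG atom, unassignable: ",
            paste(missing_sg, collapse = ", "))
  }
  structure(list(model_id = model_id, residues = residues, sg = sg,
                 confidence = confidence, unassignable_cys = missing_sg),
            class = "lampyritox_structure")
}

#' Pairwise SG-SG distance matrix
#'
#' @param model a `lampyritox_structure`.
#' @return symmetric matrix of Euclidean distances (Angstrom) between the SG
#'   atoms of all assignable cysteines, dimnames = residue numbers; an empty
#'   matrix when fewer than two cysteines carry SG atoms.
#' @export
sg_distance_matrix <- function(model) {
  sg <- model$sg
  if (nrow(sg) < 2L) {
    return(matrix(numeric(), 0L, 0L))
  }
  m <- as.matrix(stats::dist(sg[, c("x", "y", "z")]))
  dimnames(m) <- list(sg$resno, sg$resno)
  m
}

#' Assign disulfide bridges by optimal distance matching
#'
#' Searches all disjoint pairings of cysteines whose SG-SG distance is at
#' most `threshold`, maximising the number of bridges and, among pairings of
#' equal size, minimising the total distance. Exhaustive enumeration is
#' cheap for the peptide scale involved (<= 12 cysteines). Pairs within
#' `proximal_threshold` but above `threshold` are reported separately and
#' never counted as bridges.
#'
#' @param dmat symmetric SG distance matrix from [sg_distance_matrix()].
#' @param threshold bridge distance cutoff in Angstrom (default 2.5).
#' @param proximal_threshold reporting-only cutoff (default 4.5).
#' @return list of class `lampyritox_disulfides`: `pairs` (data.frame cys_i,
#'   cys_j, sg_distance), `n_bridges`, `free_cysteines`, `proximal_pairs`.
#' @export
assign_bridges <- function(dmat, threshold = 2.5, proximal_threshold = 4.5) {
  stopifnot(threshold > 0)
  n <- nrow(dmat)
  ids <- if (n) rownames(dmat) else character()
  empty_pairs <- data.frame(cys_i = character(), cys_j = character(),
                            sg_distance = numeric(),
                            stringsAsFactors = FALSE)
  if (n < 2L) {
    return(structure(list(pairs = empty_pairs, n_bridges = 0L,
                          free_cysteines = ids,
                          proximal_pairs = empty_pairs),
                     class = "lampyritox_disulfides"))
  }
  # exhaustive branch-and-take over disjoint admissible pairs
  best <- list(count = -1L, total = Inf, pairs = NULL)
  search <- function(avail, pairs, total) {
    if (length(avail) < 2L) {
      count <- nrow(pairs)
      if (count > best$count ||
          (count == best$count && total < best$total)) {
        best <<- list(count = count, total = total, pairs = pairs)
      }
      return()
    }
    i <- avail[1L]
    rest <- avail[-1L]
    # option 1: leave cysteine i unpaired
    search(rest, pairs, total)
    # option 2: pair i with each admissible partner
    for (j in rest) {
      d <- dmat[i, j]
      if (d <= threshold) {
        search(setdiff(rest, j),
               rbind(pairs, data.frame(cys_i = ids[i], cys_j = ids[j],
                                       sg_distance = d,
                                       stringsAsFactors = FALSE)),
               total + d)
      }
    }
  }
  search(seq_len(n), empty_pairs, 0)
  pairs <- best$pairs
  used <- c(pairs$cys_i, pairs$cys_j)
  prox <- empty_pairs
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- dmat[i, j]
    if (d > threshold && d <= proximal_threshold) {
      prox <- rbind(prox, data.frame(cys_i = ids[i], cys_j = ids[j],
                                     sg_distance = d,
                                     stringsAsFactors = FALSE))
    }
  }
  structure(list(pairs = pairs, n_bridges = nrow(pairs),
                 free_cysteines = setdiff(ids, used),
                 proximal_pairs = prox),
            class = "lampyritox_disulfides")
}

#' @export
print.lampyritox_disulfides <- function(x, ...) {
  cat("Disulfide assignment:", x$n_bridges, "bridge(s)\n")
  if (x$n_bridges) {
    for (k in seq_len(nrow(x$pairs))) {
      cat(sprintf("  C%s - C%s  %.2f A\n", x$pairs$cys_i[k],
                  x$pairs$cys_j[k], x$pairs$sg_distance[k]))
    }
  }
  if (length(x$free_cysteines)) {
    cat("  free cysteines:", paste(x$free_cysteines, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconcile structural and proteomic disulfide counts
#'
#' Mass spectrometry constrains the number of bridges (each bridge removes
#' 2.01565 Da); structure models can disagree, particularly for divergent
#' scaffolds the predictor has not seen. This reports concordance between
#' the two counts without privileging either.
#'
#' @param assignment a `lampyritox_disulfides`.
#' @param proteomic_n_bridges bridge count implied by the mass data.
#' @return list: `structural_n`, `proteomic_n`, `concordant`.
#' @export
reconcile <- function(assignment, proteomic_n_bridges) {
  structural <- assignment$n_bridges
  list(structural_n = structural,
       proteomic_n = as.integer(proteomic_n_bridges),
       concordant = structural == proteomic_n_bridges)
}

#' Write a minimal PDB file for a peptide backbone with SG atoms
#'
#' Utility used by the synthetic-data generator and tests: writes CA atoms
#' for every residue and SG atoms for cysteines at supplied coordinates.
#'
#' @param sequence amino-acid string.
#' @param sg_coords data.frame with `resno`, `x`, `y`, `z` for cysteine SG
#'   atoms.
#' @param path output path.
#' @param ca_coords optional data.frame of CA coordinates (defaults to a
#'   straight chain 3.8 A apart along x).
#' @param bfactor per-residue confidence written to the B-factor column.
#' @export
write_toy_pdb <- function(sequence, sg_coords, path, ca_coords = NULL,
                          bfactor = 90) {
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  if (is.null(ca_coords)) {
    ca_coords <- data.frame(resno = seq_len(n), x = 3.8 * seq_len(n),
                            y = 0, z = 0)
  }
  bf <- rep_len(bfactor, n)
  lines <- character()
  serial <- 0L
  fmt <- function(serial, name, res3, resno, x, y, z, b) {
    # strict PDB column layout (name right-padded in cols 13-16, chain A)
    paste0("ATOM  ", sprintf("%5d", serial), " ",
           sprintf("%-4s", paste0(" ", name)), " ",
           sprintf("%3s", res3), " A", sprintf("%4d", resno), "    ",
           sprintf("%8.3f%8.3f%8.3f", x, y, z),
           sprintf("%6.2f%6.2f", 1, b),
           "          ", sprintf("%2s", substr(name, 1L, 1L)))
  }
  for (i in seq_len(n)) {
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, "CA", aa3[[aa[i]]], i,
                          ca_coords$x[i], ca_coords$y[i], ca_coords$z[i],
                          bf[i]))
    if (aa[i] == "C") {
      row <- sg_coords[sg_coords$resno == i, , drop = FALSE]
      if (nrow(row) == 1L) {
        serial <- serial + 1L
        lines <- c(lines, fmt(serial, "SG", "CYS", i,
                              row$x, row$y, row$z, bf[i]))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
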