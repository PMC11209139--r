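#' Monoisotopic mass constants
#'
#' Monoisotopic residue masses (Da) for the 20 standard amino acids, together
#' with the water, proton, disulfide and amidation deltas used throughout the
#' package. Residue masses are derived from elemental compositions with
#' monoisotopic atomic masses (H = 1.00782503207, C = 12, N = 14.0030740048,
#' O = 15.9949146196, S = 31.97207100).
#'
#' @format A named list with components:
#' \describe{
#'   \item{residues}{named numeric vector, one entry per standard residue (Da)}
#'   \item{water}{mass of H2O added to the residue sum for a neutral peptide (Da)}
#'   \item{proton}{proton mass, added for the singly charged [M+H]+ ion (Da)}
#'   \item{disulfide_delta}{mass lost per disulfide bridge (2 H, Da)}
#'   \item{amidation_delta}{mass lost on C-terminal amidation (OH -> NH2, Da)}
#' }
#' @export
mass_constants <- list(
  residues = c(
    G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
    V = 99.06841390, T = 101.04767846, C = 103.00918478, L = 113.08406396,
    I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
    K = 128.09496300, E = 129.04259308, M = 131.04048490, H = 137.05891186,
    F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294
  ),
  water = 18.01056468,
  proton = 1.00727646688,
  disulfide_delta = 2.01565006,
  amidation_delta = 0.98401558
)

#' Neutral monoisotopic mass of a peptide
#'
#' Sums standard monoisotopic residue masses and adds one water, giving the
#' neutral, fully reduced (no disulfide) monoisotopic mass.
#'
#' @param seq single amino-acid string using the 20 standard one-letter codes.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptide_monoisotopic_mass("G")  # glycine, 75.032 Da
#' @export
peptide_monoisotopic_mass <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.na(seq) || !nzchar(seq)) {
    stop("empty peptide sequence: mass is undefined")
  }
  aa <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- mass_constants$residues[aa]
  if (anyNA(m)) {
    bad <- unique(aa[is.na(m)])
    stop("mass-incomputable residue(s) in peptide: ",
         paste(bad, collapse = ", "))
  }
  sum(m) + mass_constants$water
}

#' Theoretical [M+H]+ of a processed peptide product
#'
#' Computes the singly protonated monoisotopic ion mass of a peptide with a
#' given number of disulfide bridges (each bridge removes two hydrogens,
#' 2.01565 Da) and optional C-terminal amidation (-0.98402 Da).
#'
#' @param seq amino-acid string (20 standard residues).
#' @param n_disulfides number of disulfide bridges; requires at least
#'   `2 * n_disulfides` cysteines in `seq`.
#' @param amidated logical; apply the C-terminal amidation delta.
#' @return [M+H]+ in Da.
#' @examples
#' mh_ion("ANCGLCPVFCKLGFHCTANGQRCC", n_disulfides = 3)
#' @export
mh_ion <- function(seq, n_disulfides = 0L, amidated = FALSE) {
  stopifnot(length(n_disulfides) == 1L, n_disulfides >= 0)
  n_cys <- count_cysteines(seq)
  if (2L * n_disulfides > n_cys) {
    stop("n_disulfides = ", n_disulfides, " requires ", 2L * n_disulfides,
         " cysteines but sequence has ", n_cys)
  }
  peptide_monoisotopic_mass(seq) -
    n_disulfides * mass_constants$disulfide_delta -
    (if (isTRUE(amidated)) mass_constants$amidation_delta else 0) +
    mass_constants$proton
}

#' Count cysteine residues in a sequence
#'
#' @param seq amino-acid string.
#' @return integer number of 'C' residues.
#' @export
count_cysteines <- function(seq) {
  if (is.na(seq) || !nzchar(seq)) return(0L)
  sum(strsplit(seq, "", fixed = TRUE)[[1L]] == "C")
}

#' Default disulfide count under the all-cysteines-paired assumption
#'
#' Venom-peptide precursors are assumed fully oxidized: every cysteine
#' participates in a bridge, so the bridge count is `floor(#C / 2)`; an odd
#' cysteine count leaves one free thiol.
#'
#' @param seq amino-acid string.
#' @return integer number of disulfide bridges.
#' @export
default_disulfides <- function(seq) {
  count_cysteines(seq) %/% 2L
}

#' Tabulate theoretical masses for peptide products
#'
#' @param products data.frame of peptide products as produced by
#'   [enumerate_products()], with columns `precursor_id`, `label`, `sequence`,
#'   `n_disulfides`, `amidated`.
#' @return the same data.frame with `neutral_mass` and `theoretical_mh`
#'   columns appended; products containing non-standard residues (e.g. 'X'
#'   from ambiguous codons) get `NA` masses and `mass_computable = FALSE`.
#' @export
product_mass_table <- function(products) {
  stopifnot(is.data.frame(products),
            all(c("sequence", "n_disulfides") %in% names(products)))
  amid <- if ("amidated" %in% names(products)) products$amidated else FALSE
  n <- nrow(products)
  neutral <- rep(NA_real_, n)
  mh <- rep(NA_real_, n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      neutral[i] <- peptide_monoisotopic_mass(products$sequence[i])
      mh[i] <- mh_ion(products$sequence[i], products$n_disulfides[i],
                      if (length(amid) > 1L) amid[i] else amid)
      TRUE
    }, error = function(e) FALSE)
    ok[i] <- res
  }
  products$neutral_mass <- neutral
  products$theoretical_mh <- mh
  products$mass_computable <- ok
  products
}
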