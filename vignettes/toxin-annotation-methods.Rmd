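---
title: "Methods: annotating putative neurotoxins in firefly midgut secretions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating putative neurotoxins in firefly midgut secretions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lampyritox)
```

## The inference problem

Snail-hunting firefly larvae inject a midgut secretion that digests and
apparently paralyzes their prey. The paralyzing candidates are short
(roughly 3–12 kDa), cysteine-rich secreted peptides, and no single data
type identifies them: transcripts provide candidate precursors, proteomic
fragment spectra tie transcripts to actually secreted protein, MALDI-TOF
ion signals of the intact secretion reveal which processed forms circulate,
and homology plus predicted structure suggest function. `lampyritox`
formalises the chain of inferences joining these data. This vignette
explains each model and the choices behind it; the package's test suite
computes every number cited here.

## Precursor model

A secreted peptide precursor is signal peptide + optional propeptide +
mature peptide. The package reconstructs precursors from contigs in two
steps:

* **ORF discovery** (`find_orfs()`): every ATG-initiated reading frame in
  all six frames, translated to the first in-frame stop. Each ATG yields
  one ORF deliberately — the data, not the scanner, should decide the true
  start, because toxin precursors are short (~50–120 residues) and an
  aggressive "longest ORF per contig" rule would silently drop them. The
  default length floor is 40 residues for the same reason. Nucleotide
  spans are 0-based half-open on the forward strand; residue spans
  everywhere else are 1-based inclusive, the convention in which precursor
  tables are printed.
* **Segmentation** (`segment_precursor()`): the signal span ends at the
  annotated signal-peptidase site (annotations are consumed from a
  SignalP-style table; probability ≥ 0.5 counts as "signal present", since
  such predictors emit calibrated probabilities and a coin-flip is the
  natural indifference point). Cleavage sites, when present, end the
  propeptide; otherwise the mature peptide begins directly C-terminal to
  the signal peptide. The three spans always tile the protein exactly — a
  property the suite asserts on random precursors.

Codons containing ambiguous bases translate to `X`; any product containing
`X` is flagged mass-incomputable rather than approximated, because a wrong
mass is worse than a missing one.

## Cleavage motifs

Propeptides of venom peptides are removed by proteolysis C-terminal to
basic residues. Three motif classes are scanned (`scan_cleavage_sites()`),
with priority quadruplet > dibasic > monobasic at overlapping positions:

* **processing quadruplet motif**: arginine at −1 with glutamate at −2, −3
  or −4 (e.g. `VVER`, `VPER`);
* **dibasic**: `KR`, `RR`, `KK`, `RK`, cleaving after the pair;
* **monobasic**: a single R with no basic neighbour — a comparatively
  unusual maturation signal that several of these midgut peptides use.

Cleavage polarity is strictly C-terminal to the basic residue, which stays
on the propeptide fragment. This polarity is not arbitrary: it is the only
reading under which the printed mature masses of the monobasically cleaved
peptides are reproducible. All candidate sites are reported and all
corresponding products enumerated (`enumerate_products()`); downstream
MALDI evidence arbitrates, mirroring how prominent ion signals, not motif
heuristics, support processing claims.

## Mass model

`peptide_monoisotopic_mass()` sums standard monoisotopic residue masses
plus water; `mh_ion()` applies

\[ [M+H]^+ = M + 1.00728 - n_{SS}\cdot 2.01565 - a\cdot 0.98402 \]

with $n_{SS}$ disulfide bridges (two hydrogens lost each) and $a \in
\{0,1\}$ for C-terminal amidation. Amidation is off by default — the
study's data did not corroborate the candidate amidations — but exposed as
a flag. The default bridge count is the all-cysteines-paired assumption
$n_{SS} = \lfloor \#C/2\rfloor$, consistent with disulfide bridges being
the only confirmed modification class of these peptides; an odd cysteine
leaves one free thiol. Masses are never rounded internally. The suite
checks the residue table against an independent atom-by-atom
elemental-composition oracle on 1,000 random peptides (< 1e−4 Da) and
asserts additivity and monotonicity. Published theoretical masses computed
by other software deviate from first-principles recomputation by up to
~0.09 Da (different constants and rounding), so comparisons against
printed values use a ±0.15 Da band; the package itself reports full
precision.

## MALDI reproducibility and matching

Spectra arrive as peak lists (m/z, intensity). Consensus peaks across
spectra are built by single-linkage clustering in one dimension
(`cluster_peaks()`, default tolerance 0.3 Da): a gap larger than the
tolerance between adjacent sorted m/z values splits clusters, which makes
the result provably independent of spectrum order. Each spectrum
contributes at most one member per cluster (nearest to the
intensity-weighted mean wins), so occurrence counts distinct spectra. The
consensus m/z is the intensity-weighted mean — robust to weak shoulder
members; the median was considered and rejected as the default because it
discards the intensity information entirely.

A signal is **reproducible** when it occurs in at least
$\lceil f \cdot n \rceil$ spectra (`flag_reproducible()`, default
$f = 0.5$): with the 13-spectra design that means ≥ 7, the reading of "at
least half" under an odd denominator. Matching
(`match_masses()`) compares theoretical [M+H]⁺ against consensus peaks
within ±0.5 Da inside the m/z 800–4500 acquisition window. The 0.5 Da
default reflects calibration drift of reflectron MALDI-TOF at m/z
2000–4500 while still excluding the monoisotopic peaks of different
peptides; it is configurable in Da or ppm, and is deliberately separate
from the tighter clustering tolerance (cross-spectrum scatter of one
compound is smaller than absolute calibration error). Products outside
the window are never searched — large toxins are simply invisible to this
acquisition, and reporting "no match" for them would conflate absence of
evidence with evidence of absence.

## Homology classification and quality gates

BLAST hits (tabular, with query and subject lengths) are filtered by
per-database E-value ceilings — 1e−5 for the general Metazoa database,
1e−2 for the curated animal-toxin set, which is small and diverged enough
that informative hits can be weak. The best hit is selected among the ten
lowest E-values by maximal **accordance**,

\[ \mathrm{acc} = \frac{\ell_{aln}}{\ell_{query}} \cdot
   \frac{\ell_{aln}}{\ell_{subject}}, \]

the product of the bidirectional alignment-length fractions: symmetric in
query and subject, maximal only at full-length mutual coverage, and
penalising both partial alignments and length-mismatched subjects. Ties
break by lower E-value, then subject id, so selection is deterministic;
the suite checks it against brute-force enumeration on 500 random hit
lists.

A precursor is called a **putative neurotoxin** when toxin-similarity
evidence exists (passing toxin-database hit or a toxin-family InterPro
domain) *and* its mature peptide has at least four cysteines. Whether the
mature mass falls in the 3–12 kDa range observed for this peptide class is
reported as a consistency flag, never used as a gate — it is a property of
the described dataset, not a law. Hydrolase, odorant-binding and
housekeeping classes come from keyword tables shipped as editable
configuration (`inst/extdata/class_keywords.tsv`), not code. Precursors
with no passing hit and no domain call are **novel**; cysteine-rich novel
peptides are flagged as toxin candidates.

Quality gates (`apply_filters()`) keep precursors that are complete (start
methionine and stop codon), signal-bearing, with transcript–proteome
coverage ≥ 7% and best PSM score −10lg(P) ≥ 30. All thresholds are
inclusive ("at least"), and the precursor-level score is the *maximum* PSM
score — the least destructive reading of a per-run score gate. Every
rejection lists its failed gates, so counts at every gate are recoverable.

Toxin families for naming group mature peptides with identical cysteine
frameworks and ≥ 50% identity (single linkage). Identity is computed from
the Levenshtein edit distance ($1 - d/\max(|a|,|b|)$); family members are
near-identical isoforms, so this approximation is tight where it matters
and avoids any dependence on alignment scoring matrices. Names follow
rational venom nomenclature: `U-` (unknown activity) + `Lampyristoxin` +
species code + family number (by descending summed expression) + isoform
letter (by descending tpm, ties by id); hit-less cysteine-rich compounds
become `NLVC n`.

## Disulfides from structure

Given predicted coordinates, cysteine SG–SG distances are computed and
bridges assigned by exhaustive search over disjoint pairings
(`assign_bridges()`): maximise bridge count, then minimise total distance.
Greedy pairing was rejected because clustered cysteines can make it
mis-pair; exhaustive matching is cheap at peptide scale (≤ 12 cysteines,
≤ 10,395 pairings). The default threshold is 2.5 Å around the covalent
S–S bond length of ~2.05 Å; pairs within 4.5 Å are reported as "proximal"
but never counted. Per-residue confidence (B-factor column, where
predicted models store pLDDT) is echoed in the report without gating —
structure predictors are known to miss disulfide connectivity for
divergent scaffolds, which is exactly why `reconcile()` reports
concordance with the mass-derived bridge count instead of trusting either
side.

## The synthetic cohort

`synthetic_truth()` fixes the study conditions the generator emulates: 13
spectra from 4 specimens, m/z jitter σ = 0.05 Da (well inside the matching
tolerance, outside exactness), ~30 uniform noise peaks per spectrum with
exponential intensities (the simplest model that exercises reproducibility
filtering), planted reproducible products present in 7–13 spectra, and a
log-normal expression model whose dominant toxin family exceeds the median
family more than tenfold. The published per-specimen extraction counts
(1, 5, 3, 3) sum to 12 although 13 spectra are described; the generator
keeps the 13-spectrum total — it anchors the ⌈13/2⌉ = 7 reproducibility
rule — and uses (1, 5, 4, 3). One root seed derives per-section streams,
and identical seeds give byte-identical bundles.

The precursor roster mixes three neurotoxin families covering all three
motif classes plus direct post-signal cleavage, two cysteine-rich novel
singletons, and hydrolase/odorant-binding/housekeeping background.
Contigs embed each precursor with start and stop codons between short
UTRs; UTRs avoid G so no spurious ATG can start there, and synonymous
codon choices are resampled until the planted ORF is the unambiguous
maximal ORF of its contig — the generator guarantees identifiability so
that recovery failures indict the pipeline, not the fixture. Toy PDB
files place SG atoms of planted bridge pairs 2.05 Å apart.

What the generator does *not* emulate: isotope envelopes and peak shape,
chimeric or fragmented assemblies, sequencing error, shared peptides
between paralogs, FDR structure in PSM scores, and homology that is
borderline rather than clear-cut. Passing the replay therefore shows the
pipeline's logic is correct under the stated statistical structure — not
that real cohorts will be as clean.

## Problem sizes and numerical choices

The shipped suite replays one ~20-precursor cohort with 13 spectra
(seconds), checks mass equivalence on 1,000 random peptides, best-hit
selection on 500 random lists, and pairing optimality for up to 8
cysteines — sizes at which the independent oracles are exact and fast.
Degenerate inputs are defined, not accidental: empty peptides and unknown
residues raise errors; empty peak lists, empty hit lists and cysteine-free
products flow through as valid empties; cysteines without SG atoms are
reported unassignable rather than guessed.

## Known limitations

* ORF selection inside `run_pipeline()` prefers complete, longer ORFs;
  genuinely truncated 5′ ends (observed for one printed precursor) are
  kept as annotated rather than repaired.
* Edit-distance identity slightly underestimates alignment identity for
  diverged pairs; families near the 50% boundary could split. The
  threshold interacts with the identical-framework requirement, which does
  most of the discriminating.
* The keyword classifier is transparent but shallow; it will misclassify
  descriptions that avoid its vocabulary.
* MALDI matching at ±0.5 Da cannot distinguish near-isobaric products; all
  matches are reported with an ambiguity flag instead of being resolved.
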