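---
title: "Discovering intron gain events with marked-protein alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering intron gain events with marked-protein alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgain)
```

## The problem

Spliceosomal introns are routinely lost over evolutionary time, but the
appearance of an *entirely new* intron in a lineage is rare and hard to
document. Given a focal species (in practice, human with one canonical
transcript per protein-coding gene) and annotated orthologs across many
related genomes, we want to (i) find introns of the focal species that are
missing from most orthologs, (ii) place the gain on the species taxonomy,
and (iii) test whether the gain arose by **intronization** — a stretch of
formerly coding exon becoming spliced out, which shortens the protein by one
third of the intron's nucleotide length without shifting the reading frame.

`introgain` implements this comparative pipeline together with a gene-family
simulator that plants gains, losses, paralogs and intronization events with
full ground truth, so every stage can be validated end to end at desk scale.

## The method

**Intron marking.** Each intron is projected into protein coordinates: with
`c` coding nucleotides upstream of the intron, its phase is `c mod 3` and an
`X` character is inserted immediately to the left of residue
`floor(c/3) + 1` (for phase 0 this places the marker between complete
codons; mid-codon introns sit left of the interrupted residue). Removing the
markers recovers the original sequence exactly, and the marker alphabet is
scored zero against every residue, so markers neither attract nor repel the
alignment — coincident introns co-align because their flanking residues do.

**Orthologs.** For each focal protein, the single best hit per species is
kept among hits with significance at most $10^{-6}$. Significance is a
Karlin–Altschul E-value emulation, $E = K m n e^{-\lambda S}$, on the raw
Smith–Waterman score (BLOSUM62, gap open 11, extend 1) with ungapped
constants $\lambda = 0.3176$, $K = 0.134$. Since gapped alignments reuse
ungapped constants this quantity is a ranking and threshold device, not a
calibrated statistic; an import hook (`import_hit_table()`) accepts tabular
output of real BLASTP runs for full-scale work.

**Presence matrix.** Marked proteins are aligned progressively (pairwise
identity distances, average-linkage guide tree, affine-gap profile–profile
merges; deterministic for a fixed input order), or an externally produced
alignment is attached with `import_alignment()`. For each focal `X` column,
every ortholog is `present` (an `X` within the column tolerance, default 0 =
exact column, the strictest reading of "same position"), `uncovered` (the
ortholog has no residue on one side of the column, i.e. the position falls
beyond its annotated start or end), or `absent`.

**Gain clade.** For one intron, let $R$ and $B$ count in-clade species whose
ortholog has, respectively lacks, the intron at the aligned position
(uncovered species count in neither; the focal species always counts in
$R$). The gain point is the clade maximizing $R - B$. Only clades containing
the focal species can explain a focal intron, and those are exactly the
nodes on the path from the focal leaf to the root, so the search is a single
pass over at most `depth(tree)` nodes. Ties break toward the smallest clade
— the most recent origin consistent with the data.

**Filters.** A candidate must be absent from at least 70% of all species
with an ortholog (`>=`, so exactly 70% passes; uncovered species count in
the denominator only). Events supported mainly by uncovered orthologs are
excluded when the uncovered fraction among non-clade species exceeds 0.50
(strict inequality; the cutoff operationalizes the exclusion of gains
falling beyond annotated protein boundaries and is exposed as a parameter).
A species whose ortholog lacks the intron but that has a paralog carrying it
at the matching position is re-marked as present, and the clade and the 70%
rule are recomputed — this rescue is idempotent. Finally, introns spanned by
an exon of an alternative transcript are flagged as potential
intron-retention artifacts.

**Intronization.** For a gained intron, the two flanking exonic peptides
(default 50 residues each, truncated at protein ends) are aligned
independently against each ortholog lacking the intron. A candidate needs
both flanks significant, in order, with a positive gap $g$ between the
matched regions; $g$ is compared with the expected
`round(intron_length / 3)` residues within a tolerance of
`max(5, 0.2 * expected)` (the flanks are expected to be conserved while the
intronized segment drifts, so the tolerance absorbs modest indel drift).
The intron DNA is then translated in all three frames (stopping at stop
codons) and the best frame's local-alignment similarity against the
ortholog's gap segment is reported. Insertion of exonic sequence into
pre-existing introns is out of scope.

## The simulator

`simulate_taxonomy()` draws a pure-birth tree scaled to unit root-to-tip
depth (or uses a fixed, possibly multifurcating topology), so branch lengths
are fractions of total depth and node ages live in $[0, 1]$.
`simulate_gene_family()` evolves one ancestral gene along it:

* amino-acid substitutions per branch with probability
  $1 - e^{-\rho t}$ per site ($\rho$ = `substitution_rate`, replacement
  residues drawn from Robinson–Robinson background frequencies, codons
  re-encoded), intron interiors substituting at the same per-site rate at
  the nucleotide level;
* Dollo-style intron loss: per-branch Bernoulli with probability
  `loss_rate`, no regain. Planted gains are never lost on the path from the
  gain node to the focal leaf — the analysis, like the study design it
  emulates, ascertains introns present in the focal species;
* generic gains insert `GT...AG` intronic sequence at the gain node;
  intronization gains excise a planted ancestral coding segment (its splice
  dinucleotides are planted in the ancestral exon, and the codons overlapping
  them are held fixed so the signal is not destroyed by substitution),
  shortening carrier proteins by `intron_length/3` residues;
* optional paralogs: the parent-node state evolved over three times the
  terminal branch with independent loss draws, giving clearly more diverged
  decoys that may or may not carry planted introns (exercising the rescue
  filter both ways).

Every emitted gene satisfies `translate(splice(genome, model)) == protein`,
and fixtures written by `write_fixtures()` (FASTA, GFF3 1-based inclusive,
Newick, truth tables) round-trip through the package readers. Internally all
coordinates are 0-based half-open.

What the simulator does **not** emulate: indels in coding sequence,
codon-level selection, rate heterogeneity across sites, transposable-element
("Introner") insertions, annotation errors, and truncated or missing
ortholog annotations (the `uncovered` status is exercised with constructed
alignments instead). Passing tests therefore demonstrate correctness of the
machinery and realistic statistical behaviour under clean annotations, not
robustness to annotation noise in real genome databases.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 1e-6 | maximum ortholog/flank significance (read as $E \le 10^{-6}$) |
| `min_unaligned_frac` | 0.70 | minimum absent fraction for a candidate |
| `uncovered_cutoff` | 0.50 | maximum uncovered fraction among non-clade species |
| `tolerance` | 0 | column tolerance for "same intron position" |
| `flank_len` | 50 | residues per flank in the intronization scan |
| `tol_abs`, `tol_frac` | 5, 0.2 | gap-length tolerance `max(5, 0.2·expected)` |
| `loss_rate` | 0.02 | simulator per-branch loss probability (a calibration choice; vertebrate loss rates are not well constrained) |
| `substitution_rate` | 0.05 | expected substitutions/site per unit tree depth |

## Numerical and design choices

* Gap penalties follow the BLAST convention: a gap of length $k$ costs
  $11 + k$. Guide-tree ties are resolved by `hclust`'s deterministic merge
  order; profile-merge traceback prefers diagonal, then a gap in the first
  profile, making alignments reproducible for a fixed input order.
* `expected_gap_residues()` uses `round()` (nearest, ties to even); for
  intronization lengths, which are multiples of 3, the division is exact.
* A mark falling at or beyond the stop codon is rejected as out of range:
  protein coordinates exclude the stop, and UTR-only introns are ignored —
  the analysis lives entirely in protein space.
* The 70% filter is applied after clade selection, on the full ortholog set.
* Multifurcations are handled natively (no arbitrary resolution); the
  validation fixtures include an equidistant three-way split in the focal
  clade.
* Degenerate inputs: single-exon genes yield empty mark lists; a family
  with no orthologs rejects the event with a logged reason; empty peptide
  translations (immediate stops) give a flagged no-similarity result.

## Validation and problem sizes

The test suite validates, among other properties: exact agreement of the
clade search with brute-force enumeration over all focal-containing clades
on 200 random trees of up to 12 leaves (multifurcations included);
end-to-end recovery of planted gain clades on 50 simulated families of 20
species (loss 0.05, substitution 0.1, gains planted in recent clades of 4–8
species, the regime the alignment-based method targets) with recovery
$\ge 90\%$ and never a clade disjoint from the planted one; intronization
detection on 100 families at per-site substitution probability 0.3
($\ge 80\%$, and 100% without noise) with $\le 5\%$ false positives on
generic gains and exact reading-frame recovery for every significant
similarity; and exact reproduction of planted intron positions and phases
from the emitted annotations. `scripts/acceptance.R` recomputes these
quantities from scratch.

The dominant failure mode of clade recovery is honest: when a loss hits a
deep branch inside the planted clade, a smaller clade genuinely maximizes
$R - B$, and the smallest-clade tie-break keeps the estimate conservative
(asserting the latest origin consistent with the data). On real data the
same behaviour means an inferred gain clade is a lower bound on the true
gain clade when losses have occurred within it.

## Limitations

Known limitations beyond the simulator's scope: the E-value emulation is
not numerically comparable to BLAST E-values (search-space and
composition-based adjustments differ); the internal progressive aligner has
no iterative refinement, so very diverged families benefit from importing a
MUSCLE/MAFFT alignment; divergence dating only reads node ages supplied
with the tree; and structure-based corroboration of intronization is out of
scope.
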