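---
title: "Methods: IgL locus annotation and repertoire characterization with iglkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IgL locus annotation and repertoire characterization with iglkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iglkit)
```

## Scope and model

Immunoglobulin light chains (IgL) are encoded by loci whose germline anatomy
— variable (V), joining (J) and constant (C) gene segments, leader-peptide
exons and recombination signal sequences (RSS) — determines both the
rearranged repertoire a species can express and the isotype of the resulting
chain. Vertebrates carry up to five ancient IgL isotypes (kappa, lambda,
sigma, sigma-2, lambda-2), distinguishable by RSS spacer organization
(kappa-type loci pair a 12-nt spacer on V with a 23-nt spacer on J;
lambda-type loci the reverse), by characteristic CDR1/CDR2 length patterns,
and most decisively by phylogenetic clustering of their V and C domains.

iglkit implements the full desk-scale workflow for characterizing such loci
in a newly sequenced species:

1. **Germline annotation** (`findSegments`, `flagDefects`,
   `classifyOrganization`): locate C exons by local alignment to a reference
   panel, V exons by cross-subfamily similarity plus a downstream RSS and an
   upstream leader exon across an AG/GT intron, and J segments de novo from
   an adjacent RSS plus the 3' splice donor; flag pseudogenes; classify the
   locus as translocon, single V-J-C cluster, or non-rearranging.
2. **Repertoire QC and structure** (`assignPool`, `qcFilter`,
   `collapseUnique`, `clusterSubfamilies`, `inferAlleles`): pool 5'-RACE
   amplicons by best CL hit, discard frameshifted/stop-containing/truncated
   cDNAs, count unique sequences and J usage, cluster V genes into
   subfamilies at the 75% nucleotide-identity criterion, and infer gene
   versus allele status from variant-by-specimen co-occurrence under the
   diploid (at most two alleles per gene per animal) constraint.
3. **Junction analysis** (`decomposeJunction`, `summarizeJunctions`):
   partition observed V-J junctions into germline-derived, P- and
   N-nucleotides; an N-free repertoire is the signature of absent terminal
   deoxynucleotidyl transferase (TdT) at the time of rearrangement.
4. **CDR delineation** (`imgtAnnotate`, `cdrLengthProfile`): IMGT-style
   FR/CDR boundaries and per-isotype CDR length profiles.
5. **Expression** (`coverageDepth`, `expressionProportions`): mean
   transcriptome read depth per nucleotide of each CL reference, normalized
   to percentages (the bedtools-genomecov style of quantification).
6. **Phylogeny** (`filterColumns`, `pDistance`, `njTree`,
   `bootstrapSupport`, `assignIsotype`): 95% site-coverage column filtering,
   p-distances with pairwise deletion, neighbor joining, column-bootstrap
   supports, and isotype calls from the smallest supported clade shared with
   a labeled reference panel.
7. **Simulation** (`simConfig`, `genGermline`, `simulateRearrangements`,
   `simulateReads`, `simulateTranscriptome`, `evolvePanel`,
   `simulateVPanel`): synthetic loci, cDNAs, reads and panels with complete
   ground truth, so that every stage above is testable.

This is an analysis package: the R functions, `runPipeline()` (an
end-to-end simulate/annotate/repertoire/junction driver with a JSON run
manifest) and `scripts/acceptance.R` are the interface; there is no separate
shell tool.

## Parameters that matter

* **Alignment scoring** — nucleotide match +2 / mismatch −3, gap open 5 /
  extend 2; protein BLOSUM62, gap open 11 / extend 1 (Biostrings
  conventions, penalties positive). Percent identity is computed over
  columns where both sequences have a residue (`exclude_gap_columns`), the
  usual reading of "percent identical residues"; `count_gaps` is available.
  Published identity figures rarely state aligner settings, so small
  deviations from any particular printed value are expected.
* **RSS model** — consensus heptamer `CACAGTG`, nonamer `ACAAAAACC`;
  score = match count (0–16); `requireCAC` enforces the functionally
  critical first three heptamer positions; spacer 12 or 23 ± 1 nt. Flank
  classification uses `minScore = 10`; de novo J discovery uses a stricter
  13 because a J is called genome-wide from the RSS alone. A 12-spacer
  window can nest inside a genuine 23-spacer RSS (its nonamer window lands
  on the true nonamer), so overlapping J candidates are resolved by motif
  score.
* **Annotation thresholds** — C exons: ≥70% identity over ≥80% of the
  reference; V exons: ≥60% (within-isotype V identities sit near or above
  75%, cross-subfamily ones lower); leader search window 500 nt; exact
  AG/GT splice dinucleotides; segments may not span `NNN` assembly gaps.
  J coding length must fall in 30–60 nt, ending at the first in-window GT
  donor after the RSS heptamer (the same convention the simulator uses).
* **Repertoire QC** — pool assignment at ≥80% identity over ≥60% of the CL
  reference (CL domains of distinct isotypes are ≤~49% identical, so pools
  are well separated; two ~90%-identical CL subtypes of one isotype are
  kept apart by best-hit scoring). "Truncated" means the pre-CL region
  covers <95% of the pool's median pre-CL length — published pipelines
  discard truncated cDNAs without an operational definition, so one is
  fixed here. Amplicons are assumed to start at the leader/FR1 codon
  boundary, as full-length 5'-RACE products do; the frame is anchored on
  the CL match and extended 5'.
* **Subfamilies and alleles** — single-linkage clustering at 75% nucleotide
  identity defines V subfamilies; variants within 97% identity are
  candidate alleles of one gene (allelic variants differ by a few
  substitutions); gene count is the minimum packing of variants such that
  no specimen carries more than two alleles per gene (exact search up to 10
  variants per identity group, first-fit-decreasing beyond).
* **Junctions** — maximal germline assignment; a nucleotide explainable by
  both V and J goes to V (the ambiguous-overlap count is reported so the
  J-first convention can be recomputed); P-nucleotides require an untrimmed
  end and exact palindromy, at most 4 nt; the remainder is N. Deduplication
  for unique-sequence counting covers the region from the amplicon start
  through J (the pre-CL region), so clones sharing a V but using different
  J segments count as distinct.
* **Phylogeny** — site-coverage threshold 0.95, bootstrap 500 replicates,
  support display/call threshold 70% (all configurable). NJ joins the
  Q-minimal pair, ties broken by the smallest index pair; a negative
  pendant branch is clamped to zero with the deficit moved to its sister,
  so output branch lengths are non-negative while additive path lengths are
  preserved. "Nucleotide sequences after amino acid alignment" is supported
  by `backThreadCodons()`, which threads codons through a given protein
  alignment; the protein MSA itself is produced upstream by any aligner and
  is an input, not a product, of this package.

## What the simulator emulates — and what it does not

`genGermline()` builds scaffolds with the canonical anatomy: leader exon
(ATG-initiated, 19 codons), GT…AG intron, V exon (96 codons), RSS with the
configured spacer class, J segments (36 nt, starting with the GT dinucleotide
typical of RSS-proximal J ends) with upstream RSS and downstream splice
donor, and C exons (105 codons) behind an AG acceptor. V families are built
from independent random founders (between-family identity well below the 75%
criterion) mutated at codon level to a within-family identity of 0.92 by
default (≥0.85 enforced). Defects — in-frame stops, 1-nt frameshifts,
missing leader exons, disrupted RSS — are injected deliberately, never
stochastically, so pseudogene truth is exact. For "missing leader" the
would-be AG acceptor is scrubbed so that leader absence is a property of the
sequence rather than of chance flanking bases.

`simulateRearrangements()` draws V/J by configurable usage weights (e.g. a
9:1 J bias), trims geometrically (p = 0.25, capped at 6 nt), adds 1–2 nt
P-nucleotides with probability 0.2 per untrimmed end, and adds no
N-nucleotides by default — the no-TdT junction model in which junctional
diversity comes from trimming and P-additions only. Reads carry iid
substitution errors; transcriptome mixtures sample CL references at fixed
proportions with uniform start positions; `evolvePanel()` evolves coding
sequences along a tree by Poisson substitution counts, avoiding in-frame
stops.

Deliberate simplifications: substitution-only evolution (no indels), so CDR
lengths and frames are controlled exactly; no somatic hypermutation, UMIs,
chimeras or quality-score error profiles; single-scaffold loci; the splice
donor after a J is constrained to be the first in-window GT so annotation
truth is unambiguous. Passing tests therefore demonstrate correctness of the
algorithms under clean, fully known conditions — they do not demonstrate
robustness to assembly fragmentation, hypermutated repertoires or
polyploid allele complexity in real data.

## Synthetic stand-in panels

The published sequence panels this workflow was designed around (cloned cDNA
figures and supplementary alignments) are not redistributable inside the
package, and its acceptance checks therefore run on synthetic stand-ins
generated at the reported divergence scales: a conserved sigma-type VL pair
at ~10% amino-acid divergence (~90% identity), a J-CL pair at ~17% (~83%),
two CL subtypes of one isotype at ~10% nucleotide divergence (~90%), four
unrelated CL domains (cross-isotype identity ≤49%), and a 54-sequence V
panel in three families of 33/13/8 members. These exercise the same
computations (global alignment identity, single-linkage clustering) on
inputs with the same statistical structure; they are labelled synthetic
wherever they appear.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed (`GRanges`); exported GFF3 follows GFF
  conventions.
* Percent identity with zero compared columns is `NA`; empty sequences are
  errors, absence of an RSS is a value (`NULL`), not an error.
* `scanRSS` on sequences shorter than heptamer + 12 + nonamer returns an
  empty table.
* Identical-sequence alignments resolve no bipartitions; bootstrap supports
  are seed-deterministic and invariant to input row order.
* Reads tying across k references in `coverageDepth` count 1/k to each and
  are reported separately (`n_multi`); reference pairs with fewer than two
  mismatches in any read-length window are flagged unresolvable by
  `referenceResolvability`.
* Pool assignment ties break by alignment score then lexicographic label
  and are flagged ambiguous.

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on simulated data at
desk scale, chosen to keep each property statistically decisive: loci of
2–8 V segments; 150–2,000 rearrangements for junction and J-usage
statistics (binomial checks at three standard deviations); 20,000
transcriptome reads for the 85/11/3/1 expression design (recovered within
one percentage point); 54-sequence clustering panels; 4–12-taxon trees for
NJ exactness and a 15-taxon five-clade panel with 500 bootstrap replicates
for isotype assignment.

## Known limitations

* Leader-exon detection requires the AG acceptor directly at the V exon
  start and a GT donor with an ATG upstream within the search window; it
  reports presence/absence, not leader coordinates.
* V-segment functionality counts both with and without RSS integrity can be
  derived from the `defects` column; classification into locus organization
  uses the all-defects definition of "functional".
* `imgtAnnotate` transfers boundaries from one curated reference per
  isotype; highly diverged V domains (identity to every reference ≪50%)
  may anchor poorly — the per-call reference identity is reported so such
  cases can be filtered.
* `assignIsotype` walks rootward from each query; on an unrooted tree this
  treats the arbitrary root trifurcation as resolved context. With the
  recommended panel (≥2 references per isotype, all five isotypes present)
  this matches the intended "smallest supported homogeneous clade" reading.
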