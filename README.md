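# iglkit

Annotation and repertoire analysis of immunoglobulin light-chain (IgL) genes
in non-model vertebrates.

## The problem

Characterizing the IgL genes of a newly sequenced species means answering a
chain of linked questions from raw scaffolds and amplicon reads: where are
the V, J and C gene segments, and are they intact? Do their recombination
signal sequences (RSS) pair a 12-nt spacer on V with a 23-nt spacer on J
(kappa-type, "12/23") or the reverse (lambda-type, "23/12")? Is the locus a
translocon (many V, a bank of J, one C), a single V-J-C cluster, or a
non-rearranging gene? How many V subfamilies and genes does the expressed
repertoire use, and which sequence variants are alleles of one gene rather
than distinct genes? Do V-J junctions carry non-templated N-nucleotides
(evidence of TdT activity) or only germline-derived and palindromic
P-nucleotides? How much does each locus contribute to the expressed CL pool?
And finally: which of the five ancient IgL isotypes — kappa (κ), lambda (λ),
sigma (σ), sigma-2 (σ-2), lambda-2 (λ-2) — does each chain belong to?

iglkit implements this workflow end to end at desk scale, in the core
notation of the field:

* RSS detection: heptamer–spacer–nonamer motifs scored by match count
  against the `CACAGTG` / `ACAAAAACC` consensus; locus typing by the
  12/23 vs 23/12 spacer rule.
* V subfamilies: single-linkage clustering at the 75% nucleotide-identity
  criterion; allele/gene inference under the diploid constraint (at most
  two alleles per gene per specimen).
* Junction decomposition: an observed junction is partitioned as
  `V-retained | P | N | P | J-retained` with maximal germline assignment;
  P requires an untrimmed coding end and exact palindromy.
* CDR delineation: IMGT-style boundaries (CDR1 = positions 27–38, CDR2 =
  56–65, CDR3 = 105–117; anchors 1st-CYS 23, conserved-TRP 41, 2nd-CYS
  104, J-PHE/TRP 118).
* Expression: mean transcriptome read depth per nucleotide of each CL
  reference, normalized to percent of total (genomecov-style).
* Phylogeny: p-distance (`d = differing sites / compared sites`, pairwise
  deletion) after removing alignment columns with <95% site coverage;
  neighbor-joining trees; column-bootstrap supports; isotype assignment by
  the smallest supported clade shared with a labeled reference panel.

A synthetic-data module generates germline loci, rearranged cDNAs, amplicon
and transcriptome reads, and evolving sequence panels with complete ground
truth, so every stage is validated against known answers.

## Worked example

Simulate a kappa-type translocon locus (3 V families × 2 members, 2 J with
a 9:1 usage bias, 1 C), then annotate the scaffold, QC the amplicons, and
decompose every V-J junction:

```r
library(iglkit)

cfg <- simConfig(seed = 7, nVFamilies = 3, familySize = 2, nJ = 2,
                 rssType = "kappa", jWeights = c(9, 1))
res <- runPipeline(cfg, nRearrangements = 300, seed = 7)

res$locus
#> LocusModel 'sim_locus': translocon (kappa_type)
#>   segments: L=0 V=6 J=2 C=1
#>   functional: 9/9

res$pool
#> AmpliconPool 'C1': 98 sequences
#>   input=300 discarded(frameshift/stop/truncated)=202/0/0

res$uniques$n_unique
#> [1] 58
round(res$uniques$j_usage, 3)
#>    J1    J2
#> 0.898 0.102

res$junctions$summary$frac_with_N
#> [1] 0
```

Reading the output: all six planted V segments, both J and the C exon were
recovered and typed 12/23 (kappa); the locus classifies as a translocon.
Random exonucleolytic trimming makes about two thirds of simulated
rearrangements out of frame, and QC discards exactly those (202 of 300
here), mirroring the heavy frameshift attrition real amplicon pools show.
The J-usage estimate (0.898/0.102) recovers the planted 9:1 bias, and no
junction contains N-nucleotides because the simulator's default junction
model adds none — the signature expected when TdT is not expressed at the
time of rearrangement.

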