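---
title: "Characterizing dsRNA LA helper-virus genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing dsRNA LA helper-virus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lahelper)
```

## The biological problem

Killer yeasts carry a ~4.6 kb double-stranded RNA helper virus (V-LA)
whose capsid (Gag) and polymerase (Pol, expressed as a Gag-Pol fusion via
a -1 programmed ribosomal frameshift) maintain and replicate the
toxin-encoding M virus. High-throughput sequencing of these genomes
recovers, besides the classical ("canonical") genome, additional
nucleotides on both ends -- extra sequences that can carry repeats of the
viral genome itself (self-identity), near-palindromes that fold into stem
loops, and fragments of host rRNA or chromosomal sequence.

`lahelper` implements the complete characterization workflow for such
genomes: zone partitioning with the signed coordinate convention,
Gag/Pol/fusion annotation, thermodynamic discovery of the cis-acting stem
loops, extra-sequence analysis, and region-resolved comparative identity
analysis with neighbor-joining phylograms. A synthetic-genome simulator
with planted ground truth makes every stage testable without downloading
any sequence.

## Coordinate convention and partitioning

The canonical zone is numbered 1..N from the conserved 5' motif
(`GAAAAA` in most LA viruses; the homologous `AATTAA` in the
*Torulaspora* helper virus) to the 3' terminus of the canonical end motif
(`CCATATGC`-like). Extra nucleotides upstream are numbered (-)1, (-)2,
... toward the 5' terminus; extra nucleotides downstream are (+)1, (+)2,
... Internally all coordinates are plain 1-based absolute positions; the
signed convention is a presentation layer (`to_signed_coord()`,
`from_signed_coord()`, and labels like `C(-)14-A37` in reports), and all
file output (GFF3) is 1-based inclusive.

Motif anchoring must resolve two ambiguities:

* **Multiple motif occurrences.** The occurrence that maximizes the
  canonical length is chosen, subject to the extra zone being at most
  `max_extra` nucleotides (default 400 nt, comfortably above the longest
  extra zone reported for these viruses, 252 nt). Occurrences implying
  longer extras are treated as implausible and raise an
  `"ambiguous anchor"` error rather than silently guessing.
* **Novel genomes without the motif.** A genome whose canonical zone is
  defined by homology rather than by motif (the *Torulaspora* virus is
  the motivating case) can be partitioned by projecting the zone
  boundaries of an annotated reference through a global nucleotide
  alignment (`reference` argument); this mode takes precedence over motif
  anchoring when both are supplied.

Deposited records may or may not include the extra zones, so extras of
length zero are legal everywhere.

## ORF and frameshift model

`find_orfs()` reports, per stop codon and forward frame, the ORF from the
first `ATG` after the previous in-frame stop; the `end` coordinate
*excludes* the stop codon, so `end - start + 1 = 3 x protein length`.
Published ORF spans for these genomes are not multiples of three, so the
printed convention there is ambiguous; this package states one convention
and uses it consistently, which makes every coordinate testable.

The slippery site is the XXXYYYZ heptamer (three identical bases, three
identical bases, one more base). By default Y must be `A`/`T` and Z must
not be `G`, the composition of heptamers known to support efficient -1
frameshifting (`GGGUUUA` being the motivating example); `strict = FALSE`
relaxes this for exploratory scans.

`build_gagpol_model()` assembles the gene model: Gag is the longest
5'-proximal ORF of at least `min_gag_len` residues (default 400; Gag is
~680 aa in LA viruses, so this filters spurious ORFs while tolerating
heavy divergence); the annotated slippery site is the candidate nearest
to, and upstream of, the Gag stop; Pol is the longest ORF in frame
`(gag - 1) mod 3` overlapping or following the slippery site. The
residue-level splice of the fusion protein is defined explicitly, since
published descriptions leave it implicit: Gag codons ending at or before
the heptamer's last base are retained, and translation resumes in the -1
frame one nucleotide 5' of the next codon boundary, continuing to the Pol
stop. Re-initiation candidates are all in-frame `ATG`s strictly between
the Gag end and the Pol start. Note a structural consequence of
ATG-defined ORFs: because the -1 frame must be stop-free from the
frameshift point to the Pol stop, any in-frame `ATG` upstream of the
intended Pol start *is itself* the 5'-most ORF start, so the chosen Pol
ORF normally begins at the first in-frame `ATG` and the re-initiation
list is empty unless annotation places Pol downstream of other starts.

## Hairpin thermodynamics

Every cis-signal handled here is a simple stem loop, so folding is
restricted to single hairpins: nested structures with stacks, bulges and
interior loops up to 30 nt, hairpin loops of 3-30 nt, no multiloops, no
pseudoknots. The energy model is the standard nearest-neighbor set at
37 degrees C in 1 M NaCl, shipped as plain TSV tables
(`inst/extdata/energy/`): Watson-Crick and GU stack free energies,
loop-size-indexed initiation penalties, terminal-mismatch tables for
hairpin and interior loops, the interior-loop asymmetry (Ninio)
parameters, and the 0.5 kcal/mol terminal AU/GU penalty.

Numerical choices worth knowing:

* **Units.** Folding computes kcal/mol and reports both kcal/mol and
  kJ/mol (`dG_kJ = 4.184 x dG_kcal`); LA literature quotes kJ/mol.
* **Terminal mismatches are on by default.** Without them the 31-nt
  worked example below misses the published value by ~20%; with them it
  lands within a few percent. A flag (`terminal_mismatch = FALSE`)
  recovers the simpler stacking-only model.
* **Small interior loops.** The tabulated 1x1, 2x1 and 2x2 interior
  loops of the full model are scored by the generic
  initiation + asymmetry + mismatch formula instead of their dedicated
  tables. On the worked example this approximation changes the minimum
  free energy by ~0.1 kcal/mol; the declared 10% tolerance for comparing
  against published values absorbs parameter-set differences of this
  order (values published for these signals came from an earlier
  parameter generation).
* **Ties** between equal-energy hairpins break toward the smallest span,
  then the 5'-most position -- deterministic output for identical input.
* **Suboptimal enumeration** (`enumerate_hairpins()`) treats hairpins as
  distinct when their outermost pair differs, reporting the optimal
  structure per closing pair within 5% of the minimum (capped at 50),
  mirroring common suboptimality settings for these analyses.

The worked example -- the printed near-palindromic 31-mer from the 5'
region of the *Torulaspora* helper genome -- folds to a hairpin whose
loop holds the first four canonical nucleotides unpaired:

```{r fold}
h <- fold_hairpin("CACGTAGCTTTATTAATTAATATGCTACGTG")
h
kissing_pairs(h$loop_seq, h$loop_seq)
```

The loop (`AAUU`) is self-complementary in antiparallel orientation, so
two such loops can anneal into a four-base-pair kissing complex.

Signal discovery (`find_signal_stemloops()`) operationalizes the five
conserved features: the 5' motif within canonical 1-10; the AU-rich
element as the maximum-AU 15-nt window of the 5' UTR (published figures
mark this element only graphically, so the max-AU window is our explicit
operationalization; ties break 5'-most); the frameshift stem loop as the
best hairpin starting within 12 nt 3' of the heptamer; the packaging stem
loop as the best 20-30-nt hairpin in the 3' half of the canonical zone --
ranked by loop-sequence identity to a reference packaging loop when one
is supplied, because for this signal the loop sequence, not the stem, is
the conserved feature -- and the replication stem loop as the best
hairpin wholly within the last 40 canonical nucleotides. Published
coordinate sets for the packaging region are internally inconsistent
(nucleotide-change positions ~25 nt upstream of the quoted stem-loop
span), so the scan covers the whole 3' half rather than assuming either
span.

## Extra-sequence analysis

Self-identity (`find_self_identity()`) reports maximal exact matches of
at least 13 nt -- the shortest stretch reported for real genomes, and the
default minimum -- between windows overlapping either extra zone and the
canonical interior, requiring disjoint absolute intervals. Query windows
include 60 nt of adjacent canonical sequence because the motivating
repeat spans the zone boundary (14 nt in the extra zone + 37 nt of
canonical sequence). The implementation is k-mer seeding with maximal
extension, but its contract is the quadratic brute-force definition the
test suite enforces. `find_shared_stretches()` applies the same machinery
between the extra zones of two viruses.

`palindrome_scan()` reports arm pairs (left arm = reverse complement of
right arm up to `max_mismatch` mismatches, default 2) around loops of at
most `max_loop` nt, arms at least `min_arm` nt, arms ending on a matching
pair. Hits whose span is contained in a longer hit are dropped, and
same-span hits collapse to the largest arm.

Host matching (`match_host_sequences()`) runs Smith-Waterman local
alignment (through Biostrings, match +5 / mismatch -4, gap open 10 /
extend 0.5) of the extra zone plus flank against each host record on
both strands -- reverse-strand rRNA hits occur in real genomes -- and
filters by aligned length (>= 50) and percent identity (>= 85). With weak
gap-extension costs, chance local alignments of ~80% identity over a few
hundred columns exist between unrelated sequences; the identity threshold
is the guard against them.

## Comparative analysis

`pairwise_identity()` uses global affine-gap alignment (nucleotides:
match +5 / mismatch -4; amino acids: BLOSUM62; both gap open 10 / extend
0.5) and defines identity as identical columns over columns where both
sequences are non-gap, rounded to one decimal. Published identity values
for these viruses mix two aligner families (one for nucleotides, one for
proteins), so a +/-1.5-point tolerance is declared wherever printed
values are reproduced. Matrices are built from pairwise alignments, not a
multiple alignment: the result is then independent of input order and
insensitive to taxon sampling.

Region-resolved comparisons (`region_spec()` + `extract_region()`)
project a reference interval onto each target through the pairwise
alignment. Two conventions had to be fixed where descriptions are loose:
the highly conserved RdRp region is operationalized as the middle third
of the Pol domain by residue count, and the 19-aa variable region as the
residues immediately downstream of the cap-snatching histidine (reference
positions 155-173).

`nj_phylogram()` builds a neighbor-joining tree on `1 - identity/100`
distances. Labels are sorted before tree construction so the result does
not depend on input order; negative branch lengths (a known NJ artifact)
are clamped to zero with a warning.

## What the simulator emulates -- and what it does not

`simulate_genome()` emits an LA-like genome in which every annotation
target is planted and recorded: geometry presets mirror sequenced LA
genomes (14/4591/17 with full extra-sequence features; 187/4580/9 with a
178-nt host fragment), the slippery heptamer is codon-aligned `GGGTTTA`,
the -1 frame is stop-free from the frameshift point to the Pol stop, and
the three stem loops are built with GC-only arms. Design details that
make exact recovery provable rather than probable:

* Stops and spurious starts are removed from the random background by a
  repair pass that mutates one free base of each offending codon to `C`
  (no stop codon or `ATG` contains a `C`, so the pass terminates).
* An in-frame stop is planted 10 nt upstream of the slippery site and
  in-frame `ATG`s are excluded between it and the Pol start, so the Pol
  ORF provably begins at the planted `ATG`.
* Stem loops are flanked by pairing-inert guard zones (A/C-only, which
  cannot pair with A/C) so the minimum-free-energy hairpin cannot extend
  by chance into flanking sequence; self-identity copies carry mismatched
  flanking bases so planted matches are exactly maximal; host fragments
  are planted at the extra zone's 5' terminus and taken from the host
  record's 3' terminus so local alignments cannot extend on either side.
* Every emitted genome is validated by running the full annotation
  pipeline and comparing against the planted truth; an attempt that
  fails (e.g. a chance slippery heptamer downstream of the planted one)
  is re-drawn. Generation is deterministic per seed.

`evolve_family()` applies Jukes-Cantor substitutions along a guide tree
(Poisson-distributed counts per branch, uniform sites, uniform
replacement bases), avoiding planted feature intervals when protection is
on, and rejecting substitutions that would make a genome un-annotatable:
premature stops in the Gag frame or the -1 fusion frame, spurious
in-frame starts that would move the Gag or Pol start, and new slippery
heptamers between the planted one and the Gag stop. This mimics the
purifying selection that keeps real LA coding regions open, and it is
what allows simulated families at realistic divergence to remain fully
annotatable. Optional indels (geometric lengths, <= 10 nt) are confined
to unprotected non-coding canonical sequence (5' UTR filler and the
stretch between the Pol stop and the replication stem loop), and leaf
truths carry coordinates shifted accordingly. The default family tree
(`two_cluster_tree()`) reproduces the identity strata observed in real LA
virus sets: two tight clusters (>= 99% within) separated by a deeper
split.

The simulator deliberately does **not** emulate: sequencing error or
assembly artifacts; codon-usage or GC-content realism (backgrounds are
uniform random); rate heterogeneity, transition/transversion bias or
indel realism beyond the confined model; true rRNA sequence in the host
database (records are labelled `*_synthetic` and are random). Passing
tests therefore demonstrate algorithmic correctness on genomes with the
right architecture, not robustness to real sequencing noise or to
divergence patterns shaped by real selection.

## Problem sizes and reproducibility

The test suite and the analysis scripts run entirely on synthetic data:
genomes of ~4.6 kb, families of 8 leaves, folding oracle comparisons on
sequences up to 22 nt (exhaustive enumeration) and scan windows up to
~80 nt. The acceptance script recomputes the headline thermodynamic
quantity from the printed 31-mer input alone. Comparisons against the
deposited GenBank records are supported end to end
(`fetch_accessions()`, `load_accession()`) but never run implicitly:
fetching requires explicit network access, and the corresponding checks
fail with an explanatory message when records are absent rather than
silently passing.

## Known limitations

* Hairpin-only folding: no multiloops, pseudoknots, or partition-function
  ensembles; genome-wide minimum-free-energy folding is out of scope.
* The generic interior-loop approximation can differ from the fully
  tabulated model by a few tenths of kcal/mol on structures dominated by
  small asymmetric loops.
* ORF annotation is ATG-anchored; genomes whose Pol domain begins at a
  non-ATG homology boundary will have their Pol ORF reported from the
  first in-frame ATG instead.
* Identity values depend mildly on aligner parameters; the declared
  +/-1.5-point band reflects that, and no attempt is made to reproduce a
  specific aligner's output exactly.
* The host-matching step reports one best local alignment per record and
  strand; multiple disjoint fragments of the same host record require
  splitting the record.
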