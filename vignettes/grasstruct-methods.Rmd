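---
title: "Methods: gene-structure evolution and expression analysis with grasstruct"
author: "grasstruct authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-structure evolution and expression analysis with grasstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasstruct)
```

# Scope

grasstruct implements the comparative-genomics workflow used to
characterize small grass gene families such as the phytoene synthases
(PSY): homology scoring from tabular BLAST hits, exon–intron annotation
by spliced alignment, intron-loss inference by Dollo parsimony on a
species tree, sequence-signature scanning at loss breakpoints, promoter
cis-element scanning, and efficiency-normalized relative quantification
of qPCR data. A seeded synthetic-data generator emulates every input the
pipeline touches, so each step can be tested against planted ground
truth.

# Homology statistics: AL, CIP, CALP and COS/CNV/PAV

A BLAST comparison of a query gene against a genome returns a set of
local alignments (HSPs) per subject. Per query–subject pair the package
rebuilds a non-redundant alignment and computes

* **AL** (aligned length, bp): the sum of HSP lengths,
* **CIP** (cumulative identity percentage): $100 \sum_i \mathrm{id}_i / AL$,
* **CALP** (cumulative alignment length percentage): $AL / L_q$ with
  $L_q$ the query length,

so the best homolog is the one with the highest cumulative identity over
the longest cumulative coverage. HSPs may overlap on the query; each
query position must be counted once for CIP to be a true percentage and
CALP to stay at or below 1, so overlaps are resolved by trimming the HSP
with the lower identity fraction, rescaling its counts proportionally to
the retained span (rounded half up; ties trim the later-starting HSP).
The alternative of summing raw HSP lengths is available as
`overlapPolicy = "raw"` since published descriptions of such statistics
do not always say which convention was used. The trimming fixpoint is
verified against an independently coded brute-force resolver on all
small HSP sets in the test suite.

Conservation calls use two thresholds, `cipMin = 60` (percent) and
`calpMin = 0.7` (fraction), both configurable — they are conventional
stringency settings, not measured constants. Zero passing subjects give
**PAV** (presence–absence variant), one gives **COS** (conserved
orthologous pair), two or more within a tandem window of 5 gene
positions give **CNV** (tandem-duplicated copies), and dispersed
multiples resolve to the best-scoring subject (CALP, then CIP, then
lexicographic subject id).

# Exon–intron structure by spliced alignment

`splicedAlign()` anchors exact 15-nt seeds of the CDS on the genomic
template, merges them into colinear diagonal blocks (bridging seed gaps
of up to 50 nt caused by isolated mismatches), and chains blocks by
dynamic programming maximizing matched CDS coverage; introns only widen
the template, so diagonals must increase along the chain. Each
inter-block junction is then slid within a ±6 nt window to the split
maximizing the local match count; exact ties prefer a canonical GT..AG
intron, then GC..AG, then the leftmost position. Both strands are tried.
If fewer than 90% of CDS positions match (configurable), a structured
`grasstruct_no_structure` error is raised rather than a bad structure
returned. The homoeolog-divergence regime the defaults anticipate is a
few percent of substitutions; indels between CDS and its own genomic
template are not modelled (they do not occur in the data the pipeline
targets, where the CDS is derived from the same locus).

Intron records carry the donor and acceptor dinucleotides read off the
coding strand, the length, and the phase — the number of coding bases
upstream modulo 3, so a phase-1 intron interrupts a codon after its
first base. GT..AG is canonical; GC..AG is flagged as the well-known
non-canonical GC class that the spliceosome removes like a GT intron.

In-silico PCR (`insilicoPcr()`) reports every primer-pair product up to
10 kb, smallest first, with primer-inclusive product lengths (the
standard convention for reported amplicon sizes; a flag is not needed
because the primer coordinates are returned and the caller can subtract).
A binding site must match with at most `maxMismatches` mismatches and
the 3′-terminal base exactly, reflecting polymerase extension chemistry.

# Intron-site homology and Dollo parsimony

`mapIntronSites()` projects intron positions across orthologs through
codon-aware alignment: translated CDS are aligned globally (BLOSUM62,
gap open 10, extend 4 — mismatch-tolerant enough that a few diverged
codons at a fusion junction do not open spurious double gaps), and each
intron's anchor codon is mapped to the reference. Two introns are the
same ancestral site only when their projected nucleotide coordinate and
phase agree exactly; near-misses within one codon raise a warning but
are never merged, because intron sliding is contentious and conservative
non-merging avoids false homology. Cells where the reference codon has
no counterpart in a gene are `unalignable` (missing data), distinct from
`absent`.

`inferLossEvents()` applies Dollo parsimony with the gain fixed at the
root: a site is ancestrally present whenever any taxon retains it, and
losses are placed on the highest branches whose subtrees contain at
least one absent taxon and no present one. This is the minimum-loss
reconstruction; the test suite proves it equal to exhaustive enumeration
over all single-gain labelings for every presence pattern on 4-leaf
trees and on randomized 6-leaf patterns with missing data. Polytomies
need no special casing (losses fall on the polytomy's child edges), and
unalignable cells never force a loss. Adjacent sites lost on one branch
merge into a single event whose multiplicity of two or more is labeled
`mrna_mediated` — recombination with a reverse-transcribed spliced
transcript removes runs of neighbouring introns — while single-site
events stay `indeterminate` until the breakpoint scanner votes.

One ambiguity is irreducible: independent losses of the same site in two
sister clades leave a presence/absence matrix byte-identical to a single
loss on their parent branch, so no method can separate the scenarios and
parsimony reports the single deeper event. The recovery study
(`recoveryStudy()`) therefore reports loss-event recovery both strictly
(exact site and branch) and ambiguity-aware (the planted branch or a
parsimony-equivalent ancestor), together with a false-positive count; at
the study's default loss rate the ambiguity-aware rate is the criterion
and strict placement is reported alongside.

# Breakpoint signatures and mechanism classification

`scanBreakpointRepeats()` enumerates all direct and inverted repeat
pairs with one arm on each side of a fusion junction, arms within 15 nt
of it and at least 3 nt long (both configurable; the defaults are sized
to the 3-nt motifs like TGG|CCA seen at real deletion breakpoints). The
scanner is brute-force-equivalent by construction and tested as such on
random sequences up to 200 nt.

`classifyLossMechanism()` is a pure function of multiplicity and repeat
evidence: runs of two or more adjacent losses are `mrna_mediated`, a
single loss with a junction-spanning repeat is `repeat_mediated`
(replication slippage / illegitimate recombination), a single loss
without one is `simple_deletion`, and conflicting evidence is
`indeterminate`. What counts as *evidence* matters: 3-nt arms within a
15-nt window occur by chance at almost every junction (about
$169 \times 2/64 \approx 5$ expected chance pairs), so the recovery
study defines evidence as arms at least as long as the planted repeat
(5 nt) abutting the junction on both sides, where the chance rate is
$2/4^5 \approx 0.2\%$ per junction. Users scanning real junctions should
likewise require arms abutting the breakpoint.

`findTirElements()` detects MITE-like elements as spans of at most
800 nt bounded by terminal inverted repeats of at least 10 nt with at
most one mismatch (all configurable), merging overlapping candidates in
favour of the longest TIR. A perfect-TIR element is reverse-complement
symmetric at its termini, so insertion orientation is defined by a
canonical form of the interior sequence (lexicographic comparison with
its reverse complement): two copies of one element in opposite
orientations receive opposite flags.

`findExonDuplication()` aligns an exon locally (both orientations,
match +2 / mismatch −3, gap open 25 / extend 0.1) against the region
downstream of the stop codon. The cheap gap extension lets one long
internal deletion be bridged instead of truncating the alignment, while
the expensive opening stops chance micro-blocks from chaining; a copy
must reach 80% identity over aligned columns and span at least half the
query. The offset convention is the 1-based distance from the base after
the stop codon to the first aligned base of the copy. Deletions inside
the copy are read off the alignment's gap runs; because a deletion
between direct repeats can slide within the repeat, all
sequence-equivalent gap placements are scanned for an identical flanking
k-mer (k from 8 down to 4), the signature of illegitimate recombination.

`scanCisElements()` scans both strands for IUPAC consensus motifs; the
default table carries the ABA-response elements ABRE (core ACGTG), the
palindromic G-box (CACGTG) and the coupling elements CE1 and CE3 that
ABRE function requires. Published element names do not come with unique
consensus strings; these are the standard literature definitions and are
plain configuration. Positions are reported relative to the sequence 3′
end, the natural anchoring for promoters supplied as the region upstream
of the ATG.

# qPCR quantification

Amplification efficiency comes from a dilution standard curve:
$E = 10^{-1/\mathrm{slope}}$ of the least-squares fit of Cq against
log10 dilution; a slope of −3.3219 is perfect doubling ($E = 2$). The
single-sample expression measure is the normalized ratio
$E_T^{-Cq_T} / E_R^{-Cq_R}$; with two reference genes the per-reference
ratios are combined by geometric mean — the standard multi-reference
aggregation, chosen here because instrument "advanced relative
quantification" modules do not document their exact arithmetic. Ratios
are computed per biological replicate and then averaged (never from
averaged Cq), and fold changes divide each condition's mean ratio by the
untreated (0 h) control of the same gene, tissue and treatment. With
$E = 2$ everywhere the pipeline provably reduces to the classic
$2^{-\Delta\Delta Cq}$, a property the tests verify on random tables.

Significance over a time course uses one-way ANOVA computed from the
between/within mean squares (checked against `stats::aov`), with
pairwise pooled-variance t-tests at $\alpha = 0.05$ flagging stage
pairs; pairwise tests are uncorrected by default, matching the
two-by-two stage comparison design, with a Bonferroni option. When every
group has zero variance but means differ — possible only in noiseless
synthetic data — the p-value is reported below machine precision with a
`degenerate` flag rather than as an exact zero.

# What the synthetic generator emulates, and what it does not

`simulateGeneFamily()` evolves one ancestral gene (random sense codons
between ATG and stop; exons 120–480 bp, introns 80–600 bp, 10% GC
donors) along a rooted species tree by substitutions (default 2% per
site per branch, never creating internal stops) and intron losses
(default 2% per site per branch — the literature reports no measured
per-branch rate, so this is a free parameter chosen to make multiple
independent losses of one site uncommon, the regime real gene families
show). Mechanisms mix 40% repeat-mediated (planting an inverted-repeat
pair across the splice junction before deletion, the slippage/DNA-loop
geometry), 40% simple deletion and 20% mRNA-mediated (removing a
3′-biased geometric run of adjacent introns, mean 2). Leaves can carry
homoeologous copies at 2% divergence, emulating the A/B/D sub-genomes of
hexaploid wheat. Evolution is substitution-only, so coding coordinates
are stable across the family; the generator's truth set (structures,
events, planted repeats) indexes every modern gene directly.

The generator deliberately omits: insertions and deletions in coding
sequence (so alignment projection is easy; real families need indel-
tolerant projection), transposon insertions beyond breakpoint repeats
and simple TIR elements, rate heterogeneity across sites and branches,
intron gain, and sequencing artefacts. Passing the recovery tests
therefore demonstrates correctness of the inference machinery under
clean, known conditions — not robustness to every feature of real BAC
sequences.

`syntheticPsy3Family()` is a separate, fully synthetic construction of a
wheat-PSY3-like homoeolog trio in which published structural quantities
are planted as construction parameters — exon sizes (466/433/436, 412,
216, 148/145/148 bp), protein lengths (413/401/403 aa), approximate
inter-copy protein identity, fusion-junction motifs TGG|CCA (phase 1)
and CGG|CCG (phase 0), an exon-3 primer pair with a 216 bp product, and
on the D copy an inverted downstream duplication at offset 1729 bp with
a 154 bp internal deletion flanked by TACTGG. Tests and the acceptance
script then recompute each quantity from the sequences alone. This
verifies the pipeline's arithmetic end to end; it does not re-measure
the real BAC sequences, which are not redistributed here.

`simulateCqTable()` generates $Cq = Cq_0 - \log_E(\mathrm{abundance}) +
\varepsilon$ with per-gene efficiencies in [1.8, 2.0], flat reference
genes, noise sd 0.15 cycles, three biological replicates, two tissues,
ABA treatments at 50/100/150 µM and sampling at 0/1/2/5/8 h. The planted
response profile peaks at 18-fold in roots at 2 h and 4-fold in leaves
at 5 h for the stress-inducible paralog, with mild transient changes for
the other two — the shape of a root-specific ABA induction.

# Worked example

```{r example}
cfg <- familyConfig(
  taxa = c("rice", "sorghum", "brachypodium", "wheat"),
  tree = "(rice,(sorghum,(brachypodium,wheat)));",
  lossProbPerBranch = 0, substRate = 0, seed = 7)
fam <- simulateGeneFamily(cfg, forcedLosses = data.frame(
  site = c(3, 3, 1, 3), branch = c("brachypodium", "sorghum", "wheat", "wheat")))
vapply(trueStructures(fam), function(s) length(exonRanges(s)), integer(1))

rec <- splicedAlign(fam@cds[["wheat"]], fam@genomic[["wheat"]],
                    geneId = "wheat")
annotateIntrons(rec, fam@genomic[["wheat"]])[, c("index", "length", "donor",
                                                 "acceptor", "phase")]

m <- mapIntronSites(trueStructures(fam), fam@cds)
inferLossEvents(m, fam@tree)
```

Note the parsimony merge at work: the third intron was planted as two
independent losses (sorghum; brachypodium) plus one on wheat, but on
this four-taxon tree all three absences sit in one clade, so the minimal
reconstruction is a single loss on that clade's stem (`n2`). With maize
in the analysis (five taxa, as in the acceptance checks) the sorghum
loss separates and three events are reported.

# Numerical choices and conventions

* Coordinates are 1-based inclusive throughout (the IRanges/Biostrings
  and GFF3 convention), so no conversion happens at I/O boundaries;
  BLAST tabular input is likewise 1-based.
* Identity rescaling on HSP trimming rounds half away from zero.
* Junction-placement ties prefer GT..AG, then GC..AG, then leftmost.
* Seeds: every simulate/construct function takes an explicit seed,
  restores the caller's RNG state, and is byte-reproducible.
* Problem sizes in the shipped tests and acceptance script — six-HSP
  oracle sweeps, 4–6-leaf exhaustive Dollo enumeration, 200-nt
  brute-force repeat scans, 12-family recovery studies with 8 taxa and
  8 ancestral introns, 1000-run type-I-error simulation — were chosen to
  exercise every code path while keeping a full run in tens of seconds.

# Limitations

* Intron-site projection assumes colinear, internally-stop-free CDS;
  genes with frame-disrupting indels need external codon alignments.
* Dollo parsimony cannot, in principle, separate parallel sister-clade
  losses from one parental loss; interpret branch placements of deep
  events accordingly (the dual recovery metric quantifies this).
* The duplication finder reports the single best local alignment per
  orientation; families of many dispersed copies need an iterative
  masking strategy.
* The qPCR module assumes one efficiency per gene (from its standard
  curve) across all samples, as standard-curve workflows do.
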