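# grasstruct

Comparative-genomics toolkit for small grass gene families — built
around the phytoene synthase (PSY) family, whose three paralogs
(*PSY1–3*) control the first committed step of carotenoid biosynthesis
and whose wheat *PSY3* copies carry a reshaped exon–intron structure
produced by lineage-specific intron losses. The package is for
researchers who need to take a gene family from raw homology hits to an
evolutionary and functional characterization: which copies are
conserved across genomes, how their exon–intron architecture changed,
which mechanism deleted each intron, and how the genes respond to a
stress treatment in qPCR data.

## What it computes

**Homology scoring (COS/CNV/PAV).** Per query–subject pair, tabular
BLAST HSPs are rebuilt into a non-redundant chain and scored with

- AL = Σᵢ lenᵢ (aligned length),
- CIP = 100 · Σᵢ idᵢ / AL (cumulative identity percentage),
- CALP = AL / L_query (cumulative alignment length percentage),

then classified: no subject passing both thresholds → PAV; one → COS;
several within a tandem window → CNV.

**Exon–intron structure.** `splicedAlign()` maps a CDS onto genomic
sequence by seed-and-chain spliced alignment, placing each splice
junction at the best-scoring split with GT..AG preferred (GC..AG
recognized as the non-canonical GC class). `annotateIntrons()` reports
per-intron length, donor/acceptor, and phase = (coding bases upstream)
mod 3. `insilicoPcr()` validates primer pairs with a 3′-exact-match
rule.

**Intron-loss inference.** `mapIntronSites()` projects intron positions
across orthologs through codon-aware alignment into a presence/absence
matrix over homologous sites; `inferLossEvents()` applies Dollo
parsimony (single gain at the root, minimum losses, verified against
exhaustive enumeration); `detectExonFusions()` names the ancestral exons
merged by each loss. `scanBreakpointRepeats()` and
`classifyLossMechanism()` assign each loss a mechanism — mRNA-mediated
(adjacent-intron runs), repeat-mediated (inverted/direct repeats such as
TGG|CCA at the junction), or simple deletion. `findTirElements()` and
`findExonDuplication()` detect MITE-like elements and downstream exon
duplications; `scanCisElements()` scans promoters for ABRE, G-box and
coupling elements.

**qPCR quantification.** `fitEfficiency()` (E = 10^(−1/slope)),
`normalizedRatio()` (E_T^(−CqT) / E_R^(−CqR), geometric mean over
reference genes), `foldChangeTable()` (replicate-level ratios, fold
change vs. untreated control), `anovaPairwise()` (one-way ANOVA from
mean squares plus pairwise stage comparisons).

**Synthetic data.** `simulateGeneFamily()`, `simulateHspTable()` and
`simulateCqTable()` generate seeded inputs with planted truth for every
step; `syntheticPsy3Family()` constructs a fully synthetic wheat-like
PSY3 homoeolog trio whose planted structural quantities the pipeline
recomputes from sequence alone. `recoveryStudy()` measures truth
recovery under fixed zero-noise study conditions.

## Worked example

Simulate a four-taxon family with the grass PSY3 loss configuration
(third intron lost in sorghum and Brachypodium, first and third in
wheat), then recover the structures and losses from sequence alone:

```r
library(grasstruct)

cfg <- familyConfig(
  taxa = c("rice", "sorghum", "brachypodium", "wheat"),
  tree = "(rice,(sorghum,(brachypodium,wheat)));",
  lossProbPerBranch = 0, substRate = 0, seed = 7)
fam <- simulateGeneFamily(cfg, forcedLosses = data.frame(
  site = c(3, 3, 1, 3), branch = c("brachypodium", "sorghum", "wheat", "wheat")))

vapply(trueStructures(fam), function(s) length(exonRanges(s)), integer(1))
#>         rice      sorghum brachypodium        wheat
#>            6            5            5            4

rec <- splicedAlign(fam@cds[["wheat"]], fam@genomic[["wheat"]], geneId = "wheat")
annotateIntrons(rec, fam@genomic[["wheat"]])[, c("index", "length", "donor",
                                                 "acceptor", "phase")]
#>   index length donor acceptor phase
#> 1     1    296    GT       AG     0
#> 2     2    236    GC       AG     1
#> 3     3    147    GT       AG     2

m <- mapIntronSites(trueStructures(fam), fam@cds)
inferLossEvents(m, fam@tree)
#>   site sites branch multiplicity     mechanism
#> 1    1     1  wheat            1 indeterminate
#> 2    3     3     n2            1 indeterminate
```

Rice keeps the ancestral six exons, sorghum and Brachypodium five,
wheat four; wheat's recovered introns carry their donor/acceptor
dinucleotides and phases. Dollo parsimony reports a wheat-specific loss
of site 1 and — on this four-taxon tree — a single stem loss of site 3,
the minimal explanation of its absence from the whole
sorghum/Brachypodium/wheat clade (adding a fifth taxon that separates
sorghum resolves it into independent events; see the methods vignette).

A command-line front end over the same functions is installed at
`inst/scripts/grasstruct` (`simulate-family`, `structure`, `introns`,
`pcr`, `cipcalp`, `promoter`, `qpcr`).

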