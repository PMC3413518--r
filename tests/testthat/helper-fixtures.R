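# Shared fixtures, built in code.

# grass species tree used by the worked examples
GRASS_TREE <- "((maize,sorghum),(rice,(brachypodium,wheat)));"

# gene structures realizing the published exon/intron counts: rice and
# maize with six exons and five introns, sorghum and brachypodium lacking
# the ancestral third intron, wheat lacking the first and third
fig2cStructures <- function() {
  exonLens <- c(120, 198, 240, 150, 210, 330)   # ancestral exon sizes (bp)
  intronAfter <- list(
    rice = 1:5, maize = 1:5,
    sorghum = c(1, 2, 4, 5), brachypodium = c(1, 2, 4, 5),
    wheat = c(2, 4, 5))
  # one shared random CDS so intron sites project onto identical codons
  set.seed(20)
  sense <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                         paste0), c("A","C","G","T"), paste0)),
                   c("TAA", "TAG", "TGA"))
  L <- sum(exonLens)
  cds <- paste0("ATG", paste(sample(sense, L / 3 - 2, replace = TRUE),
                             collapse = ""), "TGA")
  sites <- cumsum(exonLens)[1:5]
  structures <- list(); cdsSet <- character()
  for (g in names(intronAfter)) {
    keep <- intronAfter[[g]]
    cuts <- c(0, sites[keep], L)
    widths <- diff(cuts)
    starts <- integer(); pos <- 0
    gpos <- 100                                  # 5' flank
    st <- integer(); en <- integer()
    for (w in widths) {
      st <- c(st, gpos + 1); gpos <- gpos + w; en <- c(en, gpos)
      gpos <- gpos + 250                         # fixed intron length
    }
    structures[[g]] <- GeneStructure(g, IRanges::IRanges(start = st, end = en),
                                     taxon = g, genomicId = g)
    cdsSet[g] <- cds
  }
  list(structures = structures, cds = Biostrings::DNAStringSet(cdsSet),
       sites = sites, exonLens = exonLens)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
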