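#' Synthetic wheat PSY3-like homoeolog family
#'
#' Constructs, deterministically from a seed, a fully synthetic trio of
#' wheat-style homoeologous loci (A, B and D copies) that emulates the
#' published structural characteristics of the hexaploid wheat PSY3 gene
#' family; the sequences themselves are random and carry no real genomic
#' content. The construction plants, as parameters:
#' \itemize{
#'   \item the four-exon / three-intron structure with exon sizes
#'     466/412/216/148 (A), 433/412/216/145 (B) and 436/412/216/148 (D) bp,
#'     giving proteins of 413, 401 and 403 amino acids;
#'   \item amino-acid divergence between the copies targeting roughly
#'     91\% (A-B), 90\% (A-D) and 96\% (B-D) identity;
#'   \item inverted-repeat breakpoint motifs at the two exon-fusion
#'     junctions: TGG|CCA inside exon 1 (a phase-1 ancestral intron site)
#'     and CGG|CCG inside exon 2 (phase 0);
#'   \item a primer pair on the third exon amplifying a 216 bp product
#'     from all three copies;
#'   \item on the D copy, an inverted duplication of the fourth exon (plus
#'     202 bp of upstream gene sequence) planted 1729 bp downstream of the
#'     stop codon, interrupted by a 154 bp deletion flanked on both sides
#'     by the TACTGG motif;
#'   \item a 2 kb promoter carrying ABRE, G-box, CE1 and CE3 elements.
#' }
#' The pipeline's own functions are expected to recover each planted
#' quantity by computation; nothing in the returned object is measured,
#' only constructed.
#'
#' @param seed integer seed.
#' @return list with \code{genomic} and \code{cds} (\code{DNAStringSet}s
#'   named PSY3A/PSY3B/PSY3D), \code{structures} (named list of
#'   \linkS4class{GeneStructure}), \code{proteins} (\code{AAStringSet}),
#'   \code{primers} (list \code{forward}, \code{reverse}),
#'   \code{stopCodonPos} (named, genomic coordinate of the last stop-codon
#'   base), \code{junctions} (data.frame of fusion-junction CDS
#'   coordinates and motifs per locus), \code{duplication} (list:
#'   \code{locus}, \code{offset}, \code{deletion_length},
#'   \code{flank_motif}, \code{source_segment}), \code{promoterLength},
#'   \code{promoters} (named character).
#' @export
syntheticPsy3Family <- function(seed = 42L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  GENCODE <- Biostrings::GENETIC_CODE
  aaOf <- GENCODE[SENSE_CODONS]
  codonsFor <- split(SENSE_CODONS, aaOf)
  aaAlphabet <- names(codonsFor)

  # ---- B-copy CDS: 401 codons + stop, with planted junction motifs ----
  nCoreAA <- 401L
  codB <- c("ATG", sample(SENSE_CODONS, nCoreAA - 1L, replace = TRUE))
  cdsB <- paste(codB, collapse = "")
  # exon-fusion junction 1 after CDS base 232 (phase 1): TGG|CCA
  substr(cdsB, 230L, 235L) <- "TGGCCA"
  # junction 2 after base 639 (phase 0): CGG|CCG
  substr(cdsB, 637L, 642L) <- "CGGCCG"
  # neither planting can create a stop: x-T-G, A-x-x, CGG, CCG are sense
  codB <- substring(cdsB, 3L * (seq_len(nCoreAA) - 1L) + 1L,
                    3L * seq_len(nCoreAA))
  protB <- unname(aaOf[match(codB, SENSE_CODONS)])
  protB[is.na(protB)] <- vapply(codB[is.na(match(codB, SENSE_CODONS))],
                                function(c) GENCODE[[c]], character(1))

  # codons that must stay identical across copies: start, planted
  # junctions (codons 77-79 and 213-214), primer sites on exon 3
  # (B CDS 846-865 and 1042-1061 -> codons 282-289 and 348-354)
  protected <- c(1L, 77:79, 213:214, 282:289, 348:354)
  pool <- setdiff(2:nCoreAA, protected)

  # divergence design: 14 B/D differences, 5 of which A shares with D,
  # plus 20 A-only differences -> 25 A-B and 29 A-D differing columns
  sBD <- sample(pool, 14L)
  shared <- sBD[1:5]
  sAonly <- sample(setdiff(pool, sBD), 20L)

  newAA <- function(not) sample(setdiff(aaAlphabet, not), 1L)
  protD_core <- protB
  for (i in sBD) protD_core[i] <- newAA(protB[i])
  protA_core <- protB
  for (i in shared) protA_core[i] <- protD_core[i]
  for (i in sAonly) protA_core[i] <- newAA(c(protB[i], protD_core[i]))

  # terminal extensions: A gains 11 aa after Met and 1 before the stop;
  # D gains 1 and 1; all extension residues mutually distinct
  extPool <- setdiff(aaAlphabet, c("M", "W"))
  aIns <- sample(extPool, 11L)
  dIns <- sample(setdiff(extPool, aIns), 1L)
  aCt <- sample(extPool, 1L)
  dCt <- sample(setdiff(extPool, aCt), 1L)

  protA <- c("M", aIns, protA_core[-1L], aCt)     # 413 aa
  protD <- c("M", dIns, protD_core[-1L], dCt)     # 403 aa

  backTranslate <- function(prot, coreProt, coreCodons, nInsert) {
    # reuse the B codon wherever the amino acid is unchanged
    out <- character(length(prot))
    out[1L] <- "ATG"
    for (i in 2:length(prot)) {
      corePos <- i - nInsert
      if (corePos >= 2L && corePos <= length(coreProt) &&
          prot[i] == coreProt[corePos]) {
        out[i] <- coreCodons[corePos]
      } else {
        out[i] <- sample(codonsFor[[prot[i]]], 1L)
      }
    }
    paste(c(out, "TGA"), collapse = "")
  }
  cdsA <- backTranslate(protA, protB, codB, 11L)
  cdsD <- backTranslate(protD, protB, codB, 1L)
  cdsBfull <- paste(c(codB, "TGA"), collapse = "")

  exonLens <- list(PSY3A = c(466L, 412L, 216L, 148L),
                   PSY3B = c(433L, 412L, 216L, 145L),
                   PSY3D = c(436L, 412L, 216L, 148L))
  cdsSet <- c(PSY3A = cdsA, PSY3B = cdsBfull, PSY3D = cdsD)
  stopifnot(vapply(names(exonLens), function(g)
    sum(exonLens[[g]]) == nchar(cdsSet[[g]]), logical(1)))

  # primers on exon 3, conserved across copies, product = whole exon 3
  fwd <- substr(cdsBfull, 846L, 865L)
  rev <- revcompChr(substr(cdsBfull, 1042L, 1061L))

  promoterLength <- 2000L
  makePromoter <- function() {
    p <- randomDna(promoterLength)
    substr(p, 520L, 524L) <- "ACGTG"          # ABRE core
    substr(p, 1200L, 1205L) <- "CACGTG"       # G-box
    substr(p, 1215L, 1223L) <- "TGCCACCGG"    # CE1
    substr(p, 1400L, 1408L) <- "ACGCGTGTC"    # CE3
    p
  }

  intronLens <- c(520L, 640L, 410L)
  makeIntron <- function(len) paste0("GT", randomDna(len - 4L), "AG")

  genomic <- character(); structures <- list(); stopPos <- integer()
  promoters <- character()
  dupTruth <- NULL
  for (g in names(exonLens)) {
    ex <- exonLens[[g]]
    cds <- cdsSet[[g]]
    cuts <- c(0L, cumsum(ex))
    exSeq <- substring(cds, cuts[1:4] + 1L, cuts[2:5])
    introns <- vapply(intronLens, makeIntron, character(1))
    if (g == "PSY3D") {
      # plant TACTGG flanks of the future 154 bp deletion in the tail of
      # intron 3 (source tract T = last 202 nt of intron 3 + exon 4)
      i3 <- introns[3L]
      off <- nchar(i3) - 202L                 # T[1] = i3[off + 1]
      substr(i3, off + 39L, off + 44L) <- "TACTGG"
      substr(i3, off + 193L, off + 198L) <- "TACTGG"
      introns[3L] <- i3
    }
    promoter <- makePromoter()
    body <- paste0(exSeq[1], introns[1], exSeq[2], introns[2],
                   exSeq[3], introns[3], exSeq[4])
    if (g == "PSY3D") {
      Tsrc <- paste0(substr(introns[3L], nchar(introns[3L]) - 201L,
                            nchar(introns[3L])), exSeq[4])
      # deletion of source positions 45..198 (154 bp), flanked on both
      # sides by the planted TACTGG motif
      Tdel <- paste0(substr(Tsrc, 1L, 44L), substr(Tsrc, 199L, 350L))
      copy <- revcompChr(Tdel)
      threePrime <- paste0(randomDna(1728L), copy, randomDna(300L))
      dupTruth <- list(locus = g, offset = 1729L, deletion_length = 154L,
                       flank_motif = "TACTGG", source_segment = Tsrc)
    } else {
      threePrime <- randomDna(2200L)
    }
    gseq <- paste0(promoter, body, threePrime)
    starts <- integer(4); ends <- integer(4)
    pos <- promoterLength
    for (i in 1:4) {
      starts[i] <- pos + 1L
      pos <- pos + ex[i]
      ends[i] <- pos
      if (i < 4L) pos <- pos + nchar(introns[i])
    }
    genomic[g] <- gseq
    promoters[g] <- promoter
    stopPos[g] <- ends[4L]
    structures[[g]] <- GeneStructure(g, IRanges(start = starts, end = ends),
                                     taxon = "wheat", genomicId = g,
                                     strand = "+")
  }

  junctions <- data.frame(
    locus = rep(names(exonLens), each = 2L),
    junction = c(265L, 672L, 232L, 639L, 235L, 642L),
    phase = rep(c(1L, 0L), 3L),
    motif = rep(c("TGG|CCA", "CGG|CCG"), 3L),
    stringsAsFactors = FALSE)

  prot <- Biostrings::AAStringSet(c(
    PSY3A = paste(protA, collapse = ""),
    PSY3B = paste(protB, collapse = ""),
    PSY3D = paste(protD, collapse = "")))

  list(genomic = DNAStringSet(genomic), cds = DNAStringSet(cdsSet),
       structures = structures, proteins = prot,
       primers = list(forward = fwd, reverse = rev),
       stopCodonPos = stopPos, junctions = junctions,
       duplication = dupTruth, promoterLength = promoterLength,
       promoters = promoters)
}
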