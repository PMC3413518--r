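#' Configuration for a simulated ortholog gene family
#'
#' Describes the conditions under which \code{\link{simulateGeneFamily}}
#' evolves a gene family along a rooted species tree: an ancestral
#' exon-intron architecture generated once at the root, lineage-specific
#' intron losses drawn along branches with a mix of mechanisms, and
#' near-identical homoeologous copies within taxa. The defaults emulate a
#' small grass gene family with the ancestral five-intron architecture seen
#' in PSY3-like genes.
#'
#' @param taxa character vector of taxon labels.
#' @param tree rooted species tree as Newick text; leaves must match
#'   \code{taxa}.
#' @param nIntronsAncestral number of introns in the ancestral gene
#'   (default 5).
#' @param exonLengthRange integer pair, exon length bounds in bp.
#' @param intronLengthRange integer pair, intron length bounds in bp.
#' @param lossProbPerBranch probability that a present intron site is lost
#'   on a branch (default 0.1; the literature gives no measured rate, so
#'   this is a free parameter of the simulation).
#' @param mechanismMix named proportions over \code{repeat_mediated},
#'   \code{simple_deletion} and \code{mrna_mediated}; must sum to 1.
#' @param plantedRepeatArmLen arm length in nt of inverted repeats planted
#'   at repeat-mediated breakpoints (default 3, the size of the motifs seen
#'   at real deletion breakpoints).
#' @param homoeologDivergence per-site substitution probability between
#'   within-taxon homoeologous copies (default 0.02).
#' @param nHomoeologs copies per taxon (default 1).
#' @param substRate per-site substitution probability per branch
#'   (default 0.02).
#' @param gcDonorFraction fraction of simulated introns whose donor is GC
#'   rather than GT (default 0.1).
#' @param mrnaRunMean mean run length of adjacent introns removed by one
#'   mRNA-mediated event (geometric; default 2).
#' @param flankLength bp of flanking sequence on each side of the gene.
#' @param seed integer seed; every draw in the simulation derives from it.
#' @return a validated list of class \code{familyConfig}.
#' @export
familyConfig <- function(taxa,
                         tree,
                         nIntronsAncestral = 5L,
                         exonLengthRange = c(120L, 480L),
                         intronLengthRange = c(80L, 600L),
                         lossProbPerBranch = 0.1,
                         mechanismMix = c(repeat_mediated = 0.4,
                                          simple_deletion = 0.4,
                                          mrna_mediated = 0.2),
                         plantedRepeatArmLen = 3L,
                         homoeologDivergence = 0.02,
                         nHomoeologs = 1L,
                         substRate = 0.02,
                         gcDonorFraction = 0.1,
                         mrnaRunMean = 2,
                         flankLength = 300L,
                         seed = 1L) {
  stopifnot(length(exonLengthRange) == 2L, length(intronLengthRange) == 2L)
  if (any(exonLengthRange <= 0) || diff(exonLengthRange) < 0)
    stop("exonLengthRange must be positive and ordered", call. = FALSE)
  if (any(intronLengthRange < 10) || diff(intronLengthRange) < 0)
    stop("intronLengthRange must be >= 10 and ordered", call. = FALSE)
  for (p in c(lossProbPerBranch, homoeologDivergence, substRate,
              gcDonorFraction))
    if (p < 0 || p > 1) stop("probabilities must be in [0,1]", call. = FALSE)
  if (abs(sum(mechanismMix) - 1) > 1e-8)
    stop("mechanismMix must sum to 1", call. = FALSE)
  if (!all(names(mechanismMix) %in%
           c("repeat_mediated", "simple_deletion", "mrna_mediated")))
    stop("unknown mechanism in mechanismMix", call. = FALSE)
  if (plantedRepeatArmLen < 3L)
    stop("plantedRepeatArmLen must be >= 3", call. = FALSE)
  phy <- readSpeciesTree(text = tree)
  if (!setequal(phy$tip.label, taxa))
    stop("tree leaves must match taxa", call. = FALSE)
  structure(list(
    taxa = taxa, tree = tree, nIntronsAncestral = as.integer(nIntronsAncestral),
    exonLengthRange = as.integer(exonLengthRange),
    intronLengthRange = as.integer(intronLengthRange),
    lossProbPerBranch = lossProbPerBranch, mechanismMix = mechanismMix,
    plantedRepeatArmLen = as.integer(plantedRepeatArmLen),
    homoeologDivergence = homoeologDivergence,
    nHomoeologs = as.integer(nHomoeologs), substRate = substRate,
    gcDonorFraction = gcDonorFraction, mrnaRunMean = mrnaRunMean,
    flankLength = as.integer(flankLength), seed = as.integer(seed)
  ), class = "familyConfig")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                              c("A","C","G","T"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# per-site substitutions that never create an internal stop codon or touch
# the start/stop codons
mutateCds <- function(cds, rate) {
  if (rate <= 0) return(cds)
  v <- strsplit(cds, "", fixed = TRUE)[[1]]
  n <- length(v)
  hit <- which(stats::runif(n) < rate)
  hit <- hit[hit > 3L & hit <= n - 3L]
  if (!length(hit)) return(cds)
  bases <- c("A", "C", "G", "T")
  old <- v
  for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1L)
  # revert any codon that became a stop
  for (i in hit) {
    cstart <- ((i - 1L) %/% 3L) * 3L + 1L
    if (paste(v[cstart:(cstart + 2L)], collapse = "") %in% STOP_CODONS)
      v[cstart:(cstart + 2L)] <- old[cstart:(cstart + 2L)]
  }
  paste(v, collapse = "")
}

mutateIntron <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) <= 4L) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  hit <- which(stats::runif(n) < rate)
  hit <- hit[hit > 2L & hit <= n - 2L]   # preserve donor/acceptor
  bases <- c("A", "C", "G", "T")
  for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1L)
  paste(v, collapse = "")
}

#' Simulate a gene family with lineage-specific intron losses
#'
#' Generates one ancestral gene (random sense codons between an ATG and a
#' stop codon, split into exons by \code{nIntronsAncestral} intron sites)
#' at the root of the species tree, then walks the tree: on each branch the
#' coding sequence accumulates substitutions and each present intron site
#' is lost with probability \code{lossProbPerBranch}. A loss draws its
#' mechanism from \code{mechanismMix}: \code{repeat_mediated} losses first
#' plant an inverted-repeat pair across the splice junction (one arm at the
#' end of the upstream exon, its reverse complement at the start of the
#' downstream exon) so that the fused exon carries the breakpoint
#' signature; \code{mrna_mediated} losses remove a contiguous run of
#' adjacent introns, extended toward the 3' end with geometric run length;
#' \code{simple_deletion} losses remove the intron cleanly. Leaves receive
#' \code{nHomoeologs} near-identical copies. Coding coordinates are stable
#' across the family (substitution-only evolution), so the ancestral site
#' table indexes every modern gene.
#'
#' @param config a \code{\link{familyConfig}}.
#' @param forcedLosses optional data.frame with columns \code{site},
#'   \code{branch} (child-node or tip label) and optionally
#'   \code{mechanism}: losses applied deterministically on those branches,
#'   in addition to any random draws.
#' @return a \linkS4class{FamilyTruth}.
#' @examples
#' cfg <- familyConfig(
#'   taxa = c("rice", "sorghum", "brachypodium", "wheat"),
#'   tree = "(rice,(sorghum,(brachypodium,wheat)));",
#'   lossProbPerBranch = 0, substRate = 0, seed = 7)
#' fam <- simulateGeneFamily(cfg)
#' trueStructures(fam)[[1]]
#' @export
simulateGeneFamily <- function(config, forcedLosses = NULL) {
  stopifnot(inherits(config, "familyConfig"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  phy <- readSpeciesTree(text = config$tree)
  if (is.null(phy$node.label) || !all(nzchar(phy$node.label)))
    phy <- ape::makeNodeLabel(phy, prefix = "n")
  nTip <- length(phy$tip.label)
  labelOf <- function(node) if (node <= nTip) phy$tip.label[node]
                            else phy$node.label[node - nTip]

  nI <- config$nIntronsAncestral
  exLen <- sample(config$exonLengthRange[1]:config$exonLengthRange[2],
                  nI + 1L, replace = TRUE)
  total <- sum(exLen)
  exLen[nI + 1L] <- exLen[nI + 1L] + (3L - total %% 3L) %% 3L
  L <- sum(exLen)
  nCodon <- L %/% 3L
  cds0 <- paste0("ATG",
                 paste(sample(SENSE_CODONS, nCodon - 2L, replace = TRUE),
                       collapse = ""),
                 sample(STOP_CODONS, 1L))
  siteCoord <- cumsum(exLen[seq_len(nI)])
  sites <- data.frame(site = seq_len(nI), coord = as.integer(siteCoord),
                      phase = as.integer(siteCoord %% 3L))
  introns0 <- vapply(seq_len(nI), function(i) {
    len <- sample(config$intronLengthRange[1]:config$intronLengthRange[2], 1L)
    donor <- if (stats::runif(1) < config$gcDonorFraction) "GC" else "GT"
    paste0(donor, randomDna(len - 4L), "AG")
  }, character(1))

  forced <- if (!is.null(forcedLosses)) {
    if (is.null(forcedLosses$mechanism))
      forcedLosses$mechanism <- "simple_deletion"
    forcedLosses
  } else data.frame(site = integer(), branch = character(),
                    mechanism = character())

  events <- list()
  repeats <- list()

  # preorder walk; each node state: cds, present (logical over sites),
  # introns (character over sites)
  root <- nTip + 1L
  states <- vector("list", max(phy$edge))
  states[[root]] <- list(cds = cds0, present = rep(TRUE, nI),
                         introns = introns0)
  edges <- phy$edge[order(phy$edge[, 1L], phy$edge[, 2L]), , drop = FALSE]
  # reorder edges so parents are processed before children (preorder)
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    node <- stack[[1L]]; stack <- stack[-1L]
    kids <- which(edges[, 1L] == node)
    ord <- c(ord, kids)
    stack <- c(edges[kids, 2L], stack)
  }
  edges <- edges[ord, , drop = FALSE]

  applyLoss <- function(st, site, mech, branchLabel) {
    lostSites <- site
    if (mech == "mrna_mediated") {
      run <- 1L + stats::rgeom(1L, prob = 1 / max(config$mrnaRunMean, 1))
      s <- site
      while (length(lostSites) < run && s < nI && st$present[s + 1L]) {
        s <- s + 1L
        lostSites <- c(lostSites, s)
      }
    }
    if (mech == "repeat_mediated") {
      arm <- config$plantedRepeatArmLen
      coord <- sites$coord[site]
      for (try in 1:25) {
        motif <- randomDna(arm)
        v <- strsplit(st$cds, "", fixed = TRUE)[[1]]
        v[(coord - arm + 1L):coord] <- strsplit(motif, "", fixed = TRUE)[[1]]
        rcm <- as.character(reverseComplement(DNAString(motif)))
        v[(coord + 1L):(coord + arm)] <- strsplit(rcm, "", fixed = TRUE)[[1]]
        cand <- paste(v, collapse = "")
        # reject plantings that corrupt the reading frame with a stop
        codons <- substring(cand, seq(4L, nchar(cand) - 3L, 3L),
                            seq(6L, nchar(cand) - 1L, 3L))
        if (!any(codons %in% STOP_CODONS)) {
          st$cds <- cand
          repeats[[length(repeats) + 1L]] <<- data.frame(
            site = site, branch = branchLabel, motif = motif,
            arm_len = arm, cds_coord = coord, stringsAsFactors = FALSE)
          break
        }
      }
    }
    st$present[lostSites] <- FALSE
    events[[length(events) + 1L]] <<- data.frame(
      site = lostSites[1L], branch = branchLabel, mechanism = mech,
      multiplicity = length(lostSites),
      sites = paste(lostSites, collapse = ","), stringsAsFactors = FALSE)
    st
  }

  for (r in seq_len(nrow(edges))) {
    parent <- edges[r, 1L]; child <- edges[r, 2L]
    st <- states[[parent]]
    st$cds <- mutateCds(st$cds, config$substRate)
    st$introns[st$present] <- vapply(st$introns[st$present], mutateIntron,
                                     character(1), rate = config$substRate)
    lab <- labelOf(child)
    for (site in which(st$present)) {
      f <- forced[forced$branch == lab & forced$site == site, , drop = FALSE]
      if (nrow(f)) {
        st <- applyLoss(st, site, f$mechanism[[1L]], lab)
      } else if (stats::runif(1) < config$lossProbPerBranch) {
        mech <- sample(names(config$mechanismMix), 1L,
                       prob = config$mechanismMix)
        st <- applyLoss(st, site, mech, lab)
      }
    }
    states[[child]] <- st
  }

  # materialize leaf genes (homoeologous copies) and genomic sequences
  genomic <- character(0); cdsOut <- character(0)
  structures <- list()
  for (tip in seq_len(nTip)) {
    taxon <- phy$tip.label[tip]
    st <- states[[tip]]
    for (h in seq_len(config$nHomoeologs)) {
      gid <- if (config$nHomoeologs == 1L) taxon
             else paste0(taxon, "_", LETTERS[h])
      cds <- if (h == 1L) st$cds else mutateCds(st$cds, config$homoeologDivergence)
      present <- which(st$present)
      cuts <- c(0L, sites$coord[present], nchar(cds))
      exSeq <- substring(cds, head(cuts, -1L) + 1L, cuts[-1L])
      flank5 <- randomDna(config$flankLength)
      flank3 <- randomDna(config$flankLength)
      pieces <- character(0)
      starts <- integer(0); ends <- integer(0)
      pos <- nchar(flank5)
      for (i in seq_along(exSeq)) {
        starts <- c(starts, pos + 1L)
        pos <- pos + nchar(exSeq[i])
        ends <- c(ends, pos)
        pieces <- c(pieces, exSeq[i])
        if (i < length(exSeq)) {
          intr <- st$introns[[present[i]]]
          pieces <- c(pieces, intr)
          pos <- pos + nchar(intr)
        }
      }
      gseq <- paste0(flank5, paste(pieces, collapse = ""), flank3)
      genomic[gid] <- gseq
      cdsOut[gid] <- cds
      structures[[gid]] <- GeneStructure(
        gid, IRanges(start = starts, end = ends), taxon = taxon,
        genomicId = gid, strand = "+")
    }
  }

  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(site = integer(), branch = character(),
                        mechanism = character(), multiplicity = integer(),
                        sites = character(), stringsAsFactors = FALSE)
  rp <- if (length(repeats)) do.call(rbind, repeats)
        else data.frame(site = integer(), branch = character(),
                        motif = character(), arm_len = integer(),
                        cds_coord = integer(), stringsAsFactors = FALSE)

  new("FamilyTruth",
      genomic = DNAStringSet(genomic), cds = DNAStringSet(cdsOut),
      structures = structures, tree = phy, events = ev, repeats = rp,
      ancestralSites = sites, config = unclass(config))
}

#' Write a simulated family to disk
#'
#' Writes the genomic FASTA, CDS FASTA, true structures as GFF3, the
#' species tree as Newick and the truth event table as TSV.
#'
#' @param truth a \linkS4class{FamilyTruth}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
writeFamily <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genomic = file.path(dir, "genomic.fa"),
    cds = file.path(dir, "cds.fa"),
    structures = file.path(dir, "structures.gff3"),
    tree = file.path(dir, "tree.nwk"),
    events = file.path(dir, "events.tsv")
  )
  writeFastaFile(truth@genomic, paths[["genomic"]])
  writeFastaFile(truth@cds, paths[["cds"]])
  writeStructuresGff3(truth@structures, paths[["structures"]])
  ape::write.tree(truth@tree, paths[["tree"]])
  writeTsv(truth@events, paths[["events"]])
  invisible(paths)
}

#' Simulate a BLAST-style HSP table from a family truth set
#'
#' Emits HSP rows for every gene outside the chosen subject taxon against
#' every copy in that taxon. Because simulated evolution is
#' substitution-only, the true pairwise alignment is the identity mapping,
#' and identity counts are obtained by direct sequence comparison (after
#' optionally degrading the subject at rate \code{noise}); fragmented pairs
#' are split into \code{fragmentation} contiguous, non-overlapping HSPs
#' whose identity counts partition the full count. Decoy queries (random
#' sequences, identity fraction drawn uniform in 30-55 percent) are labeled
#' PAV in the returned truth.
#'
#' @param truth a \linkS4class{FamilyTruth}.
#' @param subjectTaxon taxon whose copies act as the subject genome.
#' @param fragmentation number of HSPs each true pair is split into
#'   (default 1).
#' @param noise per-site mismatch rate injected into subjects (default 0).
#' @param decoys number of non-homologous decoy queries (default 0).
#' @param seed integer seed.
#' @return list with \code{hsps} (data.frame in \code{\link{readHspTable}}
#'   schema), \code{queryLengths}, \code{subjectPositions} (gene order on
#'   the subject genome) and \code{truth} (query_id, class).
#' @export
simulateHspTable <- function(truth, subjectTaxon, fragmentation = 1L,
                             noise = 0, decoys = 0L, seed = 1L) {
  stopifnot(fragmentation >= 1L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  taxa <- vapply(truth@structures, function(s) s@taxon, character(1))
  subjects <- names(truth@structures)[taxa == subjectTaxon]
  queries <- names(truth@structures)[taxa != subjectTaxon]
  if (!length(subjects)) stop("no genes of taxon ", subjectTaxon, call. = FALSE)
  cds <- as.character(truth@cds)

  rows <- list(); truthRows <- list()
  for (q in queries) {
    qv <- strsplit(cds[[q]], "", fixed = TRUE)[[1]]
    Lq <- length(qv)
    for (s in subjects) {
      sv <- strsplit(cds[[s]], "", fixed = TRUE)[[1]]
      if (noise > 0) {
        hit <- which(stats::runif(length(sv)) < noise)
        bases <- c("A", "C", "G", "T")
        for (i in hit) sv[i] <- sample(setdiff(bases, sv[i]), 1L)
      }
      match <- qv == sv
      cuts <- if (fragmentation > 1L)
        sort(sample(seq_len(Lq - 1L), fragmentation - 1L)) else integer(0)
      bnd <- c(0L, cuts, Lq)
      for (i in seq_len(length(bnd) - 1L)) {
        a <- bnd[i] + 1L; b <- bnd[i + 1L]
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q, subject_id = s,
          query_start = a, query_end = b, subject_start = a, subject_end = b,
          aligned_length = b - a + 1L,
          identity_count = sum(match[a:b]),
          e_value = 1e-50, strand = "+", stringsAsFactors = FALSE)
      }
    }
    cls <- if (length(subjects) >= 2L) "CNV" else "COS"
    truthRows[[length(truthRows) + 1L]] <-
      data.frame(query_id = q, class = cls, stringsAsFactors = FALSE)
  }
  qLens <- vapply(cds[queries], nchar, integer(1))
  if (decoys > 0L) for (d in seq_len(decoys)) {
    did <- paste0("decoy", d)
    Ld <- sample(400:1500, 1L)
    s <- sample(subjects, 1L)
    frac <- stats::runif(1, 0.30, 0.55)
    span <- sample(150:min(400L, Ld), 1L)
    a <- sample(seq_len(Ld - span + 1L), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = did, subject_id = s,
      query_start = a, query_end = a + span - 1L,
      subject_start = 1L, subject_end = span,
      aligned_length = span,
      identity_count = as.integer(roundHalfUp(frac * span)),
      e_value = 1e-3, strand = "+", stringsAsFactors = FALSE)
    truthRows[[length(truthRows) + 1L]] <-
      data.frame(query_id = did, class = "PAV", stringsAsFactors = FALSE)
    qLens[did] <- Ld
  }
  list(
    hsps = do.call(rbind, rows),
    queryLengths = qLens,
    subjectPositions = stats::setNames(seq_along(subjects), subjects),
    truth = do.call(rbind, truthRows)
  )
}

#' Configuration for a simulated qPCR experiment
#'
#' Emulates an ABA-treatment time-course assayed by SYBR real-time PCR:
#' target and reference genes measured in several tissues at timepoints
#' after treatment, in biological replicates, with per-gene amplification
#' efficiencies and a planted fold-change profile that the quantification
#' pipeline should recover.
#'
#' @param genes target gene names.
#' @param references reference gene names (two by default, as in
#'   two-reference-gene normalization).
#' @param tissues tissue labels.
#' @param timepoints sampling times in hours (default 0, 1, 2, 5, 8).
#' @param treatments treatment labels (ABA concentrations in uM).
#' @param replicates biological replicates per condition (>= 2).
#' @param efficiencies named per-gene amplification efficiencies in (1, 2];
#'   defaults drawn in [1.8, 2.0] when NULL.
#' @param foldProfile data.frame (gene, tissue, time_h, fold) of planted
#'   fold changes relative to the untreated control; missing cells default
#'   to fold 1. The same profile applies at every treatment level.
#' @param cqNoiseSd standard deviation of Cq noise in cycles (>= 0).
#' @param cq0 baseline Cq of an unchanged target (default 24).
#' @param seed integer seed.
#' @return a validated list of class \code{cqConfig}.
#' @export
cqConfig <- function(genes = c("PSY1", "PSY2", "PSY3"),
                     references = c("spastin", "RLI"),
                     tissues = c("leaf", "root"),
                     timepoints = c(0, 1, 2, 5, 8),
                     treatments = c(50, 100, 150),
                     replicates = 3L,
                     efficiencies = NULL,
                     foldProfile = NULL,
                     cqNoiseSd = 0.15,
                     cq0 = 24,
                     seed = 1L) {
  if (replicates < 2L) stop("replicates must be >= 2", call. = FALSE)
  if (cqNoiseSd < 0) stop("cqNoiseSd must be >= 0", call. = FALSE)
  all <- c(genes, references)
  if (is.null(efficiencies)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed + 1000L)
    efficiencies <- stats::setNames(round(stats::runif(length(all), 1.8, 2.0), 3), all)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  if (any(efficiencies <= 1) || any(efficiencies > 2))
    stop("efficiencies must be in (1, 2]", call. = FALSE)
  if (is.null(foldProfile)) foldProfile <- defaultFoldProfile(timepoints)
  stopifnot(all(c("gene", "tissue", "time_h", "fold") %in% names(foldProfile)))
  structure(list(genes = genes, references = references, tissues = tissues,
                 timepoints = timepoints, treatments = treatments,
                 replicates = as.integer(replicates),
                 efficiencies = efficiencies, foldProfile = foldProfile,
                 cqNoiseSd = cqNoiseSd, cq0 = cq0, seed = as.integer(seed)),
            class = "cqConfig")
}

# planted response profile: a strong root induction peaking 18-fold at 2 h
# and a moderate 4-fold leaf response at 5 h for the stress-inducible
# paralog; mild transient changes for the other two
defaultFoldProfile <- function(timepoints) {
  grid <- expand.grid(gene = c("PSY1", "PSY2", "PSY3"),
                      tissue = c("leaf", "root"),
                      time_h = timepoints, stringsAsFactors = FALSE)
  prof <- list(
    PSY3.root = c("0" = 1, "1" = 3, "2" = 18, "5" = 6, "8" = 2),
    PSY3.leaf = c("0" = 1, "1" = 1, "2" = 2, "5" = 4, "8" = 1),
    PSY1.root = c("0" = 1, "1" = 1, "2" = 1.2, "5" = 2, "8" = 1.2),
    PSY2.root = c("0" = 1, "1" = 1.5, "2" = 2, "5" = 1.5, "8" = 1),
    PSY1.leaf = c("0" = 1, "1" = 0.8, "2" = 0.7, "5" = 1, "8" = 1),
    PSY2.leaf = c("0" = 1, "1" = 0.9, "2" = 0.8, "5" = 0.8, "8" = 0.8)
  )
  grid$fold <- vapply(seq_len(nrow(grid)), function(i) {
    p <- prof[[paste(grid$gene[i], grid$tissue[i], sep = ".")]]
    f <- p[as.character(grid$time_h[i])]
    if (is.null(p) || is.na(f)) 1 else unname(f)
  }, numeric(1))
  grid
}

#' Simulate a qPCR Cq table with planted fold changes
#'
#' Generates replicate Cq values as
#' \eqn{Cq = Cq_0 - \log_E(\mathrm{abundance}) + \epsilon}: a gene whose
#' transcript is \code{fold} times the control abundance crosses threshold
#' \eqn{\log_E(\mathrm{fold})} cycles earlier. Reference genes have flat
#' abundance in every condition. A serial-dilution standard curve (five
#' 10-fold dilutions) is generated per gene for efficiency fitting.
#'
#' @param config a \code{\link{cqConfig}}.
#' @return list with \code{cq} (the Cq table: sample_id, gene, role,
#'   tissue, treatment, time_h, replicate, Cq), \code{standards} (per-gene
#'   dilution curves: gene, log10_dilution, Cq), \code{efficiencies} and
#'   \code{truth} (the planted fold profile).
#' @export
simulateCqTable <- function(config) {
  stopifnot(inherits(config, "cqConfig"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  allGenes <- c(config$genes, config$references)
  roles <- stats::setNames(c(rep("target", length(config$genes)),
                             rep("reference", length(config$references))),
                           allGenes)
  fold <- function(g, ti, t) {
    if (roles[[g]] == "reference") return(1)
    r <- config$foldProfile[config$foldProfile$gene == g &
                            config$foldProfile$tissue == ti &
                            config$foldProfile$time_h == t, "fold"]
    if (length(r)) r[[1L]] else 1
  }
  rows <- list()
  for (ti in config$tissues) for (tr in config$treatments)
    for (t in config$timepoints) for (g in allGenes)
      for (rep in seq_len(config$replicates)) {
        E <- config$efficiencies[[g]]
        f <- fold(g, ti, t)
        cq <- config$cq0 - log(f, base = E) +
          stats::rnorm(1, 0, config$cqNoiseSd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_%sh_r%d", ti, tr, t, rep),
          gene = g, role = roles[[g]], tissue = ti, treatment = tr,
          time_h = t, replicate = rep, Cq = cq, stringsAsFactors = FALSE)
      }
  std <- list()
  for (g in allGenes) {
    E <- config$efficiencies[[g]]
    slope <- -1 / log10(E)
    for (d in 0:-4) for (rep in 1:2)
      std[[length(std) + 1L]] <- data.frame(
        gene = g, log10_dilution = d,
        Cq = config$cq0 + slope * d + stats::rnorm(1, 0, config$cqNoiseSd),
        stringsAsFactors = FALSE)
  }
  list(cq = do.call(rbind, rows), standards = do.call(rbind, std),
       efficiencies = config$efficiencies, truth = config$foldProfile)
}
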