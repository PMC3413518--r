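test_that("the published inverted breakpoint motifs are detected at the junction", {
  set.seed(51)
  # TGG|CCA: revcomp(TGG) == CCA
  s1 <- paste0(randomSeq(20), "TGG", "CCA", randomSeq(20))
  hits <- scanBreakpointRepeats(s1, junction = 23, minArm = 3)
  flank <- hits[hits$arm1_end == 23 & hits$arm2_start == 24, ]
  expect_true(any(flank$kind == "inverted" & flank$arm1 == "TGG" &
                  flank$arm2 == "CCA"))
  s2 <- paste0(randomSeq(20), "CGG", "CCG", randomSeq(20))
  hits2 <- scanBreakpointRepeats(s2, junction = 23, minArm = 3)
  flank2 <- hits2[hits2$arm1_end == 23 & hits2$arm2_start == 24, ]
  expect_true(any(flank2$kind == "inverted" & flank2$arm1 == "CGG"))
  # direct repeats are found too
  s3 <- paste0(strrep("T", 20), "ACGAC", "ACGAC", strrep("T", 20))
  d <- scanBreakpointRepeats(s3, junction = 25, minArm = 5)
  expect_true(any(d$kind == "direct" & d$arm_len >= 5))
  expect_error(scanBreakpointRepeats(s1, junction = 0), "inside")
  expect_error(scanBreakpointRepeats(s1, junction = 10, window = 2,
                                     minArm = 3), "window")
})

test_that("the breakpoint scanner equals brute-force enumeration on short sequences", {
  set.seed(53)
  for (rep in 1:25) {
    n <- sample(40:200, 1)
    s <- randomSeq(n)
    j <- sample(16:(n - 16), 1)
    got <- scanBreakpointRepeats(s, j)
    want <- oracleRepeatScan(s, j)
    key <- function(d) sort(paste(d$kind, d$arm1_start, d$arm2_start, d$arm_len))
    expect_equal(key(got), key(want))
  }
  # stringent arms on random sequence: almost surely empty
  set.seed(54)
  expect_equal(nrow(scanBreakpointRepeats(randomSeq(200), 100,
                                          window = 10, minArm = 8)), 0L)
})

test_that("scanning the reverse complement mirrors the hit set", {
  set.seed(59)
  s <- paste0(randomSeq(18), "TGGCCA", randomSeq(18))
  n <- nchar(s)
  j <- 21L
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- scanBreakpointRepeats(s, j)
  b <- scanBreakpointRepeats(rc, n - j)
  expect_equal(nrow(a), nrow(b))
  keyA <- sort(paste(a$kind, a$arm_len, a$spacer))
  keyB <- sort(paste(b$kind, b$arm_len, b$spacer))
  expect_equal(keyA, keyB)
})

test_that("the mechanism classifier covers the full evidence grid", {
  hit <- data.frame(kind = "inverted", arm_len = 3)
  none <- hit[0, ]
  expect_equal(classifyLossMechanism(1, hit), "repeat_mediated")
  expect_equal(classifyLossMechanism(1, none), "simple_deletion")
  expect_equal(classifyLossMechanism(1, NULL), "simple_deletion")
  expect_equal(classifyLossMechanism(2, none), "mrna_mediated")
  expect_equal(classifyLossMechanism(3, NULL), "mrna_mediated")
  expect_equal(classifyLossMechanism(2, hit), "indeterminate")
  expect_equal(classifyLossMechanism(data.frame(multiplicity = 1), hit),
               "repeat_mediated")
})

test_that("planted mechanisms are recovered perfectly at zero noise", {
  cfg <- familyConfig(taxa = c("rice", "sorghum", "brachypodium", "wheat"),
                      tree = "(rice,(sorghum,(brachypodium,wheat)));",
                      lossProbPerBranch = 0, substRate = 0,
                      plantedRepeatArmLen = 5, seed = 61)
  fl <- data.frame(site = c(1, 3, 2, 4),
                   branch = c("wheat", "wheat", "sorghum", "brachypodium"),
                   mechanism = c("repeat_mediated", "repeat_mediated",
                                 "simple_deletion", "simple_deletion"))
  fam <- simulateGeneFamily(cfg, forcedLosses = fl)
  m <- mapIntronSites(trueStructures(fam), fam@cds)
  ev <- inferLossEvents(m, fam@tree)
  anc <- fam@ancestralSites
  for (i in seq_len(nrow(ev))) {
    br <- ev$branch[i]
    gene <- if (br %in% colnames(presenceCells(m))) br else next
    coord <- m@geneCoords[ev$site[i], gene]
    cds <- as.character(fam@cds[[gene]])
    reps <- scanBreakpointRepeats(cds, coord)
    # breakpoint evidence: arms of at least the planted length abutting
    # the junction on both sides
    reps <- reps[reps$arm_len >= 5 & reps$distance == 0, , drop = FALSE]
    got <- classifyLossMechanism(ev[i, ], reps)
    want <- fam@events$mechanism[fam@events$branch == br &
                                 fam@events$site == ev$site[i]]
    expect_equal(got, want)
  }
})

test_that("planted TIR elements are recovered at exact coordinates", {
  arm <- "GGATCCTTGACCAT"
  rcArm <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
  set.seed(67)
  # interior ends chosen so chance inward arm extension is impossible
  interior <- paste0("A", randomSeq(70), "A")
  elem <- paste0(arm, interior, rcArm)       # perfect 14-nt TIRs, 100 nt
  # poly-A background guarantees no spurious arm matches or extensions
  s <- paste0(strrep("A", 150), elem, strrep("A", 150))
  hits <- findTirElements(s, minTir = 10, maxLen = 200, maxMismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 151L)
  expect_equal(hits$end, 150L + nchar(elem))
  expect_equal(hits$tir_len, 14L)
  # the same element inserted elsewhere in inverted orientation: both
  # copies are found and their orientation flags differ
  # the copies sit further apart than maxLen so the palindromic
  # cross-pairing between them is out of range
  rcElem <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(elem)))
  s2 <- paste0(strrep("A", 100), elem, strrep("A", 300), rcElem,
               strrep("A", 100))
  hits2 <- findTirElements(s2, minTir = 10, maxLen = 200, maxMismatch = 0)
  expect_equal(nrow(hits2), 2L)
  expect_equal(length(unique(hits2$orientation)), 2L)
  # a repeat-free sequence yields nothing
  expect_equal(nrow(findTirElements(strrep("A", 400), minTir = 10,
                                    maxLen = 200)), 0L)
  expect_error(findTirElements(s, minTir = 0), "positive")
})

test_that("an exact downstream exon copy is reported with its offset", {
  set.seed(71)
  ex <- randomSeq(120)
  d <- 400L
  gen <- paste0(randomSeq(500), ex, randomSeq(d - 1L), ex, randomSeq(200))
  # stop codon ends where the (first) exon copy ends
  dup <- findExonDuplication(gen, ex, stopCodonPos = 620L)
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$orientation, "+")
  expect_equal(dup$offset, d)
  expect_equal(dup$identity, 1)
  expect_equal(dup$n_deletions, 0L)
  expect_error(findExonDuplication(gen, randomSeq(20), 620L), "30 nt")
})

test_that("the synthetic PSY3D locus carries the planted duplication signature", {
  fam <- syntheticPsy3Family(seed = 42)
  g <- as.character(fam$genomic[["PSY3D"]])
  ex4 <- substr(g, IRanges::start(exonRanges(fam$structures[["PSY3D"]]))[4],
                IRanges::end(exonRanges(fam$structures[["PSY3D"]]))[4])
  stopPos <- fam$stopCodonPos[["PSY3D"]]
  dup <- findExonDuplication(g, ex4, stopPos)
  expect_equal(dup$orientation, "-")
  expect_equal(dup$offset, 1729L)
  dup2 <- findExonDuplication(g, fam$duplication$source_segment, stopPos)
  dels <- dup2$deletions[[1]]
  expect_equal(dels$length, 154L)
  expect_match(dels$flank_motif, "TACTGG")
})

test_that("cis-element scanning finds palindromes on both strands and planted motifs exactly", {
  # palindromic G-box gives one hit per strand at the same site
  p <- paste0(strrep("T", 40), "CACGTG", strrep("T", 40))
  hits <- scanCisElements(p)
  gbox <- hits[hits$motif == "G-box", ]
  expect_equal(nrow(gbox), 2L)
  expect_equal(unique(gbox$start), 41L)
  expect_setequal(gbox$strand, c("+", "-"))
  # relative position is anchored at the 3' end
  expect_equal(unique(gbox$rel_start), 41L - (nchar(p) + 1L))
  # a promoter without ACGT cannot contain an ABRE
  noACGT <- strrep("TTGG", 100)
  expect_equal(nrow(scanCisElements(noACGT)), 0L)
  # planted motif set on a motif-free background: full recall, exact sites
  bg <- strrep("T", 600)
  plant <- list(ABRE = c(101, "ACGTG"), CE1 = c(301, "TGCCACCGG"),
                CE3 = c(501, "ACGCGTGTC"))
  for (nm in names(plant))
    substr(bg, as.integer(plant[[nm]][1]),
           as.integer(plant[[nm]][1]) + nchar(plant[[nm]][2]) - 1L) <-
      plant[[nm]][2]
  hits2 <- scanCisElements(bg)
  for (nm in names(plant)) {
    h <- hits2[hits2$motif == nm & hits2$strand == "+", ]
    expect_equal(h$start, as.integer(plant[[nm]][1]))
  }
  # unknown IUPAC codes are rejected
  expect_error(scanCisElements(p, data.frame(name = "x", consensus = "ACGJ")),
               "IUPAC")
})
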