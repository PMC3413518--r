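test_that("an intronless gene maps to a single exon spanning its template copy", {
  set.seed(31)
  cds <- randomSeq(600)
  gs <- splicedAlign(cds, cds)
  expect_equal(length(exonRanges(gs)), 1L)
  expect_equal(IRanges::start(exonRanges(gs)), 1L)
  expect_equal(IRanges::end(exonRanges(gs)), 600L)
  # embedded in flanks
  gen <- paste0(randomSeq(200), cds, randomSeq(150))
  gs2 <- splicedAlign(cds, gen)
  expect_equal(IRanges::start(exonRanges(gs2)), 201L)
  expect_equal(sum(IRanges::width(exonRanges(gs2))), 600L)
})

test_that("zero-noise synthetic genes recover their true exon intervals exactly", {
  cfg <- familyConfig(taxa = c("rice", "sorghum", "brachypodium", "wheat"),
                      tree = "(rice,(sorghum,(brachypodium,wheat)));",
                      lossProbPerBranch = 0.25, substRate = 0, seed = 19)
  fam <- simulateGeneFamily(cfg)
  for (g in names(trueStructures(fam))) {
    got <- splicedAlign(fam@cds[[g]], fam@genomic[[g]], geneId = g)
    want <- trueStructures(fam)[[g]]
    expect_equal(IRanges::start(exonRanges(got)),
                 IRanges::start(exonRanges(want)))
    expect_equal(IRanges::end(exonRanges(got)), IRanges::end(exonRanges(want)))
    # splice-and-compare invariant
    expect_equal(as.character(spliceGenomic(fam@genomic[[g]], got)),
                 as.character(fam@cds[[g]]))
  }
})

test_that("structures survive homoeolog-level divergence within the mismatch budget", {
  cfg <- familyConfig(taxa = c("a", "b"), tree = "(a,b);",
                      lossProbPerBranch = 0, substRate = 0.02, seed = 23)
  fam <- simulateGeneFamily(cfg)
  g <- "b"
  got <- splicedAlign(fam@cds[[g]], fam@genomic[[g]])
  want <- trueStructures(fam)[[g]]
  expect_equal(IRanges::start(exonRanges(got)), IRanges::start(exonRanges(want)))
})

test_that("reverse-complementing the template yields the mirror structure", {
  cfg <- familyConfig(taxa = c("a", "b"), tree = "(a,b);",
                      lossProbPerBranch = 0, substRate = 0, seed = 29)
  fam <- simulateGeneFamily(cfg)
  g <- "a"
  gen <- as.character(fam@genomic[[g]])
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gen)))
  fwd <- splicedAlign(fam@cds[[g]], gen)
  rev <- splicedAlign(fam@cds[[g]], rc)
  expect_equal(rev@strand, "-")
  n <- nchar(gen)
  expect_equal(sort(n - IRanges::end(exonRanges(rev)) + 1L),
               sort(IRanges::start(exonRanges(fwd))))
  expect_equal(as.character(spliceGenomic(rc, rev)), as.character(fam@cds[[g]]))
})

test_that("an unalignable CDS raises a structured no-structure failure", {
  set.seed(37)
  expect_error(splicedAlign(randomSeq(300), randomSeq(2000)),
               class = "grasstruct_no_structure")
})

test_that("intron phase is the cumulative coding length mod 3", {
  # exons of 10 and 20 coding bases -> phase 1; 9 and 21 -> phase 0
  mk <- function(l1, l2) {
    intron <- paste0("GT", strrep("A", 46), "AG")
    e1 <- randomSeq(l1); e2 <- randomSeq(l2)
    gen <- paste0(e1, intron, e2)
    gs <- GeneStructure("g", IRanges::IRanges(
      start = c(1, l1 + 51), end = c(l1, l1 + 50 + l2)))
    annotateIntrons(gs, gen)
  }
  set.seed(41)
  expect_equal(mk(10, 20)$phase, 1L)
  expect_equal(mk(9, 21)$phase, 0L)
  rec <- mk(12, 24)
  expect_equal(rec$donor, "GT")
  expect_equal(rec$acceptor, "AG")
  expect_true(rec$canonical)
})

test_that("GC..AG introns are flagged as the non-canonical GC class", {
  set.seed(43)
  e1 <- randomSeq(30); e2 <- randomSeq(30)
  gen <- paste0(e1, "GC", strrep("T", 40), "AG", e2)
  gs <- GeneStructure("g", IRanges::IRanges(start = c(1, 75), end = c(30, 104)))
  rec <- annotateIntrons(gs, gen)
  expect_false(rec$canonical)
  expect_equal(rec$class, "non-canonical-GC")
  # abutting exons are an error, not an intron
  gs2 <- GeneStructure("g", IRanges::IRanges(start = c(1, 31), end = c(30, 60)))
  expect_error(annotateIntrons(gs2, gen), "zero gap")
})

test_that("in-silico PCR respects product geometry and the 3' exact-match rule", {
  set.seed(47)
  tpl <- randomSeq(400)
  fwd <- substr(tpl, 1, 20)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tpl, 381, 400))))
  p <- insilicoPcr(fwd, rev, tpl)
  expect_equal(nrow(p), 1L)
  expect_equal(p$product_length, 400L)
  # a 3'-terminal mismatch kills the product even with mismatch allowance
  bad <- fwd
  substr(bad, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 20, 20))[1]
  expect_equal(nrow(insilicoPcr(bad, rev, tpl, maxMismatches = 2)), 0L)
  # an internal mismatch is tolerated when allowed
  mid <- fwd
  substr(mid, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 10, 10))[1]
  expect_equal(nrow(insilicoPcr(mid, rev, tpl, maxMismatches = 0)), 0L)
  pm <- insilicoPcr(mid, rev, tpl, maxMismatches = 1)
  expect_equal(pm$product_length, 400L)
  expect_equal(pm$mismatches_forward, 1L)
  expect_error(insilicoPcr("ACGTACGT", rev, tpl), "at least 15")
})

test_that("the synthetic PSY3-like primers amplify 216 bp from all three copies", {
  fam <- syntheticPsy3Family(seed = 42)
  for (g in names(fam$structures)) {
    p <- insilicoPcr(fam$primers$forward, fam$primers$reverse,
                     fam$genomic[[g]], templateId = g)
    expect_equal(p$product_length, 216L)
  }
})
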