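grassCfg <- function(...) {
  familyConfig(taxa = c("rice", "sorghum", "brachypodium", "wheat"),
               tree = "(rice,(sorghum,(brachypodium,wheat)));", ...)
}

test_that("the no-loss limit gives every taxon the ancestral structure", {
  fam <- simulateGeneFamily(grassCfg(lossProbPerBranch = 0, seed = 3))
  expect_equal(nrow(trueEvents(fam)), 0L)
  nExons <- vapply(trueStructures(fam),
                   function(s) length(exonRanges(s)), integer(1))
  expect_true(all(nExons == 6L))
})

test_that("forced losses reproduce the published exon-count configuration", {
  fl <- data.frame(site = c(3, 3, 1, 3),
                   branch = c("brachypodium", "sorghum", "wheat", "wheat"))
  fam <- simulateGeneFamily(grassCfg(lossProbPerBranch = 0, substRate = 0,
                                     seed = 7), forcedLosses = fl)
  nExons <- vapply(trueStructures(fam),
                   function(s) length(exonRanges(s)), integer(1))
  expect_equal(nExons[["rice"]], 6L)
  expect_equal(nExons[["sorghum"]], 5L)
  expect_equal(nExons[["brachypodium"]], 5L)
  expect_equal(nExons[["wheat"]], 4L)
  expect_equal(nrow(trueEvents(fam)), 4L)
})

test_that("simulation is deterministic: same seed, byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- grassCfg(lossProbPerBranch = 0.2, seed = 13)
  writeFamily(simulateGeneFamily(cfg), d1)
  writeFamily(simulateGeneFamily(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # and a different seed changes the sequences
  cfg2 <- grassCfg(lossProbPerBranch = 0.2, seed = 14)
  fam2 <- simulateGeneFamily(cfg2)
  expect_false(identical(as.character(fam2@cds[[1]]),
                         as.character(simulateGeneFamily(cfg)@cds[[1]])))
})

test_that("true exons always splice back to the CDS byte-for-byte", {
  for (seed in c(5, 6)) {
    fam <- simulateGeneFamily(grassCfg(lossProbPerBranch = 0.3,
                                       substRate = 0.03, nHomoeologs = 2,
                                       seed = seed))
    for (g in names(trueStructures(fam)))
      expect_identical(
        as.character(spliceGenomic(fam@genomic[[g]], trueStructures(fam)[[g]])),
        as.character(fam@cds[[g]]))
  }
})

test_that("every true loss event removes an intron present in the parent lineage", {
  fam <- simulateGeneFamily(grassCfg(lossProbPerBranch = 0.3, seed = 17))
  ev <- trueEvents(fam)
  if (nrow(ev)) {
    # no site is lost twice along one root-to-tip path
    sitesOf <- strsplit(ev$sites, ",")
    tr <- fam@tree
    desc <- function(lab) {
      if (lab %in% tr$tip.label) return(lab)
      n <- length(tr$tip.label) + which(tr$node.label == lab)
      ape::extract.clade(tr, n)$tip.label
    }
    for (s in unique(unlist(sitesOf))) {
      br <- ev$branch[vapply(sitesOf, function(x) s %in% x, logical(1))]
      affected <- unlist(lapply(br, desc))
      expect_equal(anyDuplicated(affected), 0L)
    }
  }
  # an unrooted tree is rejected up front
  expect_error(familyConfig(taxa = c("a", "b", "c"), tree = "(a:1,b:1,c:1);"),
               "rooted")
})

test_that("repeat-mediated losses plant an inverted repeat across the junction", {
  cfg <- grassCfg(lossProbPerBranch = 0.4, substRate = 0,
                  mechanismMix = c(repeat_mediated = 1, simple_deletion = 0,
                                   mrna_mediated = 0), seed = 31)
  fam <- simulateGeneFamily(cfg)
  rp <- fam@repeats
  expect_gt(nrow(rp), 0L)
  for (i in seq_len(nrow(rp))) {
    # the motif and its reverse complement straddle the junction in every
    # descendant carrying the loss
    ev <- trueEvents(fam)
    coord <- rp$cds_coord[i]; arm <- rp$arm_len[i]
    tips <- if (rp$branch[i] %in% fam@tree$tip.label) rp$branch[i]
            else ape::extract.clade(fam@tree, which(c(fam@tree$tip.label,
                 fam@tree$node.label) == rp$branch[i]))$tip.label
    for (g in tips) {
      cds <- as.character(fam@cds[[g]])
      left <- substr(cds, coord - arm + 1, coord)
      right <- substr(cds, coord + 1, coord + arm)
      expect_equal(right, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(left))))
    }
  }
})

test_that("fragmented HSP tables conserve lengths and identities", {
  cfg <- familyConfig(taxa = c("a", "b"), tree = "(a,b);",
                      lossProbPerBranch = 0, substRate = 0.02, seed = 11)
  fam <- simulateGeneFamily(cfg)
  one <- simulateHspTable(fam, "b", fragmentation = 1, seed = 2)
  three <- simulateHspTable(fam, "b", fragmentation = 3, seed = 2)
  expect_equal(nrow(one$hsps), 1L)
  expect_equal(nrow(three$hsps), 3L)
  expect_equal(sum(three$hsps$aligned_length), one$hsps$aligned_length)
  expect_equal(sum(three$hsps$identity_count), one$hsps$identity_count)
  # zero noise, fragmentation 1: identity equals length
  noiseless <- simulateHspTable(fam, "b", seed = 2)
  expect_lte(noiseless$hsps$identity_count, noiseless$hsps$aligned_length)
  # decoys carry the PAV truth label
  dec <- simulateHspTable(fam, "b", decoys = 2, seed = 3)
  expect_equal(dec$truth$class[grepl("^decoy", dec$truth$query_id)],
               c("PAV", "PAV"))
})

test_that("the Cq generator inverts exactly at zero noise", {
  cfg <- cqConfig(cqNoiseSd = 0, seed = 5)
  sim <- simulateCqTable(cfg)
  fc <- foldChangeTable(sim$cq, sim$efficiencies)
  # every planted fold is recovered exactly
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$truth[i, ]
    got <- fc[fc$gene == row$gene & fc$tissue == row$tissue &
              fc$time_h == row$time_h & fc$treatment == 50, ]
    expect_equal(got$fold_change, row$fold, tolerance = 1e-10)
  }
  # flat profile: all ratios 1
  flat <- cqConfig(cqNoiseSd = 0, seed = 5,
                   foldProfile = data.frame(gene = "PSY1", tissue = "leaf",
                                            time_h = 0, fold = 1))
  fcFlat <- foldChangeTable(simulateCqTable(flat)$cq, flat$efficiencies)
  expect_true(all(abs(fcFlat$fold_change - 1) < 1e-10))
})

test_that("noisy Cq tables recover planted folds within Monte-Carlo error", {
  cfg <- cqConfig(cqNoiseSd = 0.15, seed = 9)
  sim <- simulateCqTable(cfg)
  fc <- foldChangeTable(sim$cq, sim$efficiencies)
  got <- fc[fc$gene == "PSY3" & fc$tissue == "root" & fc$treatment == 100 &
            fc$time_h == 2, ]
  # 18-fold planted; 0.15 cycles of noise on 3 replicates
  expect_gt(got$fold_change, 18 / 2)
  expect_lt(got$fold_change, 18 * 2)
})
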