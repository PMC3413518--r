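test_that("identical genes give an all-present matrix with one row per intron", {
  fix <- fig2cStructures()
  two <- fix$structures[c("rice", "maize")]
  m <- mapIntronSites(two, fix$cds)
  expect_equal(nrow(siteTable(m)), 5L)
  expect_true(all(presenceCells(m) == "present"))
})

test_that("zero-noise synthetic families reproduce the generator's truth matrix", {
  cfg <- familyConfig(taxa = c("rice", "sorghum", "brachypodium", "wheat"),
                      tree = "(rice,(sorghum,(brachypodium,wheat)));",
                      lossProbPerBranch = 0.25, substRate = 0, seed = 19)
  fam <- simulateGeneFamily(cfg)
  m <- mapIntronSites(trueStructures(fam), fam@cds)
  anc <- fam@ancestralSites
  # site coordinates match the ancestral truth
  expect_true(all(siteTable(m)$coord %in% anc$coord))
  for (g in colnames(presenceCells(m))) {
    truthPresent <- intronCoords(trueStructures(fam)[[g]])$coord
    gotPresent <- siteTable(m)$coord[presenceCells(m)[, g] == "present"]
    expect_equal(sort(gotPresent), sort(truthPresent))
  }
})

test_that("gene input order does not change the matrix or the events", {
  fix <- fig2cStructures()
  m1 <- mapIntronSites(fix$structures, fix$cds, reference = "rice")
  perm <- rev(names(fix$structures))
  m2 <- mapIntronSites(fix$structures[perm], fix$cds, reference = "rice")
  expect_equal(siteTable(m1), siteTable(m2))
  expect_equal(presenceCells(m1)[, colnames(presenceCells(m1))],
               presenceCells(m2)[, colnames(presenceCells(m1))])
  e1 <- inferLossEvents(m1, GRASS_TREE)
  e2 <- inferLossEvents(m2, GRASS_TREE)
  expect_equal(e1, e2)
})

test_that("the published five-taxon configuration yields three independent losses", {
  fix <- fig2cStructures()
  m <- mapIntronSites(fix$structures, fix$cds, reference = "rice")
  expect_equal(nrow(siteTable(m)), 5L)
  # wheat lacks ancestral introns 1 and 3
  wheatAbsent <- which(presenceCells(m)[, "wheat"] == "absent")
  expect_equal(wheatAbsent, c(1L, 3L))
  ev <- inferLossEvents(m, GRASS_TREE)
  expect_equal(nrow(ev), 3L)
  # third intron lost independently on the sorghum branch and on the
  # brachypodium+wheat ancestral branch; first intron on wheat alone
  site3 <- ev[ev$site == 3, ]
  expect_setequal(site3$branch, c("sorghum", "n4"))
  expect_equal(ev$branch[ev$site == 1], "wheat")
  expect_true(all(ev$multiplicity == 1L))
})

test_that("an all-present matrix yields zero loss events", {
  fix <- fig2cStructures()
  m <- mapIntronSites(fix$structures[c("rice", "maize")], fix$cds)
  tr <- "(rice,maize);"
  expect_equal(nrow(inferLossEvents(m, tr)), 0L)
})

test_that("Dollo inference matches exhaustive minimal reconstructions on all 2^4 patterns", {
  tree <- ape::makeNodeLabel(readSpeciesTree(text = "((a,b),(c,d));"),
                             prefix = "n")
  for (mask in 0:15) {
    states <- ifelse(bitwAnd(bitwShiftR(mask, 0:3), 1L) == 1L,
                     "present", "absent")
    names(states) <- c("a", "b", "c", "d")
    cells <- matrix(states, nrow = 1, dimnames = list(NULL, names(states)))
    m <- new("IntronSiteMatrix",
             sites = data.frame(coord = 99L, phase = 0L),
             cells = cells,
             geneCoords = matrix(99, 1, 4, dimnames = list(NULL, names(states))),
             reference = "a")
    got <- inferLossEvents(m, tree)
    if (!any(states == "present")) {
      expect_equal(nrow(got), 0L)
      next
    }
    want <- oracleDollo(tree, as.list(states))
    expect_equal(nrow(got), want$min)
    expect_true(list(sort(got$branch)) %in% want$sets ||
                (want$min == 0 && nrow(got) == 0))
  }
})

test_that("Dollo handles missing data and polytomies without forcing losses", {
  tree <- ape::makeNodeLabel(readSpeciesTree(text = "((a,b,c),(d,e));"),
                             prefix = "n")
  states <- c(a = "present", b = "unalignable", c = "absent",
              d = "absent", e = "unalignable")
  cells <- matrix(states, nrow = 1, dimnames = list(NULL, names(states)))
  m <- new("IntronSiteMatrix", sites = data.frame(coord = 3L, phase = 0L),
           cells = cells,
           geneCoords = matrix(3, 1, 5, dimnames = list(NULL, names(states))),
           reference = "a")
  got <- inferLossEvents(m, tree)
  want <- oracleDollo(tree, as.list(states))
  expect_equal(nrow(got), want$min)
  expect_true(list(sort(got$branch)) %in% want$sets)
  # randomized agreement on a 6-leaf tree including missing data
  tree6 <- ape::makeNodeLabel(
    readSpeciesTree(text = "((a,(b,c)),((d,e),f));"), prefix = "n")
  set.seed(71)
  for (rep in 1:40) {
    st <- sample(c("present", "absent", "unalignable"), 6, replace = TRUE,
                 prob = c(.5, .35, .15))
    names(st) <- letters[1:6]
    if (!any(st == "present")) next
    cells <- matrix(st, nrow = 1, dimnames = list(NULL, names(st)))
    m6 <- new("IntronSiteMatrix", sites = data.frame(coord = 3L, phase = 0L),
              cells = cells,
              geneCoords = matrix(3, 1, 6, dimnames = list(NULL, names(st))),
              reference = "a")
    got <- inferLossEvents(m6, tree6)
    want <- oracleDollo(tree6, as.list(st))
    expect_equal(nrow(got), want$min)
  }
})

test_that("adding an all-present taxon never increases any site's loss count", {
  fix <- fig2cStructures()
  full <- readSpeciesTree(text = GRASS_TREE)
  pruned <- ape::drop.tip(full, "maize")
  m4 <- mapIntronSites(fix$structures[c("rice", "sorghum", "brachypodium",
                                        "wheat")], fix$cds, reference = "rice")
  e4 <- inferLossEvents(m4, pruned)
  m5 <- mapIntronSites(fix$structures, fix$cds, reference = "rice")
  e5 <- inferLossEvents(m5, full)   # maize (all sites present) added
  for (s in 1:5)
    expect_lte(sum(e5$site == s), sum(e4$site == s))
})

test_that("adjacent sites lost on one branch merge into one multi-intron event", {
  fix <- fig2cStructures()
  st <- fix$structures
  # build a taxon lacking ancestral introns 2 and 3 (adjacent)
  exonLens <- fix$exonLens
  sites <- fix$sites
  keep <- c(1, 4, 5)
  cuts <- c(0, sites[keep], sum(exonLens))
  stElt <- integer(); en <- integer(); gpos <- 100
  for (w in diff(cuts)) {
    stElt <- c(stElt, gpos + 1); gpos <- gpos + w; en <- c(en, gpos)
    gpos <- gpos + 250
  }
  st$wheat <- GeneStructure("wheat", IRanges::IRanges(start = stElt, end = en),
                            taxon = "wheat", genomicId = "wheat")
  st <- st[c("rice", "maize", "wheat")]   # wheat alone lacks sites 2 and 3
  m <- mapIntronSites(st, fix$cds, reference = "rice")
  ev <- inferLossEvents(m, "(maize,(rice,wheat));")
  run <- ev[ev$branch == "wheat" & ev$multiplicity == 2, ]
  expect_equal(nrow(run), 1L)
  expect_equal(run$sites, "2,3")
  expect_equal(run$mechanism, "mrna_mediated")
})

test_that("exon fusions report the flanking ancestral exons and exact junctions", {
  fix <- fig2cStructures()
  m <- mapIntronSites(fix$structures, fix$cds, reference = "rice")
  fus <- detectExonFusions(m, fix$structures)
  wf <- fus[fus$gene_id == "wheat", ]
  expect_equal(wf$ancestral_exons, c("1+2", "3+4"))
  expect_equal(wf$fused_exon, c(1L, 2L))
  # junction coordinate: ancestral site coord minus coding bases upstream
  # of the modern exon
  expect_equal(wf$junction_coord[1], fix$sites[1])
  expect_equal(wf$junction_coord[2],
               as.integer(fix$sites[3] - sum(fix$exonLens[1:2])))
  # taxa with no absences contribute nothing
  expect_false("rice" %in% fus$gene_id)
  expect_false("maize" %in% fus$gene_id)
})

test_that("synthetic truth fusions are recovered exactly at zero noise", {
  cfg <- familyConfig(taxa = c("rice", "sorghum", "brachypodium", "wheat"),
                      tree = "(rice,(sorghum,(brachypodium,wheat)));",
                      lossProbPerBranch = 0, substRate = 0, seed = 7)
  fl <- data.frame(site = c(1, 3), branch = c("wheat", "wheat"))
  fam <- simulateGeneFamily(cfg, forcedLosses = fl)
  m <- mapIntronSites(trueStructures(fam), fam@cds)
  fus <- detectExonFusions(m, trueStructures(fam))
  wf <- fus[fus$gene_id == "wheat", ]
  anc <- fam@ancestralSites
  w <- IRanges::width(exonRanges(trueStructures(fam)[["wheat"]]))
  expect_equal(wf$junction_coord[1], anc$coord[1])
  expect_equal(wf$junction_coord[2], as.integer(anc$coord[3] - sum(w[1])))
})

test_that("an internal stop codon in a CDS is reported by gene name", {
  fix <- fig2cStructures()
  cds <- as.character(fix$cds)
  bad <- cds[["rice"]]
  substr(bad, 301, 303) <- "TAA"
  cds[["rice"]] <- bad
  expect_error(mapIntronSites(fix$structures, cds), "rice")
})
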