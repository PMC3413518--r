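#' Intron coordinates of a gene structure in its own CDS
#'
#' @param structure a \linkS4class{GeneStructure}.
#' @return data.frame with \code{coord} (coding bases upstream of each
#'   intron) and \code{phase}.
#' @export
intronCoords <- function(structure) {
  w <- width(structure@exons)
  if (length(w) < 2L)
    return(data.frame(coord = integer(), phase = integer()))
  cum <- cumsum(w[-length(w)])
  data.frame(coord = as.integer(cum), phase = as.integer(cum %% 3L))
}

#' Map intron positions across orthologs to homologous sites
#'
#' Projects every gene's intron positions onto a reference CDS through
#' codon-aware pairwise alignment (translated sequences are aligned
#' globally and coordinates projected back to nucleotides), then merges
#' positions into one homologous site only when the projected coordinate
#' and the phase coincide exactly. Near-miss positions at most one codon
#' apart raise a warning but are never merged (intron sliding is treated as
#' non-homology). Cells are \code{present}, \code{absent} (the region
#' aligns but carries no intron) or \code{unalignable}.
#'
#' @param structures named list of \linkS4class{GeneStructure} objects
#'   (at least two).
#' @param cdsSet \code{DNAStringSet} (or named character) of the CDS of
#'   each gene; an internal stop codon raises an error naming the gene.
#' @param reference gene id used as projection reference; defaults to a
#'   gene with the maximal intron count.
#' @return an \linkS4class{IntronSiteMatrix}.
#' @export
mapIntronSites <- function(structures, cdsSet, reference = NULL) {
  if (length(structures) < 2L)
    stop("need at least two gene structures", call. = FALSE)
  cdsSet <- Biostrings::DNAStringSet(cdsSet)
  ids <- names(structures)
  if (!all(ids %in% names(cdsSet)))
    stop("every structure needs a CDS of the same name", call. = FALSE)

  aa <- lapply(ids, function(g) {
    s <- cdsSet[[g]]
    if (Biostrings::nchar(s) %% 3L != 0L)
      stop("CDS length of ", g, " is not a multiple of 3", call. = FALSE)
    p <- suppressWarnings(Biostrings::translate(s))
    pc <- as.character(p)
    core <- sub("\\*$", "", pc)
    if (grepl("*", core, fixed = TRUE))
      stop("internal stop codon in CDS of ", g, call. = FALSE)
    core
  })
  names(aa) <- ids

  if (is.null(reference)) {
    nInt <- vapply(structures, function(s) length(s@exons) - 1L, integer(1))
    reference <- ids[[which.max(nInt)]]
  }

  # codon maps gene -> reference and reference -> gene through global
  # protein alignment
  refAA <- aa[[reference]]
  maps <- lapply(ids, function(g) {
    if (g == reference) {
      n <- nchar(refAA)
      return(list(toRef = seq_len(n), fromRef = seq_len(n)))
    }
    pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(aa[[g]]),
                                        Biostrings::AAString(refAA),
                                        type = "global",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 4)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    gi <- cumsum(p != "-")
    ri <- cumsum(s != "-")
    toRef <- rep(NA_integer_, nchar(aa[[g]]))
    fromRef <- rep(NA_integer_, nchar(refAA))
    both <- p != "-" & s != "-"
    toRef[gi[both]] <- ri[both]
    fromRef[ri[both]] <- gi[both]
    list(toRef = toRef, fromRef = fromRef)
  })
  names(maps) <- ids

  # project every intron of every gene onto the reference coordinates
  proj <- list()
  for (g in ids) {
    ic <- intronCoords(structures[[g]])
    for (i in seq_len(nrow(ic))) {
      c0 <- ic$coord[i]; ph <- ic$phase[i]
      anchor <- c0 %/% 3L + 1L          # codon containing/just after the site
      refCodon <- if (anchor <= length(maps[[g]]$toRef))
        maps[[g]]$toRef[anchor] else NA_integer_
      proj[[length(proj) + 1L]] <- data.frame(
        gene = g, coord = c0, phase = ph,
        ref_coord = if (is.na(refCodon)) NA_integer_
                    else 3L * (refCodon - 1L) + ph,
        stringsAsFactors = FALSE)
    }
  }
  proj <- do.call(rbind, proj)
  if (is.null(proj) || !nrow(proj)) {
    sites <- data.frame(coord = integer(), phase = integer())
    cells <- matrix(character(), 0L, length(ids), dimnames = list(NULL, ids))
    return(new("IntronSiteMatrix", sites = sites, cells = cells,
               geneCoords = matrix(numeric(), 0L, length(ids),
                                   dimnames = list(NULL, ids)),
               reference = reference))
  }
  mapped <- proj[!is.na(proj$ref_coord), , drop = FALSE]
  siteCoords <- sort(unique(mapped$ref_coord))
  if (length(siteCoords) > 1L) {
    d <- diff(siteCoords)
    near <- which(d > 0 & d <= 3L)
    for (i in near)
      if (siteCoords[i] %% 3L == siteCoords[i + 1L] %% 3L)
        warning(sprintf(
          "intron sites at reference coordinates %d and %d are within one codon; kept separate",
          siteCoords[i], siteCoords[i + 1L]), call. = FALSE)
  }
  sites <- data.frame(coord = siteCoords,
                      phase = as.integer(siteCoords %% 3L))
  cells <- matrix("absent", nrow(sites), length(ids),
                  dimnames = list(NULL, ids))
  geneCoords <- matrix(NA_real_, nrow(sites), length(ids),
                       dimnames = list(NULL, ids))
  for (k in seq_len(nrow(sites))) {
    rc <- sites$coord[k]; ph <- sites$phase[k]
    refCodon <- rc %/% 3L + 1L
    for (g in ids) {
      hit <- mapped$gene == g & mapped$ref_coord == rc
      if (any(hit)) {
        cells[k, g] <- "present"
        geneCoords[k, g] <- mapped$coord[hit][1L]
      } else {
        gc <- if (refCodon <= length(maps[[g]]$fromRef))
          maps[[g]]$fromRef[refCodon] else NA_integer_
        if (is.na(gc)) cells[k, g] <- "unalignable"
        else geneCoords[k, g] <- 3L * (gc - 1L) + ph
      }
    }
  }
  new("IntronSiteMatrix", sites = sites, cells = cells,
      geneCoords = geneCoords, reference = reference)
}

#' Infer intron-loss events by Dollo parsimony
#'
#' Each intron site is assumed gained once at the root (the ancestral state
#' is present whenever at least one taxon retains the intron) and lost any
#' number of times. The minimum set of loss branches follows from a
#' post-order reconstruction: a loss is placed on the highest branch whose
#' subtree contains at least one taxon scored absent and none scored
#' present. Unalignable cells are missing data and never force a loss.
#' Adjacent sites lost on the same branch are merged into one event with
#' multiplicity; events of multiplicity two or more are labeled
#' \code{mrna_mediated} (one spliced-transcript recombination removes a run
#' of adjacent introns), single-site losses are left \code{indeterminate}
#' for the breakpoint scanner to resolve.
#'
#' @param matrix an \linkS4class{IntronSiteMatrix} whose columns are the
#'   tree's tips (one gene per taxon).
#' @param tree rooted \code{phylo} species tree, or Newick text.
#' @return data.frame of loss events: \code{site} (first site index),
#'   \code{sites} (comma-separated indices), \code{branch} (label of the
#'   branch's child node), \code{multiplicity}, \code{mechanism}.
#' @export
inferLossEvents <- function(matrix, tree) {
  if (is.character(tree)) tree <- readSpeciesTree(text = tree)
  if (!ape::is.rooted(tree)) stop("species tree must be rooted", call. = FALSE)
  cells <- presenceCells(matrix)
  if (!setequal(colnames(cells), tree$tip.label))
    stop("matrix columns must match the tree's tip labels", call. = FALSE)
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label)))
    tree <- ape::makeNodeLabel(tree, prefix = "n")
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  labelOf <- function(v) if (v <= nTip) tree$tip.label[v]
                         else tree$node.label[v - nTip]
  kidsOf <- lapply(seq_len(nNode), function(v) tree$edge[tree$edge[, 1] == v, 2])

  lossBranches <- function(state) {
    # state: named over tips, values "present"/"absent"/"unalignable"
    kp <- logical(nNode); ka <- logical(nNode)
    fill <- function(v) {    # recursive post-order; trees are small
      if (v <= nTip) {
        s <- state[[tree$tip.label[v]]]
        kp[v] <<- s == "present"
        ka[v] <<- s == "absent"
      } else {
        for (k in kidsOf[[v]]) fill(k)
        kp[v] <<- any(kp[kidsOf[[v]]])
        ka[v] <<- any(ka[kidsOf[[v]]])
      }
    }
    fill(nTip + 1L)
    out <- character()
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
      if (kp[p] && !kp[c] && ka[c]) out <- c(out, labelOf(c))
    }
    out
  }

  ev <- list()
  for (k in seq_len(nrow(cells))) {
    st <- cells[k, ]
    if (!any(st == "present")) next
    for (b in lossBranches(st))
      ev[[length(ev) + 1L]] <- data.frame(site = k, branch = b,
                                          stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(site = integer(), sites = character(),
                      branch = character(), multiplicity = integer(),
                      mechanism = character(), stringsAsFactors = FALSE))
  ev <- do.call(rbind, ev)
  # merge adjacent sites lost on one branch
  out <- list()
  for (b in unique(ev$branch)) {
    s <- sort(ev$site[ev$branch == b])
    grp <- cumsum(c(1L, diff(s) != 1L))
    for (g in unique(grp)) {
      run <- s[grp == g]
      out[[length(out) + 1L]] <- data.frame(
        site = run[1L], sites = paste(run, collapse = ","), branch = b,
        multiplicity = length(run),
        mechanism = if (length(run) >= 2L) "mrna_mediated" else "indeterminate",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$site, out$branch), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect exon fusions implied by absent intron sites
#'
#' For every site scored absent in a gene, the two reference exons flanking
#' that site have fused in the modern gene. The junction coordinate is the
#' projected position of the lost intron within the modern exon.
#'
#' @param matrix an \linkS4class{IntronSiteMatrix}.
#' @param structures the named list of \linkS4class{GeneStructure} objects
#'   the matrix was built from.
#' @param referenceTaxon optional gene id retaining the full ancestral
#'   intron complement; defaults to the matrix reference when that gene has
#'   all sites present, otherwise the Dollo root reconstruction (the full
#'   site set) is used as the ancestral exon frame.
#' @return data.frame with \code{gene_id}, \code{site} (site index),
#'   \code{fused_exon} (index of the modern exon carrying the junction),
#'   \code{ancestral_exons} (e.g. \code{"1+2"}), \code{junction_coord}
#'   (1-based offset of the last base before the junction within the modern
#'   exon), NA where the site is unalignable.
#' @export
detectExonFusions <- function(matrix, structures, referenceTaxon = NULL) {
  cells <- presenceCells(matrix)
  gc <- matrix@geneCoords
  if (!nrow(cells))
    return(data.frame(gene_id = character(), site = integer(),
                      fused_exon = integer(), ancestral_exons = character(),
                      junction_coord = integer(), stringsAsFactors = FALSE))
  # the ancestral exon frame: site k separates ancestral exons k and k+1
  rows <- list()
  for (g in colnames(cells)) {
    absent <- which(cells[, g] == "absent")
    if (!length(absent)) next
    w <- width(structures[[g]]@exons)
    bounds <- c(0L, cumsum(w))
    for (k in absent) {
      c0 <- gc[k, g]
      if (is.na(c0)) next
      ex <- findInterval(c0, bounds, rightmost.closed = FALSE)
      # a fused junction lies strictly inside its modern exon
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, site = k, fused_exon = ex,
        ancestral_exons = paste0(k, "+", k + 1L),
        junction_coord = as.integer(c0 - bounds[ex]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), site = integer(),
                      fused_exon = integer(), ancestral_exons = character(),
                      junction_coord = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
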