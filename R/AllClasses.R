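#' @import methods
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors isSorted
NULL

#' Exon-intron structure of one gene on a genomic sequence
#'
#' A \code{GeneStructure} holds the ordered exon intervals of a gene on a
#' genomic template, in 1-based inclusive coordinates on the forward strand
#' of that template. Exons are stored in 5'-to-3' order on the coding strand,
#' so for a minus-strand gene the first exon has the largest coordinates.
#' The concatenated (and, for minus-strand genes, reverse-complemented) exon
#' sequence reproduces the CDS up to the spliced-alignment mismatch budget.
#'
#' @slot geneId character(1), gene identifier.
#' @slot taxon character(1), taxon label (may be \code{NA}).
#' @slot genomicId character(1), identifier of the genomic template.
#' @slot strand character(1), \code{"+"} or \code{"-"}.
#' @slot exons an \link[IRanges]{IRanges} of exon intervals on the template.
#' @slot cdsLength integer(1), length of the CDS in bp.
#'
#' @seealso \code{\link{splicedAlign}}, \code{\link{annotateIntrons}}
#' @export
setClass("GeneStructure",
  representation(
    geneId = "character",
    taxon = "character",
    genomicId = "character",
    strand = "character",
    exons = "IRanges",
    cdsLength = "integer"
  )
)

setValidity("GeneStructure", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "at least one exon required")
  if (any(width(ex) <= 0L)) msg <- c(msg, "exon widths must be positive")
  st <- start(ex)
  if (length(ex) > 1L) {
    ordered <- if (object@strand == "+") all(diff(st) > 0) else all(diff(st) < 0)
    if (!ordered) msg <- c(msg, "exons must be ordered 5'->3' on the coding strand")
    # non-overlap: adjacent exons must leave a positive gap
    s <- sort(st)
    e <- sort(end(ex))
    if (any(s[-1] <= e[-length(e)])) msg <- c(msg, "exons must not overlap")
  }
  if (sum(width(ex)) != object@cdsLength)
    msg <- c(msg, "sum of exon widths must equal cdsLength")
  if (length(msg)) msg else TRUE
})

#' Presence/absence of homologous intron sites across genes
#'
#' Rows are intron sites on a reference CDS coordinate system (the number of
#' coding bases upstream of the site, together with the intron phase); columns
#' are genes. Cells take values \code{"present"}, \code{"absent"} or
#' \code{"unalignable"}.
#'
#' @slot sites data.frame with columns \code{coord} (coding bases upstream of
#'   the site on the reference CDS) and \code{phase} (0, 1 or 2).
#' @slot cells character matrix, one row per site, one column per gene.
#' @slot geneCoords numeric matrix of the same shape: each site's
#'   coordinate in each gene's own CDS (coding bases upstream), \code{NA}
#'   where unalignable.
#' @slot reference character(1), gene id of the reference CDS.
#'
#' @seealso \code{\link{mapIntronSites}}, \code{\link{inferLossEvents}}
#' @export
setClass("IntronSiteMatrix",
  representation(
    sites = "data.frame",
    cells = "matrix",
    geneCoords = "matrix",
    reference = "character"
  )
)

setValidity("IntronSiteMatrix", function(object) {
  msg <- character()
  if (!all(c("coord", "phase") %in% names(object@sites)))
    msg <- c(msg, "sites must have columns 'coord' and 'phase'")
  if (nrow(object@sites) != nrow(object@cells))
    msg <- c(msg, "one cells row per site required")
  ok <- object@cells %in% c("present", "absent", "unalignable")
  if (!all(ok)) msg <- c(msg, "cells must be present/absent/unalignable")
  if (nrow(object@sites) && !all(object@sites$phase %in% 0:2))
    msg <- c(msg, "phase must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated ortholog family
#'
#' The complete record of one run of \code{\link{simulateGeneFamily}}: the
#' simulated genomic and CDS sequences, the true exon-intron structures, the
#' species tree, the intron-loss events drawn along its branches (site,
#' branch, mechanism) and the coordinates of repeats planted at
#' repeat-mediated breakpoints.
#'
#' @slot genomic a \link[Biostrings]{DNAStringSet} of genomic sequences.
#' @slot cds a \link[Biostrings]{DNAStringSet} of coding sequences.
#' @slot structures named list of \linkS4class{GeneStructure} objects.
#' @slot tree an \link[ape]{ape} \code{phylo} species tree (rooted).
#' @slot events data.frame of true losses: \code{site}, \code{branch}
#'   (child-node label), \code{mechanism}.
#' @slot repeats data.frame of planted breakpoint repeats.
#' @slot ancestralSites data.frame of ancestral intron sites (\code{coord},
#'   \code{phase}): the coordinate system in which \code{events$site} lives.
#' @slot config list, the configuration the family was simulated from.
#' @export
setClass("FamilyTruth",
  representation(
    genomic = "DNAStringSet",
    cds = "DNAStringSet",
    structures = "list",
    tree = "ANY",
    events = "data.frame",
    repeats = "data.frame",
    ancestralSites = "data.frame",
    config = "list"
  )
)

setValidity("FamilyTruth", function(object) {
  msg <- character()
  if (!all(names(object@structures) %in% names(object@cds)))
    msg <- c(msg, "every structure needs a CDS of the same name")
  for (nm in names(object@structures)) {
    gs <- object@structures[[nm]]
    if (gs@cdsLength != Biostrings::nchar(object@cds[[nm]]))
      msg <- c(msg, sprintf("cdsLength of %s does not match its CDS", nm))
  }
  if (length(msg)) msg else TRUE
})

# ---- generics ----------------------------------------------------------

#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @export
setGeneric("cdsLength", function(x) standardGeneric("cdsLength"))
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))
#' @export
setGeneric("presenceCells", function(x) standardGeneric("presenceCells"))
#' @export
setGeneric("trueEvents", function(x) standardGeneric("trueEvents"))
#' @export
setGeneric("trueStructures", function(x) standardGeneric("trueStructures"))

#' @describeIn GeneStructure gene identifier.
#' @param x a \code{GeneStructure}
#' @export
setMethod("geneId", "GeneStructure", function(x) x@geneId)

#' @describeIn GeneStructure exon intervals as an \code{IRanges}.
#' @export
setMethod("exonRanges", "GeneStructure", function(x) x@exons)

#' @describeIn GeneStructure CDS length in bp.
#' @export
setMethod("cdsLength", "GeneStructure", function(x) x@cdsLength)

#' @describeIn IntronSiteMatrix site coordinates and phases.
#' @param x an \code{IntronSiteMatrix}
#' @export
setMethod("siteTable", "IntronSiteMatrix", function(x) x@sites)

#' @describeIn IntronSiteMatrix presence/absence cell matrix.
#' @export
setMethod("presenceCells", "IntronSiteMatrix", function(x) x@cells)

#' @describeIn FamilyTruth data.frame of true loss events.
#' @param x a \code{FamilyTruth}
#' @export
setMethod("trueEvents", "FamilyTruth", function(x) x@events)

#' @describeIn FamilyTruth named list of true \code{GeneStructure} objects.
#' @export
setMethod("trueStructures", "FamilyTruth", function(x) x@structures)

setMethod("show", "GeneStructure", function(object) {
  n <- length(object@exons)
  cat("GeneStructure", object@geneId,
      if (!is.na(object@taxon)) sprintf("(%s)", object@taxon) else "",
      "\n  template:", object@genomicId, "strand:", object@strand,
      "\n  ", n, "exon(s),", n - 1L, "intron(s), CDS", object@cdsLength, "bp\n")
  ex <- object@exons
  cat("  exons:", paste(sprintf("%d-%d", start(ex), end(ex)), collapse = ", "), "\n")
})

setMethod("show", "IntronSiteMatrix", function(object) {
  cat("IntronSiteMatrix:", nrow(object@sites), "site(s) x",
      ncol(object@cells), "gene(s); reference:", object@reference, "\n")
  if (nrow(object@sites)) {
    m <- substr(object@cells, 1L, 1L)
    dim(m) <- dim(object@cells)
    dimnames(m) <- dimnames(object@cells)
    rownames(m) <- sprintf("site%d@%d.p%d", seq_len(nrow(object@sites)),
                           object@sites$coord, object@sites$phase)
    print(m, quote = FALSE)
  }
})

setMethod("show", "FamilyTruth", function(object) {
  cat("FamilyTruth:", length(object@structures), "gene(s) on",
      length(object@tree$tip.label), "taxa;",
      nrow(object@events), "true loss event(s)\n")
})

#' Construct a GeneStructure
#'
#' @param geneId gene identifier.
#' @param exons \link[IRanges]{IRanges} of exon intervals in 5'->3' coding
#'   order (1-based inclusive, forward-strand coordinates of the template).
#' @param cdsLength CDS length in bp; defaults to the summed exon widths.
#' @param taxon optional taxon label.
#' @param genomicId identifier of the genomic template.
#' @param strand \code{"+"} or \code{"-"}.
#' @return a \linkS4class{GeneStructure}.
#' @examples
#' GeneStructure("g1", IRanges::IRanges(start = c(1, 151), end = c(100, 250)))
#' @export
GeneStructure <- function(geneId, exons, cdsLength = sum(width(exons)),
                          taxon = NA_character_, genomicId = geneId,
                          strand = "+") {
  new("GeneStructure", geneId = as.character(geneId), taxon = as.character(taxon),
      genomicId = as.character(genomicId), strand = strand,
      exons = exons, cdsLength = as.integer(cdsLength))
}
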