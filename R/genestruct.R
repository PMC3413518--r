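#' Infer exon-intron structure by spliced alignment of a CDS
#'
#' Aligns a coding sequence onto its genomic template and returns the exon
#' chain. Exact k-mer seeds on the CDS are anchored on the template, merged
#' into colinear diagonal blocks and chained by dynamic programming to
#' maximize matched CDS coverage; each inter-block junction (one intron) is
#' then placed at the split point that maximizes the local match count, with
#' ties broken in favour of a canonical GT..AG intron, then GC..AG, then the
#' leftmost position. Both strands are tried and the better one kept.
#'
#' @param cds coding sequence (character or \code{DNAString}).
#' @param genomic genomic template (character or \code{DNAString}).
#' @param geneId,genomicId,taxon identifiers carried into the result.
#' @param k seed length in nt (default 15).
#' @param minCoverage minimum fraction of CDS positions matched by the
#'   spliced alignment (default 0.9); below it a structured
#'   \code{grasstruct_no_structure} error is raised.
#' @param junctionWindow half-width in nt of the window scanned around each
#'   candidate junction for the best splice placement (default 6).
#' @param bothStrands also try the reverse complement of the template
#'   (default TRUE).
#' @return a \linkS4class{GeneStructure}.
#' @seealso \code{\link{annotateIntrons}}, \code{\link{spliceGenomic}}
#' @export
splicedAlign <- function(cds, genomic, geneId = "gene", genomicId = "genomic",
                         taxon = NA_character_, k = 15L, minCoverage = 0.9,
                         junctionWindow = 6L, bothStrands = TRUE) {
  cds <- toupper(as.character(cds))
  genomic <- toupper(as.character(genomic))
  if (!nzchar(cds) || !nzchar(genomic))
    stop("cds and genomic must be non-empty", call. = FALSE)
  if (nchar(genomic) < nchar(cds))
    stop("genomic template shorter than the CDS", call. = FALSE)

  fwd <- splicedAlignOneStrand(cds, genomic, k, junctionWindow)
  res <- fwd
  strand <- "+"
  if (bothStrands) {
    rc <- as.character(reverseComplement(DNAString(genomic)))
    rev <- splicedAlignOneStrand(cds, rc, k, junctionWindow)
    if (!is.null(rev) && (is.null(fwd) || rev$matches > fwd$matches)) {
      res <- rev
      strand <- "-"
    }
  }
  L <- nchar(cds)
  if (is.null(res) || res$matches < minCoverage * L)
    stop(errorCondition(
      sprintf("no structure: only %.1f%% of the CDS is alignable",
              100 * (if (is.null(res)) 0 else res$matches / L)),
      class = c("grasstruct_no_structure", "error")))
  ex <- res$exons
  if (strand == "-") {
    n <- nchar(genomic)
    ex <- IRanges(start = n - end(ex) + 1L, end = n - start(ex) + 1L)
    # coding order on '-' = descending forward-strand start
    ex <- ex[order(-start(ex))]
  }
  GeneStructure(geneId, ex, cdsLength = L, taxon = taxon,
                genomicId = genomicId, strand = strand)
}

# spliced alignment against one strand; returns list(exons=IRanges in this
# strand's coordinates ordered 5'->3', matches=count) or NULL
splicedAlignOneStrand <- function(cds, gen, k, w) {
  L <- nchar(cds)
  n <- nchar(gen)
  if (L < k) return(NULL)
  cdsV <- strsplit(cds, "", fixed = TRUE)[[1]]
  genV <- strsplit(gen, "", fixed = TRUE)[[1]]

  gk <- substring(gen, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  gmap <- split(seq_len(n - k + 1L), gk)
  ck <- substring(cds, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  hit <- ck %in% names(gmap)
  if (!any(hit)) return(NULL)
  ci <- which(hit)
  gi <- gmap[ck[ci]]
  nper <- lengths(gi)
  ci <- rep.int(ci, nper)
  gi <- unlist(gi, use.names = FALSE)
  diag <- gi - ci

  # merge consecutive seeds on one diagonal into blocks
  o <- order(diag, ci)
  ci <- ci[o]; diag <- diag[o]
  newblock <- c(TRUE, diff(diag) != 0L | diff(ci) != 1L)
  bid <- cumsum(newblock)
  bStart <- tapply(ci, bid, min)
  bEnd <- tapply(ci, bid, max) + k - 1L
  bDiag <- diag[newblock]
  blocks <- data.frame(cs = as.integer(bStart), ce = as.integer(bEnd),
                       d = as.integer(bDiag))
  # bridge small seed gaps caused by isolated mismatches: merge blocks on
  # one diagonal when separated by <= 50 nt
  blocks <- blocks[order(blocks$d, blocks$cs), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (length(merged)) {
      last <- merged[[length(merged)]]
      if (last$d == b$d && b$cs - last$ce - 1L <= 50L) {
        last$ce <- max(last$ce, b$ce)
        merged[[length(merged)]] <- last
        next
      }
    }
    merged[[length(merged) + 1L]] <- b
  }
  blocks <- do.call(rbind, merged)
  blocks <- blocks[order(blocks$cs, blocks$ce), , drop = FALSE]

  # chain blocks: non-decreasing diagonal (introns only widen the template),
  # maximizing covered CDS length
  nb <- nrow(blocks)
  if (nb > 400L) { # keep DP quadratic cost bounded; keep longest blocks
    keep <- order(blocks$ce - blocks$cs, decreasing = TRUE)[seq_len(400L)]
    blocks <- blocks[sort(keep), , drop = FALSE]
    nb <- nrow(blocks)
  }
  score <- numeric(nb)
  prev <- integer(nb)
  for (i in seq_len(nb)) {
    best <- 0; bj <- 0L
    for (j in seq_len(i - 1L)) {
      if (blocks$d[j] > blocks$d[i]) next
      if (blocks$d[j] == blocks$d[i]) next   # same-diagonal blocks merge below
      if (blocks$ce[j] >= blocks$ce[i]) next
      gap <- blocks$cs[i] - blocks$ce[j] - 1L
      if (gap < -k) next
      if (score[j] > best) { best <- score[j]; bj <- j }
    }
    score[i] <- best + (blocks$ce[i] - blocks$cs[i] + 1L)
    prev[i] <- bj
  }
  i <- which.max(score)
  path <- integer()
  while (i > 0L) { path <- c(i, path); i <- prev[i] }
  ch <- blocks[path, , drop = FALSE]

  # junction placement between consecutive diagonals
  bounds <- integer(0)           # CDS position ending each exon
  diags <- ch$d[1L]
  if (nrow(ch) > 1L) {
    for (i in seq_len(nrow(ch) - 1L)) {
      dA <- ch$d[i]; dB <- ch$d[i + 1L]
      lo <- min(ch$ce[i], ch$cs[i + 1L] - 1L) - w
      hi <- max(ch$ce[i], ch$cs[i + 1L] - 1L) + w
      lo <- max(lo, if (length(bounds)) bounds[length(bounds)] + 1L else 1L, 1L - dA)
      hi <- min(hi, L - 1L)
      if (lo > hi) { lo <- hi <- min(max(ch$ce[i], 1L), L - 1L) }
      cand <- lo:hi
      scoreAt <- function(c) {
        a <- if (c >= lo) sum(cdsV[lo:c] == genV[pmin(pmax(lo:c + dA, 1L), n)]) else 0
        b <- if (c < hi) sum(cdsV[(c + 1L):hi] == genV[pmin(pmax((c + 1L):hi + dB, 1L), n)]) else 0
        a + b
      }
      sc <- vapply(cand, scoreAt, numeric(1))
      top <- cand[sc == max(sc)]
      pick <- top[[1L]]
      pref <- 0L
      for (c in top) {
        don <- paste0(genV[pmin(c + dA + 1L, n)], genV[pmin(c + dA + 2L, n)])
        acc <- paste0(genV[pmax(c + dB - 1L, 1L)], genV[pmax(c + dB, 1L)])
        p <- if (don == "GT" && acc == "AG") 2L
             else if (don == "GC" && acc == "AG") 1L else 0L
        if (p > pref) { pref <- p; pick <- c }
      }
      bounds <- c(bounds, pick)
      diags <- c(diags, dB)
    }
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, L)
  gs <- starts + diags
  ge <- ends + diags
  if (any(gs < 1L) || any(ge > n) || any(ge < gs)) return(NULL)
  exons <- IRanges(start = gs, end = ge)
  # matched CDS positions under the final exon chain
  m <- 0L
  for (i in seq_along(starts))
    m <- m + sum(cdsV[starts[i]:ends[i]] == genV[gs[i]:ge[i]])
  list(exons = exons, matches = m)
}

#' Splice a genomic sequence at a gene structure's exons
#'
#' @param genomic genomic template (character or \code{DNAString}).
#' @param structure a \linkS4class{GeneStructure}.
#' @return a \code{DNAString}: the spliced (coding-strand) transcript.
#' @export
spliceGenomic <- function(genomic, structure) {
  genomic <- DNAString(toupper(as.character(genomic)))
  ex <- structure@exons
  pieces <- lapply(seq_along(ex), function(i) {
    s <- Biostrings::subseq(genomic, start(ex)[i], end(ex)[i])
    if (structure@strand == "-") reverseComplement(s) else s
  })
  out <- pieces[[1L]]
  for (p in pieces[-1L]) out <- Biostrings::xscat(out, p)
  DNAString(as.character(out))
}

#' Annotate the introns of a gene structure
#'
#' One record per inter-exon gap, numbered from the 5' end of the gene.
#' Phase is the number of coding bases upstream of the intron modulo 3.
#' Donor and acceptor dinucleotides are read off the coding strand; GT..AG
#' introns are canonical, GC..AG are flagged as the non-canonical GC class.
#'
#' @param structure a \linkS4class{GeneStructure}.
#' @param genomic the genomic template the structure lives on.
#' @return data.frame with columns \code{index}, \code{start}, \code{end}
#'   (forward-strand template coordinates), \code{length}, \code{donor},
#'   \code{acceptor}, \code{phase}, \code{canonical}, \code{class}.
#' @export
annotateIntrons <- function(structure, genomic) {
  genomic <- toupper(as.character(genomic))
  ex <- structure@exons
  nI <- length(ex) - 1L
  if (nI == 0L)
    return(data.frame(index = integer(), start = integer(), end = integer(),
                      length = integer(), donor = character(),
                      acceptor = character(), phase = integer(),
                      canonical = logical(), class = character(),
                      stringsAsFactors = FALSE))
  rows <- vector("list", nI)
  cum <- 0L
  for (i in seq_len(nI)) {
    cum <- cum + width(ex)[i]
    if (structure@strand == "+") {
      s <- end(ex)[i] + 1L; e <- start(ex)[i + 1L] - 1L
    } else {
      s <- end(ex)[i + 1L] + 1L; e <- start(ex)[i] - 1L
    }
    if (e < s)
      stop("adjacent exons ", i, " and ", i + 1L,
           " have zero gap; they should have been merged", call. = FALSE)
    intron <- substr(genomic, s, e)
    if (structure@strand == "-")
      intron <- as.character(reverseComplement(DNAString(intron)))
    donor <- substr(intron, 1L, 2L)
    acceptor <- substr(intron, nchar(intron) - 1L, nchar(intron))
    cls <- if (donor == "GT" && acceptor == "AG") "canonical"
           else if (donor == "GC" && acceptor == "AG") "non-canonical-GC"
           else "non-canonical"
    rows[[i]] <- data.frame(
      index = i, start = s, end = e, length = e - s + 1L,
      donor = donor, acceptor = acceptor, phase = cum %% 3L,
      canonical = cls == "canonical", class = cls, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' In-silico PCR
#'
#' Finds all products a primer pair could amplify from a template. A primer
#' site must match with at most \code{maxMismatches} mismatches and its
#' 3'-terminal base must match exactly. Both template orientations are
#' searched, and products are reported smallest first. Product lengths are
#' primer-inclusive.
#'
#' @param forward,reverse primer sequences, 5'->3' (character).
#' @param template template sequence.
#' @param maxMismatches per-primer mismatch allowance (default 0).
#' @param maxProduct longest product reported in bp (default 10000).
#' @param minPrimer minimum primer length in nt (default 15).
#' @param templateId identifier carried into the result.
#' @return data.frame with columns \code{template_id}, \code{forward_start},
#'   \code{reverse_end} (forward-strand template coordinates of the product),
#'   \code{product_length}, \code{mismatches_forward},
#'   \code{mismatches_reverse}, \code{orientation}; zero rows when there is
#'   no product.
#' @export
insilicoPcr <- function(forward, reverse, template, maxMismatches = 0L,
                        maxProduct = 10000L, minPrimer = 15L,
                        templateId = "template") {
  forward <- toupper(as.character(forward))
  reverse <- toupper(as.character(reverse))
  template <- toupper(as.character(template))
  if (nchar(forward) < minPrimer || nchar(reverse) < minPrimer)
    stop("primers must be at least ", minPrimer, " nt", call. = FALSE)

  one <- function(fwd, rev, orientation) {
    fSites <- primerSites(fwd, template, maxMismatches, end3 = "right")
    rcRev <- as.character(reverseComplement(DNAString(rev)))
    rSites <- primerSites(rcRev, template, maxMismatches, end3 = "left")
    out <- list()
    for (i in seq_len(nrow(fSites))) for (j in seq_len(nrow(rSites))) {
      if (rSites$start[j] <= fSites$end[i]) next
      len <- rSites$end[j] - fSites$start[i] + 1L
      if (len > maxProduct) next
      out[[length(out) + 1L]] <- data.frame(
        template_id = templateId,
        forward_start = fSites$start[i], reverse_end = rSites$end[j],
        product_length = len,
        mismatches_forward = fSites$mm[i], mismatches_reverse = rSites$mm[j],
        orientation = orientation, stringsAsFactors = FALSE)
    }
    out
  }
  rows <- c(one(forward, reverse, "forward"), one(reverse, forward, "reverse"))
  if (!length(rows))
    return(data.frame(template_id = character(), forward_start = integer(),
                      reverse_end = integer(), product_length = integer(),
                      mismatches_forward = integer(),
                      mismatches_reverse = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$product_length, out$forward_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all sites where `pat` matches `subject` with <= maxMismatches mismatches
# and an exact match at the primer's 3' base (template side given by end3)
primerSites <- function(pat, subject, maxMismatches, end3) {
  m <- Biostrings::matchPattern(pat, DNAString(subject),
                                max.mismatch = maxMismatches,
                                with.indels = FALSE)
  if (length(m) == 0L)
    return(data.frame(start = integer(), end = integer(), mm = integer()))
  patV <- strsplit(pat, "", fixed = TRUE)[[1]]
  rows <- lapply(seq_along(m), function(i) {
    s <- start(m)[i]; e <- end(m)[i]
    hitV <- strsplit(as.character(m[[i]]), "", fixed = TRUE)[[1]]
    mm <- sum(patV != hitV)
    ok <- if (end3 == "right") patV[length(patV)] == hitV[length(hitV)]
          else patV[1L] == hitV[1L]
    if (!ok) return(NULL)
    data.frame(start = s, end = e, mm = mm)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), mm = integer()))
  do.call(rbind, rows)
}
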