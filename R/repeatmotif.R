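revcompChr <- function(x)
  as.character(reverseComplement(DNAString(x)))

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Scan an exon-fusion junction for breakpoint repeats
#'
#' After an intron loss the fused exon carries the former splice junction;
#' short direct or inverted repeats with one arm on each side of that
#' junction are the sequence signature of repeat-mediated deletion
#' (replication slippage / illegitimate recombination). All arm pairs with
#' one arm ending at or before the junction and the other starting after
#' it, both arms within \code{window} nt of the junction and at least
#' \code{minArm} nt long, are reported, sorted by arm length (desc) then
#' total distance to the junction (asc).
#'
#' @param seq the fused-exon (or any) sequence.
#' @param junction coordinate of the last base before the junction
#'   (the junction lies between \code{junction} and \code{junction + 1}).
#' @param window nt scanned on each side of the junction (default 15).
#' @param minArm minimum arm length in nt (default 3).
#' @return data.frame with \code{kind} (direct/inverted),
#'   \code{arm1_start}, \code{arm1_end}, \code{arm2_start}, \code{arm2_end},
#'   \code{arm1}, \code{arm2}, \code{arm_len}, \code{spacer},
#'   \code{distance}; zero rows when nothing is found.
#' @export
scanBreakpointRepeats <- function(seq, junction, window = 15L, minArm = 3L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (junction < 1L || junction >= n)
    stop("junction must lie strictly inside the sequence", call. = FALSE)
  if (window < minArm) stop("window must be >= minArm", call. = FALSE)
  lLo <- max(1L, junction - window + 1L)
  rHi <- min(n, junction + window)
  rows <- list()
  for (a in minArm:window) {
    for (i in lLo:(junction - a + 1L)) {
      if (i < lLo || i + a - 1L > junction) next
      arm1 <- substr(seq, i, i + a - 1L)
      for (j in (junction + 1L):(rHi - a + 1L)) {
        if (j <= junction || j + a - 1L > rHi) next
        arm2 <- substr(seq, j, j + a - 1L)
        kind <- if (arm1 == arm2) "direct"
                else if (arm2 == revcompChr(arm1)) "inverted"
                else next
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, arm1_start = i, arm1_end = i + a - 1L,
          arm2_start = j, arm2_end = j + a - 1L,
          arm1 = arm1, arm2 = arm2, arm_len = a,
          spacer = j - (i + a - 1L) - 1L,
          distance = (junction - (i + a - 1L)) + (j - junction - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(kind = character(), arm1_start = integer(),
                      arm1_end = integer(), arm2_start = integer(),
                      arm2_end = integer(), arm1 = character(),
                      arm2 = character(), arm_len = integer(),
                      spacer = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$arm_len, out$distance, out$arm1_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the mechanism behind an intron-loss event
#'
#' A pure function of the event's multiplicity and the repeat evidence at
#' its breakpoint: a run of two or more adjacent introns lost on one branch
#' points to recombination with a reverse-transcribed spliced mRNA
#' (\code{mrna_mediated}); a single loss with a junction-spanning repeat
#' points to \code{repeat_mediated} deletion (replication slippage /
#' illegitimate recombination); a single loss with no repeat is a
#' \code{simple_deletion}; conflicting evidence (a multi-intron run that
#' also shows a junction repeat) is \code{indeterminate}.
#'
#' @param event one loss event: either a one-row data.frame with a
#'   \code{multiplicity} column (as returned by
#'   \code{\link{inferLossEvents}}) or the multiplicity itself.
#' @param repeats data.frame of junction-spanning repeats from
#'   \code{\link{scanBreakpointRepeats}} (possibly zero rows).
#' @return character(1) mechanism label.
#' @export
classifyLossMechanism <- function(event, repeats = NULL) {
  mult <- if (is.data.frame(event)) event$multiplicity[[1L]] else event
  hasRepeat <- !is.null(repeats) && nrow(repeats) > 0L
  if (mult >= 2L && hasRepeat) "indeterminate"
  else if (mult >= 2L) "mrna_mediated"
  else if (hasRepeat) "repeat_mediated"
  else "simple_deletion"
}

#' Find MITE-like elements bounded by terminal inverted repeats
#'
#' Scans a sequence for spans of at most \code{maxLen} nt bounded by
#' terminal inverted repeats (TIRs) of at least \code{minTir} nt with at
#' most \code{maxMismatch} mismatches between the arms. Arms are extended
#' inward... outward greedily while the mismatch budget allows, and
#' overlapping candidates are merged keeping the longest TIR. The
#' orientation flag is a canonical-form convention: \code{"+"} when the
#' element's interior is lexicographically no greater than its reverse
#' complement, so two copies of one element inserted in opposite
#' orientations receive opposite flags.
#'
#' @param seq sequence to scan.
#' @param minTir minimum TIR arm length in nt (default 10).
#' @param maxLen maximum element length in nt (default 800).
#' @param maxMismatch mismatches allowed between the two arms (default 1).
#' @return data.frame with \code{start}, \code{end}, \code{length},
#'   \code{tir_len}, \code{mismatches}, \code{orientation}, \code{tir}.
#' @export
findTirElements <- function(seq, minTir = 10L, maxLen = 800L,
                            maxMismatch = 1L) {
  seq <- toupper(as.character(seq))
  if (minTir <= 0L || maxLen <= 0L) stop("parameters must be positive",
                                         call. = FALSE)
  n <- nchar(seq)
  if (n < 2L * minTir) return(emptyTirFrame())
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  cv <- unname(COMP[v]); cv[is.na(cv)] <- "N"
  cand <- list()
  # vectorized over left-arm start i for each element length Dlen
  for (Dlen in (2L * minTir):min(maxLen, n)) {
    iMax <- n - Dlen + 1L
    if (iMax < 1L) break
    idx <- seq_len(iMax)
    mism <- integer(iMax)
    for (t in 0:(minTir - 1L)) {
      # left arm base i+t vs complement of right arm base (i+Dlen-1-t)
      mism <- mism + (v[idx + t] != cv[idx + Dlen - 1L - t])
    }
    hit <- which(mism <= maxMismatch)
    for (i in hit)
      cand[[length(cand) + 1L]] <- c(i, i + Dlen - 1L, mism[i])
  }
  if (!length(cand)) return(emptyTirFrame())
  cand <- do.call(rbind, cand)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]; mm <- cand[r, 3L]
    a <- minTir
    while (i + a <= j - a && mm + (v[i + a] != cv[j - a]) <= maxMismatch) {
      mm <- mm + (v[i + a] != cv[j - a])
      a <- a + 1L
    }
    interior <- substr(seq, i + a, j - a)
    ori <- if (interior <= revcompChr(interior)) "+" else "-"
    rows[[length(rows) + 1L]] <- data.frame(
      start = i, end = j, length = j - i + 1L, tir_len = a,
      mismatches = mm, orientation = ori,
      tir = substr(seq, i, i + a - 1L), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # merge overlapping candidates keeping the longest TIR
  out <- out[order(-out$tir_len, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (r in seq_len(nrow(out))) {
    if (!keep[r]) next
    ov <- keep & out$start <= out$end[r] & out$end >= out$start[r]
    ov[r] <- FALSE
    keep[ov] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyTirFrame <- function()
  data.frame(start = integer(), end = integer(), length = integer(),
             tir_len = integer(), mismatches = integer(),
             orientation = character(), tir = character(),
             stringsAsFactors = FALSE)

#' Find duplicated copies of an exon downstream of the stop codon
#'
#' Locally aligns an exon (in both orientations) against the genomic
#' region downstream of the stop codon. Copies with identity at or above
#' \code{minIdentity} are reported with their offset, measured from the
#' base after the stop codon to the first aligned base of the copy
#' (1-based distance). Internal deletions in the copy are read off the
#' alignment's gap runs, and each deletion is checked for the signature of
#' illegitimate recombination: an identical k-mer (k from 8 down to 4)
#' abutting the deleted source segment on both sides.
#'
#' @param genomic genomic sequence.
#' @param exon exon (or any source segment, >= 30 nt) to search for.
#' @param stopCodonPos coordinate of the last base of the stop codon on
#'   \code{genomic}.
#' @param minIdentity minimum identity fraction of a copy (default 0.8).
#' @param minCoverage minimum fraction of the query the local alignment
#'   must span (default 0.5); filters chance micro-matches.
#' @return data.frame with \code{orientation}, \code{copy_start},
#'   \code{copy_end} (genomic coordinates), \code{offset},
#'   \code{identity}, \code{n_deletions}, and a \code{deletions}
#'   list-column of per-deletion data.frames (\code{source_start},
#'   \code{length}, \code{flank_motif}).
#' @export
findExonDuplication <- function(genomic, exon, stopCodonPos,
                                minIdentity = 0.8, minCoverage = 0.5) {
  genomic <- toupper(as.character(genomic))
  exon <- toupper(as.character(exon))
  if (nchar(exon) < 30L) stop("exon must be at least 30 nt", call. = FALSE)
  n <- nchar(genomic)
  if (stopCodonPos >= n) return(emptyDupFrame())
  region <- substr(genomic, stopCodonPos + 1L, n)
  rows <- list()
  for (ori in c("+", "-")) {
    pat <- if (ori == "+") exon else revcompChr(exon)
    # expensive gap opening (chance micro-blocks cannot chain through
    # gaps) but cheap extension, so one long internal deletion is
    # bridged rather than truncating the local alignment
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(pat), Biostrings::DNAString(region),
      type = "local", substitutionMatrix = sm,
      gapOpening = 25, gapExtension = 0.1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    if (!length(ap)) next
    both <- ap != "-" & as_ != "-"
    ident <- sum(ap == as_ & both) / sum(both)   # over aligned columns
    if (ident < minIdentity) next
    if (sum(ap != "-") < minCoverage * nchar(pat)) next
    subStart <- Biostrings::start(Biostrings::subject(pa))
    subEnd <- Biostrings::end(Biostrings::subject(pa))
    patStart <- Biostrings::start(Biostrings::pattern(pa))
    # gap runs in the subject = source segments missing from the copy
    patPos <- cumsum(ap != "-") + patStart - 1L
    gaps <- rle(as_ == "-")
    dels <- list()
    at <- 0L
    for (gi in seq_along(gaps$lengths)) {
      len <- gaps$lengths[gi]
      if (gaps$values[gi] && at > 0L && at + len < length(as_)) {
        ds <- patPos[at + 1L]          # first deleted source base
        de <- patPos[at + len]         # last deleted source base
        # orientation back to source coordinates of `exon`
        if (ori == "-") { tmp <- ds; ds <- nchar(exon) - de + 1L
                          de <- nchar(exon) - tmp + 1L }
        motif <- deletionFlankMotif(pat, ds0 = patPos[at + 1L],
                                    de0 = patPos[at + len])
        if (!is.na(motif) && ori == "-") motif <- revcompChr(motif)
        dels[[length(dels) + 1L]] <- data.frame(
          source_start = ds, length = len, flank_motif = motif,
          stringsAsFactors = FALSE)
      }
      at <- at + len
    }
    delDf <- if (length(dels)) do.call(rbind, dels)
             else data.frame(source_start = integer(), length = integer(),
                             flank_motif = character(), stringsAsFactors = FALSE)
    rec <- data.frame(
      orientation = ori,
      copy_start = stopCodonPos + subStart,
      copy_end = stopCodonPos + subEnd,
      offset = subStart, identity = ident,
      n_deletions = nrow(delDf), stringsAsFactors = FALSE)
    rec$deletions <- I(list(delDf))
    rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows)) return(emptyDupFrame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# identical k-mer (longest k in 8..4) immediately before the deleted
# segment and at its end. A deletion between direct repeats has
# equivalent gap placements (the gap can slide within the repeat), so all
# sequence-equivalent placements are scanned.
deletionFlankMotif <- function(pat, ds0, de0) {
  n <- nchar(pat)
  v <- strsplit(pat, "", fixed = TRUE)[[1]]
  dmin <- 0L
  while (ds0 + dmin - 1L >= 1L && de0 + dmin <= n &&
         v[ds0 + dmin - 1L] == v[de0 + dmin]) dmin <- dmin - 1L
  dmax <- 0L
  while (de0 + dmax + 1L <= n && ds0 + dmax <= n &&
         v[ds0 + dmax] == v[de0 + dmax + 1L]) dmax <- dmax + 1L
  for (k in 8:4) for (d in dmin:dmax) {
    ds <- ds0 + d; de <- de0 + d
    if (ds - k < 1L || de > n) next
    left <- substr(pat, ds - k, ds - 1L)
    right <- substr(pat, de - k + 1L, de)
    if (left == right) return(left)
  }
  NA_character_
}

emptyDupFrame <- function() {
  d <- data.frame(orientation = character(), copy_start = integer(),
                  copy_end = integer(), offset = integer(),
                  identity = numeric(), n_deletions = integer(),
                  stringsAsFactors = FALSE)
  d$deletions <- I(list())
  d
}

#' Default table of ABA-related promoter cis-elements
#'
#' Consensus strings follow the standard ABA-response literature: the ABRE
#' ACGT core element, its palindromic G-box variant and the coupling
#' elements CE1 and CE3 required for ABRE function.
#'
#' @return data.frame with columns \code{name} and \code{consensus} (IUPAC).
#' @export
defaultMotifTable <- function() {
  data.frame(
    name = c("ABRE", "G-box", "CE1", "CE3"),
    consensus = c("ACGTG", "CACGTG", "TGCCACCGG", "ACGCGTGTC"),
    stringsAsFactors = FALSE)
}

#' Scan a promoter for cis-regulatory elements
#'
#' Both strands are scanned for each IUPAC consensus in the motif table.
#' Hit positions are reported both in sequence coordinates and relative to
#' the sequence's 3' end, the convention for promoters supplied as the
#' region immediately upstream of the ATG (a relative start of -6 means
#' the hit begins 6 bp upstream of the start codon).
#'
#' @param promoter promoter sequence (typically ~2 kb upstream of the ATG).
#' @param motifTable data.frame with columns \code{name} and
#'   \code{consensus}; defaults to \code{\link{defaultMotifTable}}.
#' @return data.frame with \code{motif}, \code{consensus}, \code{start},
#'   \code{end}, \code{strand}, \code{matched}, \code{rel_start}.
#' @export
scanCisElements <- function(promoter, motifTable = defaultMotifTable()) {
  promoter <- toupper(as.character(promoter))
  if (!nzchar(promoter)) stop("promoter must be non-empty", call. = FALSE)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  for (cons in motifTable$consensus) {
    bad <- setdiff(strsplit(cons, "", fixed = TRUE)[[1]], iupac)
    if (length(bad))
      stop("unknown IUPAC code '", bad[[1]], "' in motif table", call. = FALSE)
  }
  subj <- DNAString(promoter)
  n <- nchar(promoter)
  rows <- list()
  for (r in seq_len(nrow(motifTable))) {
    pat <- DNAString(motifTable$consensus[r])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subj, fixed = FALSE)
      for (i in seq_along(m)) {
        s <- start(m)[i]; e <- end(m)[i]
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motifTable$name[r], consensus = motifTable$consensus[r],
          start = s, end = e, strand = strand,
          matched = as.character(m[[i]]),
          rel_start = s - (n + 1L), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), consensus = character(),
                      start = integer(), end = integer(),
                      strand = character(), matched = character(),
                      rel_start = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
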