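#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString reverseComplement
#' @importFrom GenomicRanges GRanges
#' @importFrom ape read.tree write.tree
#' @importFrom utils read.delim write.table
NULL

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings with the package's conventions: sequences
#' are returned as a \code{DNAStringSet}; files are written wrapped at 60
#' columns. \code{readFastaFile} raises an error naming the offending line
#' when the file does not start with a \code{>} header.
#'
#' @param path file path.
#' @param x a \code{DNAStringSet} (or named character vector) to write.
#' @return \code{readFastaFile}: a \code{DNAStringSet}.
#' @export
readFastaFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first) || !startsWith(lines[[first]], ">"))
    stop("malformed FASTA at line ", if (is.na(first)) 1L else first,
         ": expected '>' header", call. = FALSE)
  readDNAStringSet(path)
}

#' @rdname readFastaFile
#' @export
writeFastaFile <- function(x, path) {
  if (!methods::is(x, "XStringSet")) x <- DNAStringSet(x)
  writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read / write gene structures as GFF3
#'
#' Gene structures are serialized as \code{gene}/\code{exon}/\code{intron}
#' features (1-based inclusive coordinates, per the GFF3 standard) via
#' rtracklayer. Reading validates coordinates and raises an error naming the
#' offending line when a feature has \code{start > end}.
#'
#' @param structures named list of \linkS4class{GeneStructure} objects.
#' @param path file path.
#' @return \code{readStructuresGff3}: a named list of
#'   \linkS4class{GeneStructure} objects.
#' @export
writeStructuresGff3 <- function(structures, path) {
  rows <- lapply(structures, function(gs) {
    ex <- gs@exons
    ord <- order(start(ex))
    s <- start(ex)[ord]; e <- end(ex)[ord]
    data.frame(
      seqnames = gs@genomicId,
      start = c(min(s), s), end = c(max(e), e),
      strand = gs@strand,
      type = c("gene", rep("exon", length(ex))),
      ID = c(gs@geneId, paste0(gs@geneId, ".exon", seq_along(ex))),
      Parent = c(NA_character_, rep(gs@geneId, length(ex))),
      taxon = gs@taxon, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  gr <- GRanges(seqnames = d$seqnames,
                ranges = IRanges(start = d$start, end = d$end),
                strand = d$strand)
  gr$type <- d$type; gr$ID <- d$ID; gr$Parent <- d$Parent; gr$taxon <- d$taxon
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname writeStructuresGff3
#' @export
readStructuresGff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
      if (!is.na(s) && !is.na(e) && s > e)
        stop("malformed GFF3 at line ", i, ": start > end", call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  out <- lapply(seq_along(genes), function(i) {
    gid <- genes$ID[[i]]
    ex <- gr[gr$type == "exon" & vapply(gr$Parent, function(p)
      length(p) > 0 && p[[1]] == gid, logical(1))]
    strand <- as.character(GenomicRanges::strand(genes[i]))
    if (!strand %in% c("+", "-")) strand <- "+"
    r <- IRanges(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex))
    r <- if (strand == "+") r[order(start(r))] else r[order(-start(r))]
    GeneStructure(gid, r,
                  taxon = if (!is.null(genes$taxon)) genes$taxon[[i]] else NA_character_,
                  genomicId = as.character(GenomicRanges::seqnames(genes[i])),
                  strand = strand)
  })
  names(out) <- genes$ID
  out
}

#' Read a rooted species tree in Newick format
#'
#' @param path file path, or a Newick string.
#' @param text Newick text (alternative to \code{path}).
#' @return an \code{ape} \code{phylo} object; an error is raised when the
#'   tree is unrooted.
#' @export
readSpeciesTree <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) read.tree(text = text) else read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  if (!ape::is.rooted(tr)) stop("species tree must be rooted", call. = FALSE)
  tr
}

#' Read / write tab-delimited tables with a header row
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return \code{readTsv}: a data.frame.
#' @export
readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname readTsv
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BLAST outfmt-6-style HSP table
#'
#' Accepts the 12-column tabular dialect (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore), with or
#' without a header row, plus an optional 13th column of exact identity
#' counts. When identity counts are absent they are derived as
#' percent-identity times aligned length, rounded half up.
#'
#' @param path file path.
#' @return a data.frame of HSP records with columns \code{query_id},
#'   \code{subject_id}, \code{query_start}, \code{query_end},
#'   \code{subject_start}, \code{subject_end}, \code{aligned_length},
#'   \code{identity_count}, \code{e_value}, \code{strand}.
#' @export
readHspTable <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  probe <- read.delim(path, sep = "\t", header = FALSE, nrows = 1,
                      stringsAsFactors = FALSE)
  has_header <- is.character(probe[[3]]) || identical(probe[[1]], "qseqid")
  d <- read.delim(path, sep = "\t", header = has_header,
                  stringsAsFactors = FALSE, check.names = FALSE)
  if (!has_header) names(d)[seq_len(min(ncol(d), 13L))] <-
      c(cols, "nident")[seq_len(min(ncol(d), 13L))]
  need <- c("qseqid", "sseqid", "pident", "length", "qstart", "qend",
            "sstart", "send", "evalue")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("HSP table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nident <- if ("nident" %in% names(d)) as.integer(d$nident)
            else roundHalfUp(d$pident / 100 * d$length)
  data.frame(
    query_id = d$qseqid, subject_id = d$sseqid,
    query_start = as.integer(d$qstart), query_end = as.integer(d$qend),
    subject_start = as.integer(d$sstart), subject_end = as.integer(d$send),
    aligned_length = as.integer(d$length), identity_count = nident,
    e_value = as.numeric(d$evalue),
    strand = ifelse(d$sstart <= d$send, "+", "-"),
    stringsAsFactors = FALSE
  )
}

# round half away from zero, the convention used when rescaling identity
# counts (base round() rounds half to even)
roundHalfUp <- function(x) trunc(x + 0.5 * sign(x))
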