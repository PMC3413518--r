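#' Rebuild a pairwise alignment from tabular HSPs
#'
#' BLAST reports a local alignment between two sequences as a set of HSPs
#' that may overlap on the query. For cumulative pairwise statistics each
#' query position must be counted once, so overlapping HSPs are resolved
#' before summation: records are sorted by query start and, wherever two
#' HSPs overlap on the query, the one with the lower identity fraction
#' (identity count over aligned length) is trimmed back by the overlap;
#' its aligned length and identity count are rescaled proportionally to the
#' retained query span, rounded half up. On a tie the later-starting HSP is
#' trimmed. The returned records are disjoint on query coordinates. Subject
#' coordinates are carried through unchanged (they do not enter the
#' statistics).
#'
#' @param hsps data.frame of HSP records for one query-subject pair, as
#'   returned by \code{\link{readHspTable}}.
#' @param overlapPolicy \code{"trim"} (default, each query position counted
#'   once) or \code{"raw"} (sum HSPs as reported, overlaps double-counted).
#' @return a data.frame of HSP records, sorted by \code{query_start} and
#'   disjoint on the query when \code{overlapPolicy = "trim"}.
#' @seealso \code{\link{scorePair}}
#' @export
rebuildPairAlignment <- function(hsps, overlapPolicy = c("trim", "raw")) {
  overlapPolicy <- match.arg(overlapPolicy)
  if (is.null(hsps) || nrow(hsps) == 0L)
    stop("no HSPs supplied for this pair", call. = FALSE)
  if (length(unique(hsps$query_id)) != 1L ||
      length(unique(hsps$subject_id)) != 1L)
    stop("all HSPs must share one query_id and one subject_id", call. = FALSE)
  hsps <- hsps[order(hsps$query_start, hsps$query_end), , drop = FALSE]
  if (overlapPolicy == "raw") {
    rownames(hsps) <- NULL
    return(hsps)
  }
  chain <- hsps
  repeat {
    chain <- chain[order(chain$query_start, chain$query_end), , drop = FALSE]
    n <- nrow(chain)
    if (n < 2L) break
    ovAt <- which(chain$query_start[-1L] <= chain$query_end[-n])
    if (!length(ovAt)) break
    i <- ovAt[[1L]]                       # leftmost overlapping pair
    a <- chain[i, , drop = FALSE]
    b <- chain[i + 1L, , drop = FALSE]
    fA <- a$identity_count / a$aligned_length
    fB <- b$identity_count / b$aligned_length
    if (fB <= fA)
      b <- trimHspQuery(b, newStart = a$query_end + 1L)
    else
      a <- trimHspQuery(a, newEnd = b$query_start - 1L)
    chain <- rbind(chain[seq_len(n) < i, , drop = FALSE], a, b,
                   chain[seq_len(n) > i + 1L, , drop = FALSE])
  }
  rownames(chain) <- NULL
  chain
}

# trim an HSP on the query; identity and aligned length rescale with the
# retained span, rounded half up; a zero-length remainder drops out
trimHspQuery <- function(h, newStart = h$query_start, newEnd = h$query_end) {
  orig <- h$query_end - h$query_start + 1L
  kept <- newEnd - newStart + 1L
  if (kept <= 0L) return(h[0L, , drop = FALSE])
  h$identity_count <- as.integer(roundHalfUp(h$identity_count * kept / orig))
  h$aligned_length <- as.integer(roundHalfUp(h$aligned_length * kept / orig))
  h$query_start <- as.integer(newStart)
  h$query_end <- as.integer(newEnd)
  h
}

#' Cumulative pairwise statistics AL, CIP and CALP
#'
#' Given the disjoint HSP chain of one query-subject pair, computes the
#' aligned length \eqn{AL = \sum_i len_i} (sum of HSP lengths), the
#' cumulative identity percentage \eqn{CIP = 100 \sum_i id_i / AL} and the
#' cumulative alignment length percentage \eqn{CALP = AL / L_q} with
#' \eqn{L_q} the query length. Together they select the homolog with the
#' highest cumulative identity over the longest cumulative length.
#'
#' @param chain data.frame of disjoint HSPs from
#'   \code{\link{rebuildPairAlignment}}.
#' @param queryLength query sequence length in bp.
#' @return one-row data.frame: \code{query_id}, \code{subject_id},
#'   \code{AL}, \code{CIP}, \code{CALP}, \code{n_hsps_used}.
#' @export
scorePair <- function(chain, queryLength) {
  if (is.null(chain) || nrow(chain) == 0L)
    stop("empty HSP chain", call. = FALSE)
  if (!is.numeric(queryLength) || queryLength <= 0)
    stop("queryLength must be positive", call. = FALSE)
  if (max(chain$query_end) > queryLength)
    stop("queryLength smaller than the largest query_end", call. = FALSE)
  al <- sum(chain$aligned_length)
  data.frame(
    query_id = chain$query_id[[1L]], subject_id = chain$subject_id[[1L]],
    AL = al,
    CIP = 100 * sum(chain$identity_count) / al,
    CALP = al / queryLength,
    n_hsps_used = nrow(chain),
    stringsAsFactors = FALSE
  )
}

#' Score every query-subject pair in an HSP table
#'
#' Groups an HSP table by (query, subject), rebuilds each pair's alignment
#' and scores it.
#'
#' @param hsps data.frame of HSP records (any number of pairs).
#' @param queryLengths named numeric vector of query lengths in bp.
#' @inheritParams rebuildPairAlignment
#' @return data.frame of pair scores, one row per query-subject pair.
#' @export
scorePairs <- function(hsps, queryLengths, overlapPolicy = "trim") {
  key <- paste(hsps$query_id, hsps$subject_id, sep = "\r")
  rows <- lapply(split(hsps, key), function(h) {
    q <- h$query_id[[1L]]
    if (is.na(queryLengths[q]))
      stop("no query length for ", q, call. = FALSE)
    scorePair(rebuildPairAlignment(h, overlapPolicy), queryLengths[[q]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}

#' Classify a query's conservation status as COS, CNV or PAV
#'
#' Subjects whose pair scores pass both thresholds are candidate homologs.
#' No candidate gives PAV (presence-absence variant: no conserved homolog);
#' exactly one gives COS (conserved orthologous pair); two or more
#' candidates lying within a tandem window of \code{tandemWindow} gene
#' positions on the subject genome give CNV (tandem-duplicated copies);
#' two or more dispersed candidates resolve to COS with the best-scoring
#' subject (highest CALP, ties broken by higher CIP, then lexicographically
#' smaller subject id), the remainder being reported alongside.
#'
#' @param scores data.frame of pair scores for one query (output of
#'   \code{\link{scorePairs}} filtered to one query id).
#' @param cipMin minimum CIP in percent (default 60).
#' @param calpMin minimum CALP as a fraction (default 0.7).
#' @param subjectPositions named integer vector: gene-order position of each
#'   subject on its genome. Required when two or more candidates pass.
#' @param tandemWindow tandem window in gene positions (default 5).
#' @return one-row data.frame: \code{query_id}, \code{class} (COS/CNV/PAV),
#'   \code{supporting} (comma-separated subject ids; empty for PAV),
#'   \code{others} (passing but unsupporting subjects), \code{n_candidates}.
#' @export
classifyConservation <- function(scores, cipMin = 60, calpMin = 0.7,
                                 subjectPositions = NULL, tandemWindow = 5L) {
  stopifnot(length(unique(scores$query_id)) == 1L)
  q <- scores$query_id[[1L]]
  cand <- scores[scores$CIP >= cipMin & scores$CALP >= calpMin, , drop = FALSE]
  call <- function(class, supporting, others = character()) {
    data.frame(query_id = q, class = class,
               supporting = paste(supporting, collapse = ","),
               others = paste(others, collapse = ","),
               n_candidates = nrow(cand), stringsAsFactors = FALSE)
  }
  if (nrow(cand) == 0L) return(call("PAV", character()))
  if (nrow(cand) == 1L) return(call("COS", cand$subject_id))
  if (is.null(subjectPositions) ||
      any(!cand$subject_id %in% names(subjectPositions)))
    stop("subject gene positions required to resolve ", nrow(cand),
         " candidate homologs of ", q, call. = FALSE)
  ord <- order(-cand$CALP, -cand$CIP, cand$subject_id)
  cand <- cand[ord, , drop = FALSE]
  best <- cand$subject_id[[1L]]
  pos <- subjectPositions[cand$subject_id]
  cluster <- cand$subject_id[abs(pos - pos[[1L]]) <= tandemWindow]
  if (length(cluster) >= 2L)
    call("CNV", cluster, setdiff(cand$subject_id, cluster))
  else
    call("COS", best, setdiff(cand$subject_id, best))
}
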