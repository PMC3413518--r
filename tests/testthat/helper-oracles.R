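# Independent oracles used by the property-style tests. Each is written
# as a naive, direct transcription of the rule it checks, sharing no code
# with the package implementation.

makeHsp <- function(qs, qe, id, q = "q", s = "s", alen = qe - qs + 1L) {
  data.frame(query_id = q, subject_id = s,
             query_start = as.integer(qs), query_end = as.integer(qe),
             subject_start = as.integer(qs), subject_end = as.integer(qe),
             aligned_length = as.integer(alen), identity_count = as.integer(id),
             e_value = 1e-10, strand = "+", stringsAsFactors = FALSE)
}

# round half away from zero (the rescaling convention)
rhu <- function(x) trunc(x + 0.5 * sign(x))

# naive repeated-pass overlap resolution: sort, find the leftmost
# overlapping pair, trim the lower-identity-fraction member (ties: the
# later), rescale proportionally, repeat until disjoint
oracleRebuild <- function(hsps) {
  rows <- lapply(seq_len(nrow(hsps)), function(i) hsps[i, , drop = FALSE])
  repeat {
    ord <- order(vapply(rows, function(r) r$query_start, numeric(1)),
                 vapply(rows, function(r) r$query_end, numeric(1)))
    rows <- rows[ord]
    touched <- FALSE
    for (i in seq_along(rows)[-1]) {
      a <- rows[[i - 1]]; b <- rows[[i]]
      ov <- a$query_end - b$query_start + 1L
      if (ov <= 0L) next
      fa <- a$identity_count / a$aligned_length
      fb <- b$identity_count / b$aligned_length
      trim <- function(h, ns, ne) {
        orig <- h$query_end - h$query_start + 1L
        kept <- ne - ns + 1L
        if (kept <= 0L) return(NULL)
        h$identity_count <- as.integer(rhu(h$identity_count * kept / orig))
        h$aligned_length <- as.integer(rhu(h$aligned_length * kept / orig))
        h$query_start <- as.integer(ns); h$query_end <- as.integer(ne)
        h
      }
      if (fb <= fa) rows[[i]] <- trim(b, a$query_end + 1L, b$query_end)
      else rows[[i - 1]] <- trim(a, a$query_start, b$query_start - 1L)
      rows <- rows[!vapply(rows, is.null, logical(1))]
      touched <- TRUE
      break
    }
    if (!touched) break
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

oracleScore <- function(chain, qlen) {
  al <- sum(chain$aligned_length)
  list(AL = al, CIP = 100 * sum(chain$identity_count) / al, CALP = al / qlen)
}

# exhaustive minimal Dollo reconstructions on a rooted tree: enumerate all
# internal-state assignments with the root present and no absent->present
# edge; return the minimum loss count and every loss-branch set achieving it
oracleDollo <- function(tree, leafStates) {
  nTip <- length(tree$tip.label)
  nInt <- tree$Nnode
  labelOf <- function(v) if (v <= nTip) tree$tip.label[v]
                         else tree$node.label[v - nTip]
  best <- Inf; sets <- list()
  for (mask in 0:(2^nInt - 1)) {
    stateOf <- function(v) {
      if (v <= nTip) {
        s <- leafStates[[tree$tip.label[v]]]
        if (s == "unalignable") NA else s == "present"
      } else bitwAnd(bitwShiftR(mask, v - nTip - 1L), 1L) == 1L
    }
    if (!stateOf(nTip + 1L)) next          # gain fixed at the root
    ok <- TRUE; losses <- character()
    for (e in seq_len(nrow(tree$edge))) {
      p <- stateOf(tree$edge[e, 1]); c <- stateOf(tree$edge[e, 2])
      if (is.na(c)) next                   # missing data: unconstrained
      if (!p && c) { ok <- FALSE; break }  # no regain under Dollo
      if (p && !c) losses <- c(losses, labelOf(tree$edge[e, 2]))
    }
    if (!ok) next
    # a leaf marked NA imposes nothing; internal nodes with no known
    # descendants can inflate losses, handled by taking the minimum
    if (length(losses) < best) { best <- length(losses); sets <- list(sort(losses)) }
    else if (length(losses) == best) sets <- c(sets, list(sort(losses)))
  }
  list(min = best, sets = unique(sets))
}

# brute-force breakpoint repeat enumeration by direct substring comparison
oracleRepeatScan <- function(seq, junction, window = 15L, minArm = 3L) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  n <- nchar(seq)
  hits <- 0L
  rows <- list()
  for (a in minArm:window)
    for (i in max(1L, junction - window + 1L):junction)
      for (j in (junction + 1L):min(n, junction + window)) {
        if (i + a - 1L > junction) next
        if (j + a - 1L > min(n, junction + window)) next
        arm1 <- substr(seq, i, i + a - 1L)
        arm2 <- substr(seq, j, j + a - 1L)
        kind <- if (arm1 == arm2) "direct"
                else if (arm2 == rc(arm1)) "inverted" else NA
        if (is.na(kind)) next
        rows[[length(rows) + 1L]] <-
          data.frame(kind = kind, arm1_start = i, arm2_start = j, arm_len = a,
                     stringsAsFactors = FALSE)
      }
  if (!length(rows))
    return(data.frame(kind = character(), arm1_start = integer(),
                      arm2_start = integer(), arm_len = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
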