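#' Fit amplification efficiency from a dilution standard curve
#'
#' Least-squares fit of Cq against log10 template dilution; the
#' amplification efficiency is \eqn{E = 10^{-1/\mathrm{slope}}} (a perfect
#' doubling assay has slope -3.3219 and E = 2).
#'
#' @param dilutions data.frame with columns \code{log10_dilution} and
#'   \code{Cq} (three or more points), or a numeric vector of log10
#'   dilutions when \code{cq} is given separately.
#' @param cq optional numeric vector of Cq values.
#' @return list with \code{slope}, \code{E}, \code{r_squared}, \code{n}.
#' @examples
#' d <- data.frame(log10_dilution = 0:-4, Cq = 20 + 3.3219 * (0:4))
#' fitEfficiency(d)$E   # 2
#' @export
fitEfficiency <- function(dilutions, cq = NULL) {
  if (is.data.frame(dilutions)) {
    x <- dilutions$log10_dilution
    y <- dilutions$Cq
  } else {
    x <- dilutions
    y <- cq
  }
  if (length(x) < 3L) stop("need at least 3 dilution points", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("assay failure: standard-curve slope must be negative",
         call. = FALSE)
  list(slope = slope, E = 10^(-1 / slope),
       r_squared = summary(fit)$r.squared, n = length(x))
}

#' Efficiency-normalized expression ratio
#'
#' The single-sample normalized ratio \eqn{E_T^{-Cq_T} / E_R^{-Cq_R}}.
#' With several reference genes the final ratio is the geometric mean of
#' the per-reference ratios.
#'
#' @param cqT target Cq.
#' @param cqR named (or plain) numeric vector of reference Cq values.
#' @param eT target amplification efficiency (> 1).
#' @param eR numeric vector of reference efficiencies, matching
#'   \code{cqR}.
#' @return numeric(1) normalized ratio.
#' @examples
#' normalizedRatio(24, 24, 2, 2)            # 1
#' normalizedRatio(23, 24, 2, 2)            # 2: one cycle earlier
#' @export
normalizedRatio <- function(cqT, cqR, eT, eR) {
  if (any(is.na(cqR)) || !length(cqR))
    stop("missing reference Cq", call. = FALSE)
  if (eT <= 1 || any(eR <= 1))
    stop("efficiencies must exceed 1", call. = FALSE)
  if (length(eR) != length(cqR))
    stop("one efficiency per reference Cq required", call. = FALSE)
  per <- eT^(-cqT) / eR^(-cqR)
  exp(mean(log(per)))
}

#' Fold-change table from a Cq table
#'
#' Computes the efficiency-normalized ratio for every target-gene
#' measurement (per biological replicate, normalized with the geometric
#' mean over all reference genes of the same sample), then averages
#' replicates within each gene x tissue x treatment x time condition and
#' expresses each condition relative to its control (by default the 0 h
#' timepoint of the same gene, tissue and treatment). Ratios are computed
#' per replicate and then averaged, not from averaged Cq.
#'
#' @param cq Cq table: data.frame with columns \code{gene}, \code{role}
#'   (\code{target}/\code{reference}), \code{tissue}, \code{treatment},
#'   \code{time_h}, \code{replicate}, \code{Cq}.
#' @param efficiencies named numeric vector of per-gene amplification
#'   efficiencies (targets and references).
#' @param controlTime time_h value defining the untreated control
#'   (default 0).
#' @return data.frame with \code{gene}, \code{tissue}, \code{treatment},
#'   \code{time_h}, \code{n}, \code{mean_ratio}, \code{sd_ratio},
#'   \code{fold_change} (mean ratio over control mean ratio).
#' @export
foldChangeTable <- function(cq, efficiencies, controlTime = 0) {
  need <- c("gene", "role", "tissue", "treatment", "time_h", "replicate", "Cq")
  miss <- setdiff(need, names(cq))
  if (length(miss)) stop("Cq table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(cq$Cq <= 0)) stop("Cq values must be positive", call. = FALSE)
  targets <- cq[cq$role == "target", , drop = FALSE]
  refs <- cq[cq$role == "reference", , drop = FALSE]
  if (!nrow(refs)) stop("no reference-gene rows", call. = FALSE)
  genesAll <- unique(cq$gene)
  if (any(!genesAll %in% names(efficiencies)))
    stop("efficiency missing for gene(s): ",
         paste(setdiff(genesAll, names(efficiencies)), collapse = ", "),
         call. = FALSE)

  condKey <- function(d) paste(d$tissue, d$treatment, d$time_h, d$replicate,
                               sep = "\r")
  refSplit <- split(refs, condKey(refs))
  targets$ratio <- vapply(seq_len(nrow(targets)), function(i) {
    r <- refSplit[[condKey(targets[i, ])]]
    if (is.null(r) || !nrow(r))
      stop("no reference Cq for sample ", targets$tissue[i], "/",
           targets$treatment[i], "/", targets$time_h[i], " replicate ",
           targets$replicate[i], call. = FALSE)
    normalizedRatio(targets$Cq[i], r$Cq,
                    efficiencies[[targets$gene[i]]],
                    unname(efficiencies[r$gene]))
  }, numeric(1))

  agg <- do.call(rbind, lapply(
    split(targets, paste(targets$gene, targets$tissue, targets$treatment,
                         targets$time_h, sep = "\r")),
    function(d) data.frame(gene = d$gene[1L], tissue = d$tissue[1L],
                           treatment = d$treatment[1L], time_h = d$time_h[1L],
                           n = nrow(d), mean_ratio = mean(d$ratio),
                           sd_ratio = stats::sd(d$ratio),
                           stringsAsFactors = FALSE)))
  ctrlKey <- paste(agg$gene, agg$tissue, agg$treatment, sep = "\r")
  ctrl <- agg[agg$time_h == controlTime, , drop = FALSE]
  ctrlMean <- stats::setNames(ctrl$mean_ratio,
                              paste(ctrl$gene, ctrl$tissue, ctrl$treatment,
                                    sep = "\r"))
  if (any(!ctrlKey %in% names(ctrlMean)))
    stop("control condition (time_h = ", controlTime,
         ") missing for some gene x tissue x treatment", call. = FALSE)
  agg$fold_change <- agg$mean_ratio / ctrlMean[ctrlKey]
  agg <- agg[order(agg$gene, agg$tissue, agg$treatment, agg$time_h), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' One-way ANOVA with pairwise stage comparisons
#'
#' F and p are computed from the between- and within-group mean squares;
#' all stage pairs are then compared with two-sample pooled-variance
#' t-tests at level \code{alpha} (uncorrected by default, with an optional
#' Bonferroni adjustment), flagging significant pairs. With two groups the
#' ANOVA p equals the pooled t-test p (F = t squared).
#'
#' @param values numeric vector of replicate measurements (e.g. normalized
#'   ratios).
#' @param groups factor-like vector of the same length (e.g. timepoints).
#' @param alpha significance level (default 0.05).
#' @param adjust \code{"none"} (default) or \code{"bonferroni"}.
#' @return list with \code{F}, \code{p}, \code{df} (c(between, within)),
#'   \code{degenerate} (TRUE when all groups have zero variance but
#'   unequal means), and \code{pairwise}, a data.frame with \code{group1},
#'   \code{group2}, \code{t}, \code{p}, \code{p_adj}, \code{significant}.
#' @export
anovaPairwise <- function(values, groups, alpha = 0.05,
                          adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- table(groups)
  if (any(ns < 2L)) stop("need at least 2 replicates per group",
                         call. = FALSE)
  k <- nlevels(groups)
  N <- length(values)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- k - 1L
  dfw <- N - k
  degenerate <- FALSE
  if (ssw == 0) {
    if (ssb == 0) { Fstat <- 0; p <- 1 }
    else { Fstat <- Inf; p <- .Machine$double.xmin; degenerate <- TRUE }
  } else {
    Fstat <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  }
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[groups == pairs[1L, i]]
    b <- values[groups == pairs[2L, i]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- list(statistic = if (mean(a) == mean(b)) 0 else Inf,
                 p.value = if (mean(a) == mean(b)) 1 else .Machine$double.xmin)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_adj <- if (adjust == "bonferroni") pmin(1, pw$p * nrow(pw)) else pw$p
  pw$significant <- pw$p_adj <= alpha
  list(F = Fstat, p = p, df = c(between = dfb, within = dfw),
       degenerate = degenerate, pairwise = pw)
}
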