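#' Stratified k-fold assignment of labeled drug pairs
#'
#' Partitions the pairs into k folds preserving the global ST:non-ST ratio
#' within each fold to within one pair per class. Cross-validation is at
#' the pair level: an individual drug may appear in both training and test
#' pairs (the documented leakage of pair-level CV; see the package
#' vignette).
#'
#' @param labels data.frame(a, b, st) from \code{\link{labelPairs}}.
#' @param k number of folds.
#' @param seed integer seed; the assignment is reproducible given the seed.
#' @return integer vector of fold IDs (1..k), parallel to \code{labels}.
#' @export
stratifiedPairCV <- function(labels, k = 5, seed = 1) {
  stopifnot(k >= 2)
  nst <- sum(labels$st); nnon <- sum(!labels$st)
  if (nst < k || nnon < k)
    stopf("need at least k = %d pairs of each class (have %d ST, %d non-ST)",
          k, nst, nnon)
  fold <- integer(nrow(labels))
  withSeed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(labels$st == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a random positive outscores a random negative,
#' with ties counted half -- computed from average ranks, exactly
#' equivalent to the all-pairs concordance count.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class labels, \code{TRUE} = positive.
#' @return AUROC in \eqn{[0, 1]}.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Kolmogorov-Smirnov separation of ST vs non-ST scores
#'
#' D is the maximum absolute difference between the two empirical CDFs;
#' the p-value is the asymptotic two-sample approximation.
#'
#' @param scoresST,scoresNonST numeric samples (nonempty).
#' @return list with \code{D}, \code{p}, \code{nST}, \code{nNonST}.
#' @export
ksSeparation <- function(scoresST, scoresNonST) {
  stopifnot(length(scoresST) > 0, length(scoresNonST) > 0)
  pts <- sort(unique(c(scoresST, scoresNonST)))
  f1 <- stats::ecdf(scoresST); f2 <- stats::ecdf(scoresNonST)
  D <- max(abs(f1(pts) - f2(pts)))
  kt <- suppressWarnings(stats::ks.test(scoresST, scoresNonST,
                                        exact = FALSE))
  list(D = D, p = kt$p.value, nST = length(scoresST),
       nNonST = length(scoresNonST))
}

#' Pooled-fold cross-validated TLRs
#'
#' For each fold, refits the full TLR model (per-channel binning, curve
#' fit and imputation medians) on the training pairs only, scores the
#' held-out pairs, and pools all held-out TLRs.
#'
#' @param sims named list of \linkS4class{SimilarityMatrix}.
#' @param targets named list of known targets per drug.
#' @param channels channels to integrate (default: all of \code{sims}).
#' @param k folds.
#' @param seed fold-assignment seed.
#' @param requireComplete if \code{TRUE}, only pairs with a defined score
#'   in every included channel are evaluated (no imputation); otherwise
#'   all labeled pairs are scored with median imputation of missing
#'   channels.
#' @param nBins,alpha see \code{\link{fitLikelihoodModel}}.
#' @return data.frame(a, b, st, fold, tlr) of pooled held-out pairs, with
#'   attribute \code{"auroc"}.
#' @export
cvTLR <- function(sims, targets, channels = names(sims), k = 5, seed = 1,
                  requireComplete = FALSE, nBins = 20, alpha = 1) {
  sims <- sims[channels]
  drugs <- sort(unique(unlist(lapply(sims, drugIds))))
  annotated <- drugs[drugs %in% names(targets) & lengths(targets[drugs]) > 0]
  labels <- suppressWarnings(labelPairs(annotated, targets))
  if (!nrow(labels)) stopf("no labeled pairs")
  scoreTab <- vapply(sims, function(s) lookupPairScores(s, labels$a, labels$b),
                     numeric(nrow(labels)))
  scoreTab <- matrix(scoreTab, nrow = nrow(labels),
                     dimnames = list(NULL, channels))
  if (requireComplete) {
    keep <- rowSums(is.na(scoreTab)) == 0L
    labels <- labels[keep, , drop = FALSE]
    scoreTab <- scoreTab[keep, , drop = FALSE]
    if (!nrow(labels)) stopf("no pairs with complete channel data")
  }
  fold <- stratifiedPairCV(labels, k = k, seed = seed)
  tlr <- rep(NA_real_, nrow(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    liks <- rep(1, sum(te))
    for (ch in channels) {
      sc <- scoreTab[, ch]
      med <- stats::median(sc[tr], na.rm = TRUE)
      m <- fitLikelihoodModel(sc[tr], labels$st[tr], channel = ch,
                              range = sims[[ch]]@range, nBins = nBins,
                              alpha = alpha, median = med)
      sTest <- sc[te]
      l <- numeric(length(sTest))
      obs <- !is.na(sTest)
      if (any(obs)) l[obs] <- likelihoodAt(m, sTest[obs])
      if (any(!obs)) l[!obs] <- likelihoodAt(m, m@median)
      liks <- liks * l
    }
    tlr[te] <- liks
  }
  out <- data.frame(a = labels$a, b = labels$b, st = labels$st,
                    fold = fold, tlr = tlr)
  attr(out, "auroc") <- rocAuc(out$tlr, out$st)
  out
}

#' Cross-validated AUROC for every nonempty channel subset
#'
#' For each nonempty subset of the channels, the pooled-fold AUROC of the
#' subset's TLR is computed under one or both availability policies:
#' \code{"complete"} requires every included channel defined for a pair,
#' \code{"impute"} scores all labeled pairs with median imputation. A
#' subset with no eligible pairs is flagged (\code{NA} AUROC), not
#' dropped.
#'
#' @param sims named list of \linkS4class{SimilarityMatrix}.
#' @param targets named list of known targets per drug.
#' @param k,seed,nBins,alpha see \code{\link{cvTLR}}.
#' @param policies subset of \code{c("complete", "impute")}.
#' @return data.frame(subset, size, policy, auroc, nPairs).
#' @export
aurocBySubsets <- function(sims, targets, k = 5, seed = 1,
                           policies = c("complete", "impute"),
                           nBins = 20, alpha = 1) {
  policies <- match.arg(policies, several.ok = TRUE)
  chs <- names(sims)
  subsets <- unlist(lapply(seq_along(chs), function(m)
    utils::combn(chs, m, simplify = FALSE)), recursive = FALSE)
  rows <- list()
  for (sub in subsets) for (pol in policies) {
    res <- tryCatch(
      cvTLR(sims, targets, channels = sub, k = k, seed = seed,
            requireComplete = (pol == "complete"), nBins = nBins,
            alpha = alpha),
      error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      subset = paste(sub, collapse = "+"), size = length(sub), policy = pol,
      auroc = if (is.null(res)) NA_real_ else attr(res, "auroc"),
      nPairs = if (is.null(res)) 0L else nrow(res))
  }
  do.call(rbind, rows)
}

#' True-positive / false-positive ratio across TLR cutoffs
#'
#' At each cutoff, TP = ST pairs with TLR >= cutoff and FP = non-ST pairs
#' with TLR >= cutoff. The ratio is \code{Inf} when FP = 0 and TP > 0, and
#' \code{NaN} (flagged in \code{defined}) when both counts are 0.
#'
#' @param tlr numeric TLRs of labeled pairs.
#' @param st logical ST labels.
#' @param cutoffs ascending numeric cutoffs.
#' @return data.frame(cutoff, tp, fp, ratio, defined).
#' @export
tpFpRatioCurve <- function(tlr, st, cutoffs) {
  stopifnot(length(tlr) == length(st), !is.unsorted(cutoffs))
  st <- as.logical(st)
  tp <- vapply(cutoffs, function(c) sum(st & tlr >= c), integer(1))
  fp <- vapply(cutoffs, function(c) sum(!st & tlr >= c), integer(1))
  ratio <- ifelse(fp > 0, tp / fp, ifelse(tp > 0, Inf, NaN))
  data.frame(cutoff = cutoffs, tp = tp, fp = fp, ratio = ratio,
             defined = fp + tp > 0L)
}

#' Leave-one-out voting accuracy across TLR cutoffs
#'
#' For each annotated drug, the TLR model is refit with every pair
#' involving that drug held out; the drug is then compared to all other
#' annotated drugs and its top-voted target computed at each cutoff.
#' Accuracy at a cutoff is the fraction of non-abstaining drugs whose
#' top-voted target is among their known targets; abstentions (no partner
#' reaches the cutoff) are reported separately.
#'
#' @param sims named list of \linkS4class{SimilarityMatrix}.
#' @param targets named list of known targets per drug.
#' @param cutoffs ascending numeric TLR cutoffs.
#' @param weight vote weighting, see \code{\link{voteTargets}}.
#' @param nBins,alpha see \code{\link{fitLikelihoodModel}}.
#' @return data.frame(cutoff, accuracy, nEvaluated, nAbstain); accuracy is
#'   \code{NaN} where every drug abstains.
#' @export
looTargetAccuracy <- function(sims, targets, cutoffs, weight = "tlr",
                              nBins = 20, alpha = 1) {
  stopifnot(!is.unsorted(cutoffs))
  drugs <- sort(unique(unlist(lapply(sims, drugIds))))
  annotated <- drugs[drugs %in% names(targets) & lengths(targets[drugs]) > 0]
  if (length(annotated) < 2L) stopf("need at least 2 annotated drugs")
  labels <- suppressWarnings(labelPairs(annotated, targets))
  chs <- names(sims)
  scoreTab <- vapply(sims, function(s) lookupPairScores(s, labels$a, labels$b),
                     numeric(nrow(labels)))
  scoreTab <- matrix(scoreTab, nrow = nrow(labels),
                     dimnames = list(NULL, chs))
  correct <- matrix(FALSE, length(annotated), length(cutoffs))
  abstain <- matrix(TRUE, length(annotated), length(cutoffs))
  for (di in seq_along(annotated)) {
    d <- annotated[di]
    inD <- labels$a == d | labels$b == d
    if (!any(inD)) next
    tlrD <- rep(1, sum(inD))
    for (ch in chs) {
      sc <- scoreTab[, ch]
      med <- stats::median(sc[!inD], na.rm = TRUE)
      m <- fitLikelihoodModel(sc[!inD], labels$st[!inD], channel = ch,
                              range = sims[[ch]]@range, nBins = nBins,
                              alpha = alpha, median = med)
      sD <- sc[inD]
      l <- numeric(length(sD)); obs <- !is.na(sD)
      if (any(obs)) l[obs] <- likelihoodAt(m, sD[obs])
      if (any(!obs)) l[!obs] <- likelihoodAt(m, m@median)
      tlrD <- tlrD * l
    }
    partner <- ifelse(labels$a[inD] == d, labels$b[inD], labels$a[inD])
    ord <- order(-tlrD, partner)
    partner <- partner[ord]; tlrD <- tlrD[ord]
    for (ci in seq_along(cutoffs)) {
      sel <- tlrD >= cutoffs[ci]
      if (!any(sel)) next
      tally <- voteTargets(data.frame(partner = partner[sel],
                                      tlr = tlrD[sel]),
                           targets, weight = weight)
      if (!nrow(tally)) next
      abstain[di, ci] <- FALSE
      correct[di, ci] <- tally$target[1] %in% targets[[d]]
    }
  }
  nEval <- colSums(!abstain)
  acc <- ifelse(nEval > 0, colSums(correct) / nEval, NaN)
  data.frame(cutoff = cutoffs, accuracy = acc, nEvaluated = nEval,
             nAbstain = colSums(abstain))
}

#' Correlation between two similarity channels
#'
#' Pearson correlation (and R^2) of the two channels' scores over the
#' pairs defined in both -- the cross-channel dependence check that
#' underpins the naive Bayes product.
#'
#' @param simA,simB two \linkS4class{SimilarityMatrix}; drugs present in
#'   both are compared.
#' @return list with \code{pcc}, \code{r2}, \code{n} (joint pairs); values
#'   \code{NA} when fewer than 3 joint pairs exist.
#' @export
crossTypeCorrelation <- function(simA, simB) {
  common <- intersect(drugIds(simA), drugIds(simB))
  if (length(common) < 3L)
    return(list(pcc = NA_real_, r2 = NA_real_, n = 0L))
  x <- pairVector(simA@scores[common, common])
  y <- pairVector(simB@scores[common, common])
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(list(pcc = NA_real_, r2 = NA_real_, n = sum(ok)))
  pcc <- stats::cor(x[ok], y[ok])
  list(pcc = pcc, r2 = pcc^2, n = sum(ok))
}

#' Rank-sum enrichment of predicted vs non-predicted measurements
#'
#' One-sided Wilcoxon rank-sum test that the measurements of predicted
#' interactions are shifted relative to the others (for an inhibition
#' screen reporting percent remaining activity, \code{direction = "less"}
#' tests that predictions show stronger inhibition).
#'
#' @param predictedValues,otherValues numeric samples.
#' @param direction \code{"less"} (predicted < other) or \code{"greater"}.
#' @return the one-sided p-value.
#' @export
screenEnrichment <- function(predictedValues, otherValues,
                             direction = c("less", "greater")) {
  direction <- match.arg(direction)
  stopifnot(length(predictedValues) > 0, length(otherValues) > 0)
  suppressWarnings(stats::wilcox.test(predictedValues, otherValues,
                                      alternative = direction))$p.value
}
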