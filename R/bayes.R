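#' Label all unordered drug pairs as shared-target (ST) or non-ST
#'
#' A pair is ST iff the two drugs' known target sets intersect. Drugs with
#' an empty or absent target set are orphans, not negatives: they are
#' excluded with a warning and never contribute labeled pairs.
#'
#' @param drugs character vector of drug IDs to pair.
#' @param targets named list mapping drug ID to character vector of targets.
#' @return data.frame with columns \code{a}, \code{b} (IDs, canonical pair
#'   order) and logical \code{st}; attribute \code{"excluded"} lists the
#'   dropped orphans.
#' @export
labelPairs <- function(drugs, targets) {
  stopifnot(!anyDuplicated(drugs))
  has <- drugs %in% names(targets) & lengths(targets[drugs]) > 0
  if (any(!has))
    warnf("labelPairs: excluded %d drug(s) with no known targets", sum(!has))
  keep <- drugs[has]
  if (length(keep) < 2L)
    return(structure(data.frame(a = character(0), b = character(0),
                                st = logical(0)),
                     excluded = drugs[!has]))
  allT <- unique(unlist(targets[keep], use.names = FALSE))
  M <- matrix(0L, length(keep), length(allT), dimnames = list(keep, allT))
  for (d in keep) M[d, unique(targets[[d]])] <- 1L
  shared <- tcrossprod(M) > 0
  pr <- pairIndices(length(keep))
  structure(data.frame(a = keep[pr[, 1L]], b = keep[pr[, 2L]],
                       st = pairVector(shared)),
            excluded = drugs[!has])
}

#' Fit the likelihood-ratio model of one similarity channel
#'
#' Bins the labeled similarity scores into \code{nBins} evenly spaced
#' intervals over the channel's score range and computes, per bin,
#' \deqn{\hat L_b = \frac{(ST_b + \alpha) / (N_{ST} + \alpha B)}
#'                      {(nonST_b + \alpha) / (N_{nonST} + \alpha B)}}
#' i.e. the fraction of ST pairs with that score over the fraction of
#' non-ST pairs, Laplace-smoothed so empty bins stay finite. An exponential
#' curve \eqn{L(s) = a e^{b s}} is then fit by least squares on
#' \eqn{\log \hat L_b} at the bin centers, weighted by total bin occupancy;
#' the curve, not the raw ratios, scores new pairs. If fewer than two
#' distinct occupied bin centers exist (all scores identical), the model
#' degenerates to the constant \eqn{L(s) = \hat L} of the occupied bin.
#'
#' @param scores numeric similarity scores (masked \code{NA} values are
#'   dropped along with their labels).
#' @param st logical labels, parallel to \code{scores}.
#' @param channel channel name.
#' @param range score range to bin over (the channel's natural range, not
#'   the observed one).
#' @param nBins number of evenly spaced bins.
#' @param alpha pseudocount on bin counts; with \code{alpha = 0} bins with
#'   a zero or infinite raw ratio are excluded from the curve fit.
#' @param median imputation median to store; defaults to the median of the
#'   supplied defined scores. Pass the median of \emph{all} observed scores
#'   of the channel (not only labeled pairs) when available.
#' @return a \linkS4class{LikelihoodModel}.
#' @export
fitLikelihoodModel <- function(scores, st, channel, range, nBins = 20,
                               alpha = 1, median = NULL) {
  stopifnot(length(scores) == length(st), nBins >= 1, length(range) == 2L,
            range[1] < range[2])
  ok <- !is.na(scores)
  scores <- scores[ok]; st <- as.logical(st[ok])
  if (!any(st) || !any(!st))
    stopf("channel '%s': need at least one ST and one non-ST defined score",
          channel)
  span <- diff(range)
  out <- scores < range[1] - 0.05 * span | scores > range[2] + 0.05 * span
  if (any(out)) stopf("channel '%s': scores far outside the declared range",
                      channel)
  scores <- pmin(pmax(scores, range[1]), range[2])
  breaks <- seq(range[1], range[2], length.out = nBins + 1L)
  bin <- findInterval(scores, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cst <- tabulate(bin[st], nBins)
  cnon <- tabulate(bin[!st], nBins)
  num <- (cst + alpha) / (sum(cst) + alpha * nBins)
  den <- (cnon + alpha) / (sum(cnon) + alpha * nBins)
  ratios <- num / den
  centers <- (breaks[-1] + breaks[-(nBins + 1L)]) / 2
  w <- cst + cnon
  usable <- w > 0 & is.finite(ratios) & ratios > 0
  co <- if (sum(usable) >= 2L &&
            stats::sd(centers[usable]) > 0) {
    fit <- stats::lm(log(ratios[usable]) ~ centers[usable],
                     weights = w[usable])
    c(a = exp(unname(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
  } else {
    lbar <- stats::weighted.mean(ratios[usable], w[usable])
    c(a = unname(lbar), b = 0)
  }
  if (is.null(median)) median <- stats::median(scores)
  new("LikelihoodModel", channel = channel, breaks = breaks, ratios = ratios,
      counts = rbind(ST = cst, nonST = cnon), coef = co,
      median = unname(median), alpha = alpha, range = range)
}

#' @rdname likelihoodAt
#' @export
setMethod("likelihoodAt", "LikelihoodModel", function(model, s) {
  span <- diff(model@range)
  lo <- model@range[1]; hi <- model@range[2]
  far <- !is.na(s) & (s < lo - 0.05 * span | s > hi + 0.05 * span)
  if (any(far))
    stopf("channel '%s': score %g far outside range [%g, %g]",
          model@channel, s[far][1], lo, hi)
  clamped <- !is.na(s) & (s < lo - 1e-8 * span | s > hi + 1e-8 * span)
  if (any(clamped))
    warnf("channel '%s': clamped %d out-of-range score(s) to the boundary",
          model@channel, sum(clamped))
  s <- pmin(pmax(s, lo), hi)
  model@coef[["a"]] * exp(model@coef[["b"]] * s)
})

#' Fit the full TLR model over a set of similarity channels
#'
#' Labels all pairs of annotated drugs, then fits one
#' \code{\link{fitLikelihoodModel}} per channel from the defined scores of
#' the labeled pairs. Each channel's imputation median is the median of all
#' its observed similarity scores (labeled or not), recorded before any
#' imputation takes place.
#'
#' @param sims named list of \linkS4class{SimilarityMatrix} (channels may
#'   cover different drug subsets).
#' @param targets named list of known targets per drug.
#' @param pairs optional data.frame(a, b, st) of pre-labeled pairs; default
#'   labels all pairs of drugs annotated in \code{targets} that appear in
#'   at least one channel.
#' @param nBins,alpha binning parameters, see \code{\link{fitLikelihoodModel}}.
#' @return a \linkS4class{TLRModel}.
#' @export
fitTLRModel <- function(sims, targets, pairs = NULL, nBins = 20, alpha = 1) {
  stopifnot(is.list(sims), length(sims) >= 1L, !is.null(names(sims)))
  for (s in sims) stopifnot(is(s, "SimilarityMatrix"))
  if (is.null(pairs)) {
    drugs <- unique(unlist(lapply(sims, drugIds)))
    annotated <- drugs[drugs %in% names(targets) & lengths(targets[drugs]) > 0]
    pairs <- suppressWarnings(labelPairs(annotated, targets))
  }
  if (!nrow(pairs)) stopf("no labeled pairs available to fit on")
  models <- lapply(names(sims), function(ch) {
    sm <- sims[[ch]]
    sc <- lookupPairScores(sm, pairs$a, pairs$b)
    allObserved <- pairVector(sm@scores)
    med <- stats::median(allObserved, na.rm = TRUE)
    fitLikelihoodModel(sc, pairs$st, channel = ch, range = sm@range,
                       nBins = nBins, alpha = alpha, median = med)
  })
  names(models) <- names(sims)
  new("TLRModel", models = models, version = "1")
}

# Similarity scores of (a, b) pairs in one channel; NA when either drug is
# absent from the channel or the pair is masked.
lookupPairScores <- function(sim, a, b) {
  ids <- drugIds(sim)
  ia <- match(a, ids); ib <- match(b, ids)
  out <- rep(NA_real_, length(a))
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- sim@scores[cbind(ia[ok], ib[ok])]
  out
}

#' Total likelihood ratio of one drug pair
#'
#' Multiplies the per-channel likelihood ratios of the supplied similarity
#' scores. A channel whose score is missing (\code{NA} or absent from
#' \code{similarities}) contributes its imputation-median likelihood
#' \code{likelihoodAt(model, median)} -- imputation happens after the
#' similarity-to-likelihood conversion, on the likelihood scale's input,
#' never on raw bin counts.
#'
#' @param model a \linkS4class{TLRModel}.
#' @param similarities named numeric vector of per-channel scores
#'   (\code{NA} = channel missing for this pair); channels of the model
#'   absent from the vector are treated as missing.
#' @return list with \code{tlr} (positive scalar) and \code{evidence}: a
#'   data.frame with one row per model channel and columns \code{channel},
#'   \code{similarity}, \code{likelihood}, \code{imputed}.
#' @export
totalLikelihoodRatio <- function(model, similarities = numeric(0)) {
  stopifnot(is(model, "TLRModel"))
  chs <- names(model@models)
  sim <- rep(NA_real_, length(chs)); names(sim) <- chs
  got <- intersect(names(similarities), chs)
  sim[got] <- similarities[got]
  lik <- numeric(length(chs)); imputed <- is.na(sim)
  for (k in seq_along(chs)) {
    m <- model@models[[k]]
    lik[k] <- likelihoodAt(m, if (imputed[k]) m@median else sim[[k]])
  }
  if (all(imputed))
    warnf("pair has no observed channel; TLR is fully imputed")
  list(tlr = prod(lik),
       evidence = data.frame(channel = chs, similarity = unname(sim),
                             likelihood = lik, imputed = imputed))
}

#' TLRs of many pairs at once
#'
#' Vectorized scoring: for each requested pair and each channel of the
#' model, looks up the similarity score (masked/absent = imputed with the
#' channel median after likelihood conversion) and multiplies the fitted
#' likelihoods into the TLR.
#'
#' @param model a \linkS4class{TLRModel}.
#' @param sims named list of \linkS4class{SimilarityMatrix}; must cover the
#'   model's channels (a whole channel may be omitted, in which case every
#'   pair imputes it).
#' @param pairs data.frame with columns \code{a}, \code{b}; default: all
#'   unordered pairs of drugs present in any channel.
#' @param evidence if \code{TRUE}, attach per-channel similarity,
#'   likelihood and imputed columns.
#' @return data.frame with columns \code{a}, \code{b}, \code{tlr} and, with
#'   \code{evidence}, \code{sim_<ch>}, \code{lik_<ch>}, \code{imp_<ch>}.
#' @export
pairTLR <- function(model, sims, pairs = NULL, evidence = FALSE) {
  stopifnot(is(model, "TLRModel"))
  if (is.null(pairs)) {
    drugs <- sort(unique(unlist(lapply(sims, drugIds))))
    pr <- pairIndices(length(drugs))
    pairs <- data.frame(a = drugs[pr[, 1L]], b = drugs[pr[, 2L]])
  }
  out <- data.frame(a = pairs$a, b = pairs$b)
  tlr <- rep(1, nrow(pairs))
  for (ch in names(model@models)) {
    m <- model@models[[ch]]
    sc <- if (ch %in% names(sims)) lookupPairScores(sims[[ch]], pairs$a, pairs$b)
          else rep(NA_real_, nrow(pairs))
    imp <- is.na(sc)
    lik <- numeric(length(sc))
    if (any(!imp)) lik[!imp] <- likelihoodAt(m, sc[!imp])
    if (any(imp)) lik[imp] <- likelihoodAt(m, m@median)
    tlr <- tlr * lik
    if (evidence) {
      out[[paste0("sim_", ch)]] <- sc
      out[[paste0("lik_", ch)]] <- lik
      out[[paste0("imp_", ch)]] <- imp
    }
  }
  out$tlr <- tlr
  out
}
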