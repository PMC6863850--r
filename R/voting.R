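#' Shared-target predictions for a query drug
#'
#' All annotated partners of the query whose TLR meets the cutoff, sorted
#' by TLR descending (ties by partner ID for determinism). Partners without
#' known targets are never predictions.
#'
#' @param query drug ID; must appear in \code{tlr}.
#' @param tlr data.frame with columns \code{a}, \code{b}, \code{tlr} (as
#'   from \code{\link{pairTLR}}).
#' @param targets named list of known targets per drug.
#' @param cutoff positive TLR threshold (\code{tlr >= cutoff} qualifies).
#' @return data.frame with columns \code{partner}, \code{tlr}.
#' @export
predictSharedTargets <- function(query, tlr, targets, cutoff) {
  stopifnot(cutoff > 0)
  inA <- tlr$a == query; inB <- tlr$b == query
  if (!any(inA | inB)) stopf("query '%s' absent from the TLR results", query)
  partner <- c(tlr$b[inA], tlr$a[inB])
  value <- c(tlr$tlr[inA], tlr$tlr[inB])
  keep <- !duplicated(partner)
  partner <- partner[keep]; value <- value[keep]
  annotated <- partner %in% names(targets) & lengths(targets[partner]) > 0
  partner <- partner[annotated]; value <- value[annotated]
  sel <- value >= cutoff
  ord <- order(-value[sel], partner[sel])
  data.frame(partner = partner[sel][ord], tlr = value[sel][ord])
}

#' Weighted target voting over shared-target predictions
#'
#' Every prediction casts one vote for each known target of its partner
#' drug, weighted by the prediction's TLR (optionally by \code{log(TLR)}).
#' Targets are ranked by total vote mass; ties break by higher supporting
#' prediction count, then higher maximum supporting TLR, then lexical
#' target ID. An empty prediction set is an explicit abstention (zero-row
#' tally).
#'
#' @param predictions data.frame(partner, tlr) as returned by
#'   \code{\link{predictSharedTargets}}.
#' @param targets named list of known targets per drug.
#' @param weight \code{"tlr"} (raw TLR, the default) or \code{"logtlr"}.
#' @return data.frame with columns \code{target}, \code{mass},
#'   \code{support} (number of supporting predictions), \code{maxTLR},
#'   \code{rank}, ordered by rank.
#' @export
voteTargets <- function(predictions, targets, weight = c("tlr", "logtlr")) {
  weight <- match.arg(weight)
  empty <- data.frame(target = character(0), mass = numeric(0),
                      support = integer(0), maxTLR = numeric(0),
                      rank = integer(0))
  if (!nrow(predictions)) return(empty)
  w <- if (weight == "tlr") predictions$tlr else log(predictions$tlr)
  tgt <- targets[predictions$partner]
  long <- data.frame(target = unlist(tgt, use.names = FALSE),
                     w = rep(w, lengths(tgt)),
                     tlr = rep(predictions$tlr, lengths(tgt)))
  if (!nrow(long)) return(empty)
  agg <- do.call(rbind, lapply(split(long, long$target), function(d)
    data.frame(target = d$target[1], mass = sum(d$w), support = nrow(d),
               maxTLR = max(d$tlr))))
  ord <- order(-agg$mass, -agg$support, -agg$maxTLR, agg$target)
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}

#' High-confidence filter on a voting tally
#'
#' Confirms the top-voted target only if (i) it appears among the known
#' targets of a strict majority of the shared-target predictions and
#' (ii) it is among the known targets of the single highest-TLR prediction.
#' Otherwise the filter abstains -- it never substitutes a different
#' target.
#'
#' @param tally data.frame from \code{\link{voteTargets}}.
#' @param predictions data.frame(partner, tlr) already filtered at the
#'   high-confidence TLR cutoff (e.g. 500).
#' @param targets named list of known targets per drug.
#' @return the confirmed target ID, or \code{NA_character_} on abstention.
#' @export
highConfidenceFilter <- function(tally, predictions, targets) {
  if (!nrow(tally) || !nrow(predictions)) return(NA_character_)
  top <- tally$target[1]
  carries <- vapply(predictions$partner,
                    function(p) top %in% targets[[p]], logical(1))
  if (sum(carries) * 2L <= nrow(predictions)) return(NA_character_)
  best <- predictions[order(-predictions$tlr, predictions$partner), ][1, ]
  if (!top %in% targets[[best$partner]]) return(NA_character_)
  top
}

#' Predict the specific target of a query drug
#'
#' Convenience wrapper: shared-target predictions at \code{cutoff}, the
#' weighted vote tally, and the high-confidence confirmation at
#' \code{hcCutoff}.
#'
#' @param query drug ID.
#' @param tlr pairwise TLR data.frame (\code{\link{pairTLR}}).
#' @param targets named list of known targets per drug.
#' @param cutoff TLR cutoff for shared-target predictions.
#' @param hcCutoff TLR cutoff for the high-confidence filter (default 500).
#' @param weight vote weighting, see \code{\link{voteTargets}}.
#' @return list with \code{predictions}, \code{tally}, \code{topTarget}
#'   (\code{NA} on abstention) and \code{confirmed} (high-confidence target
#'   or \code{NA}).
#' @export
predictTarget <- function(query, tlr, targets, cutoff = 100, hcCutoff = 500,
                          weight = "tlr") {
  preds <- predictSharedTargets(query, tlr, targets, cutoff)
  tally <- voteTargets(preds, targets, weight = weight)
  hcPreds <- preds[preds$tlr >= hcCutoff, , drop = FALSE]
  hcTally <- voteTargets(hcPreds, targets, weight = weight)
  list(predictions = preds, tally = tally,
       topTarget = if (nrow(tally)) tally$target[1] else NA_character_,
       confirmed = highConfidenceFilter(hcTally, hcPreds, targets))
}
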