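#' Screen an orphan library for a protein target of interest
#'
#' The library-screening scenario: fit the TLR model on annotated drugs,
#' score every eligible orphan (an orphan must carry data in at least
#' \code{minChannels} channels) against all annotated drugs, run the
#' weighted vote plus the high-confidence filter, and return the orphans
#' whose confirmed high-confidence prediction equals the target, ranked by
#' vote mass.
#'
#' @param sims named list of \linkS4class{SimilarityMatrix} covering
#'   annotated drugs and orphans.
#' @param targets named list of known targets per drug (orphans absent or
#'   empty).
#' @param target protein target of interest; must occur in \code{targets}.
#' @param cutoff high-confidence TLR cutoff (default 500).
#' @param minChannels minimum number of channels with data an orphan needs
#'   to be screened (default 3).
#' @param model optional pre-fitted \linkS4class{TLRModel}; fitted from
#'   \code{sims}/\code{targets} when omitted.
#' @param weight vote weighting, see \code{\link{voteTargets}}.
#' @return data.frame(drug_id, voteMass, nSupport, topTLR) of confirmed
#'   hits, ranked by vote mass descending; zero rows (with a warning) when
#'   nothing qualifies.
#' @export
runScreen <- function(sims, targets, target, cutoff = 500, minChannels = 3,
                      model = NULL, weight = "tlr") {
  known <- unique(unlist(targets))
  if (!target %in% known) {
    near <- utils::head(known[order(utils::adist(target, known))], 3L)
    stopf("unknown target '%s'; nearest known targets: %s", target,
          paste(near, collapse = ", "))
  }
  if (is.null(model)) model <- fitTLRModel(sims, targets)
  drugs <- sort(unique(unlist(lapply(sims, drugIds))))
  annotated <- drugs[drugs %in% names(targets) & lengths(targets[drugs]) > 0]
  orphans <- setdiff(drugs, annotated)
  coverage <- channelCoverage(sims, orphans)
  eligible <- orphans[coverage >= minChannels]
  hits <- list()
  for (q in eligible) {
    prs <- data.frame(a = q, b = annotated)
    tlr <- pairTLR(model, sims, pairs = prs)
    preds <- predictSharedTargets(q, tlr, targets, cutoff = cutoff)
    tally <- voteTargets(preds, targets, weight = weight)
    conf <- highConfidenceFilter(tally, preds, targets)
    if (!is.na(conf) && conf == target)
      hits[[q]] <- data.frame(drug_id = q, voteMass = tally$mass[1],
                              nSupport = tally$support[1],
                              topTLR = max(preds$tlr))
  }
  if (!length(hits)) {
    warnf("no orphan passed the high-confidence screen for target '%s'",
          target)
    return(data.frame(drug_id = character(0), voteMass = numeric(0),
                      nSupport = integer(0), topTLR = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-out$voteMass, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict targets for a single development candidate
#'
#' The candidate scenario: TLRs between the query and all annotated drugs,
#' the weighted vote tally, the top shared-target partners with per-channel
#' evidence (imputed channels flagged), and the high-confidence
#' confirmation.
#'
#' @param sims named list of \linkS4class{SimilarityMatrix}.
#' @param targets named list of known targets per drug.
#' @param query drug ID; must carry data in at least one channel.
#' @param cutoff shared-target TLR cutoff for voting (default 100).
#' @param hcCutoff high-confidence cutoff (default 500).
#' @param model optional pre-fitted \linkS4class{TLRModel}.
#' @param weight vote weighting.
#' @return list with \code{tally}, \code{predictions}, \code{evidence}
#'   (per-partner per-channel similarity/likelihood/imputed columns),
#'   \code{topTarget} and \code{confirmed}.
#' @export
runCandidate <- function(sims, targets, query, cutoff = 100, hcCutoff = 500,
                         model = NULL, weight = "tlr") {
  if (channelCoverage(sims, query) < 1L)
    stopf("query '%s' has no data in any configured channel", query)
  if (is.null(model)) model <- fitTLRModel(sims, targets)
  drugs <- sort(unique(unlist(lapply(sims, drugIds))))
  annotated <- setdiff(
    drugs[drugs %in% names(targets) & lengths(targets[drugs]) > 0], query)
  ev <- pairTLR(model, sims, pairs = data.frame(a = query, b = annotated),
                evidence = TRUE)
  res <- predictTarget(query, ev, targets, cutoff = cutoff,
                       hcCutoff = hcCutoff, weight = weight)
  list(tally = res$tally, predictions = res$predictions,
       evidence = ev[order(-ev$tlr, ev$b), , drop = FALSE],
       topTarget = res$topTarget, confirmed = res$confirmed)
}

# number of channels in which each drug has any defined data
channelCoverage <- function(sims, drugs) {
  cov <- vapply(drugs, function(d) {
    sum(vapply(sims, function(s) {
      i <- match(d, drugIds(s))
      !is.na(i) && any(!is.na(s@scores[i, -i]))
    }, logical(1)))
  }, integer(1))
  cov
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration, seed, package version and MD5 checksums of
#' the input files -- sufficient to reproduce outputs bit-exactly.
#'
#' @param path output JSON path.
#' @param config list of run parameters.
#' @param seed integer seed used.
#' @param inputs character vector of input file paths to checksum.
#' @return invisibly, the path.
#' @export
writeManifest <- function(path, config, seed, inputs = character(0)) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  payload <- list(package = "DrugBayes",
                  version = as.character(utils::packageVersion("DrugBayes")),
                  seed = seed, config = config, inputChecksums = sums)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                              digits = I(17)), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Mirrors the run parameters (input paths per channel, active channels,
#' cutoffs, CV spec, output directory). At least one channel must be
#' configured and all cutoffs must be positive.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$channels) || !length(cfg$channels))
    stopf("run config must list at least one channel")
  for (cu in c("tlrCutoff", "hcCutoff"))
    if (!is.null(cfg[[cu]]) && cfg[[cu]] <= 0)
      stopf("'%s' must be > 0", cu)
  if (is.null(cfg$tlrCutoff)) cfg$tlrCutoff <- 100
  if (is.null(cfg$hcCutoff)) cfg$hcCutoff <- 500
  if (is.null(cfg$folds)) cfg$folds <- 5
  if (is.null(cfg$minChannels)) cfg$minChannels <- 3
  cfg
}
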