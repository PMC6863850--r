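#' @import methods
NULL

#' Symmetric drug-drug similarity matrix for one data type
#'
#' Holds all pairwise similarity scores of one evidence channel (e.g. Pearson
#' correlation of GI50 profiles, Jaccard index of positive bioassays, DICE
#' coefficient of atom-pair fingerprints). Undefined pairs -- pairs where the
#' score cannot be computed, such as profiles with fewer than three jointly
#' observed conditions or bioassay pairs never tested in a common assay --
#' are stored as \code{NA} ("masked"), never coerced to 0: a score of 0 is a
#' meaningful observation, absence of a score is not.
#'
#' @slot channel single string naming the data type.
#' @slot scores numeric matrix, symmetric, with drug IDs as dimnames;
#'   \code{NA} entries are masked pairs.
#' @slot range numeric(2), the defined score range of the channel
#'   (\code{c(-1, 1)} for correlations, \code{c(0, 1)} for Jaccard/DICE).
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(channel = "character", scores = "matrix", range = "numeric"))

setValidity("SimilarityMatrix", function(object) {
  s <- object@scores
  if (length(object@channel) != 1L || !nzchar(object@channel))
    return("'channel' must be a single non-empty string")
  if (length(object@range) != 2L || object@range[1] >= object@range[2])
    return("'range' must be c(lo, hi) with lo < hi")
  if (nrow(s) != ncol(s)) return("'scores' must be square")
  ids <- rownames(s)
  if (is.null(ids) || is.null(colnames(s)) || !identical(ids, colnames(s)))
    return("'scores' must have identical row and column drug IDs")
  if (anyDuplicated(ids)) return("drug IDs must be unique")
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-12, check.attributes = FALSE)) &&
      !identical(is.na(s), is.na(t(s))))
    return("'scores' must be symmetric (including the mask)")
  v <- s[!is.na(s)]
  tol <- 1e-8 * diff(object@range)
  if (length(v) && (min(v) < object@range[1] - tol || max(v) > object@range[2] + tol))
    return("defined scores fall outside the declared range")
  TRUE
})

#' Per-data-type likelihood-ratio model
#'
#' For one similarity channel, the result of binning labeled similarity
#' scores into evenly spaced intervals over the channel's score range,
#' forming per-bin likelihood ratios
#' \deqn{\hat L_b = \frac{(ST_b+\alpha)/(N_{ST}+\alpha B)}
#'                       {(nonST_b+\alpha)/(N_{nonST}+\alpha B)}}
#' and fitting an exponential curve \eqn{L(s) = a e^{b s}} through the bin
#' centers (least squares on \eqn{\log \hat L_b}, weighted by bin occupancy).
#' The fitted curve, not the raw bin ratios, scores new pairs. The stored
#' median of all observed similarity scores of the channel is the imputation
#' value used when a pair lacks the channel.
#'
#' @slot channel data-type name.
#' @slot breaks numeric vector of bin edges (length nBins + 1, evenly spaced).
#' @slot ratios per-bin raw likelihood ratios \eqn{\hat L_b}.
#' @slot counts 2 x nBins integer matrix of ST / non-ST bin counts.
#' @slot coef named numeric \code{c(a=, b=)} of the exponential fit.
#' @slot median imputation median of all observed scores of this channel.
#' @slot alpha pseudocount applied to bin counts.
#' @slot range score range the bins span.
#' @exportClass LikelihoodModel
setClass("LikelihoodModel",
  representation(channel = "character", breaks = "numeric", ratios = "numeric",
                 counts = "matrix", coef = "numeric", median = "numeric",
                 alpha = "numeric", range = "numeric"))

setValidity("LikelihoodModel", function(object) {
  nb <- length(object@breaks) - 1L
  if (nb < 1L) return("need at least one bin")
  if (length(object@ratios) != nb) return("one ratio per bin required")
  d <- diff(object@breaks)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-8 * abs(d[1]))
    return("'breaks' must be strictly increasing and evenly spaced")
  if (!identical(sort(names(object@coef)), c("a", "b")))
    return("'coef' must be named c(a=, b=)")
  if (object@coef[["a"]] <= 0) return("fitted 'a' must be positive")
  if (length(object@median) != 1L || is.na(object@median) ||
      object@median < object@range[1] - 1e-8 || object@median > object@range[2] + 1e-8)
    return("imputation median must lie within the score range")
  if (object@alpha < 0) return("pseudocount must be >= 0")
  TRUE
})

#' Total-likelihood-ratio model: one LikelihoodModel per data type
#'
#' The fitted evidence-integration model. Under the naive Bayes assumption
#' of mutually independent channels (empirically supported by the near-zero
#' cross-channel correlation of similarity scores), the total likelihood
#' ratio of a drug pair is the product of the per-channel likelihood ratios,
#' with a channel's imputation-median likelihood substituted where the pair
#' lacks that channel.
#'
#' @slot models named list of \linkS4class{LikelihoodModel}, one per channel.
#' @slot version serialization format version string.
#' @exportClass TLRModel
setClass("TLRModel",
  representation(models = "list", version = "character"),
  prototype(version = "1"))

setValidity("TLRModel", function(object) {
  if (length(object@models) < 1L) return("need at least one channel model")
  ok <- vapply(object@models, is, logical(1), class2 = "LikelihoodModel")
  if (!all(ok)) return("all elements of 'models' must be LikelihoodModel")
  ch <- vapply(object@models, function(m) m@channel, character(1))
  if (is.null(names(object@models)) || !identical(unname(ch), names(object@models)))
    return("'models' must be named by their channels")
  TRUE
})

#' A generated synthetic drug universe with planted ground truth
#'
#' Drugs with planted protein-target assignments and five per-channel
#' feature tables in which shared-target pairs are stochastically more
#' similar than non-shared-target pairs, channels are generated from
#' independent latent target signatures (so cross-channel similarity
#' correlation is near zero), and a configurable fraction of drugs are
#' emitted as orphans: their features are present but their target
#' assignments are withheld from the public target table and kept only in
#' the truth slot.
#'
#' @slot drugIds character vector of drug identifiers.
#' @slot truth named list: full planted drug -> target-set assignment.
#' @slot targetTable named list: the public annotation (orphans withheld).
#' @slot orphans drug IDs whose annotation was withheld.
#' @slot channels named list of channel payloads (see
#'   \code{\link{generateUniverse}} for the payload structures).
#' @slot moa optional named character of planted sub-mechanism labels for
#'   drugs on the mechanism-split target (empty if the split is disabled).
#' @slot config the generating \code{\link{universeConfig}} list (seed included).
#' @exportClass SyntheticUniverse
setClass("SyntheticUniverse",
  representation(drugIds = "character", truth = "list", targetTable = "list",
                 orphans = "character", channels = "list", moa = "character",
                 config = "list"))

setValidity("SyntheticUniverse", function(object) {
  if (anyDuplicated(object@drugIds)) return("drug IDs must be unique")
  if (!all(names(object@truth) %in% object@drugIds))
    return("truth refers to unknown drugs")
  if (!all(object@orphans %in% object@drugIds))
    return("orphans must be drugs of the universe")
  if (any(object@orphans %in% names(object@targetTable)))
    return("orphan annotations must be withheld from the public table")
  TRUE
})

setMethod("show", "SimilarityMatrix", function(object) {
  n <- nrow(object@scores)
  nd <- sum(!is.na(object@scores[upper.tri(object@scores)]))
  cat(sprintf("SimilarityMatrix '%s': %d drugs, %d/%d defined pairs, range [%g, %g]\n",
              object@channel, n, nd, n * (n - 1L) / 2L,
              object@range[1], object@range[2]))
})

setMethod("show", "LikelihoodModel", function(object) {
  cat(sprintf(
    "LikelihoodModel '%s': %d bins on [%g, %g], L(s) = %.4g * exp(%.4g * s), median %.4g, alpha %g\n",
    object@channel, length(object@ratios), object@range[1], object@range[2],
    object@coef[["a"]], object@coef[["b"]], object@median, object@alpha))
})

setMethod("show", "TLRModel", function(object) {
  cat(sprintf("TLRModel with %d channel(s): %s\n",
              length(object@models), paste(names(object@models), collapse = ", ")))
  for (m in object@models) show(m)
})

setMethod("show", "SyntheticUniverse", function(object) {
  cat(sprintf(
    "SyntheticUniverse: %d drugs (%d orphans), %d targets, channels: %s (seed %s)\n",
    length(object@drugIds), length(object@orphans),
    length(unique(unlist(object@truth))),
    paste(names(object@channels), collapse = ", "),
    format(object@config$seed)))
})
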