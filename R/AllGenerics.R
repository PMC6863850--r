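#' Drug identifiers of an object
#' @param x a \linkS4class{SimilarityMatrix} or \linkS4class{SyntheticUniverse}.
#' @return character vector of drug IDs.
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname drugIds
#' @export
setMethod("drugIds", "SimilarityMatrix", function(x) rownames(x@scores))

#' @rdname drugIds
#' @export
setMethod("drugIds", "SyntheticUniverse", function(x) x@drugIds)

#' Channel (data-type) name(s) of an object
#' @param x a \linkS4class{SimilarityMatrix}, \linkS4class{LikelihoodModel}
#'   or \linkS4class{TLRModel}.
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "SimilarityMatrix", function(x) x@channel)

#' @rdname channelNames
#' @export
setMethod("channelNames", "LikelihoodModel", function(x) x@channel)

#' @rdname channelNames
#' @export
setMethod("channelNames", "TLRModel", function(x) names(x@models))

#' Similarity scores of a SimilarityMatrix
#' @param x a \linkS4class{SimilarityMatrix}.
#' @return the symmetric numeric score matrix (\code{NA} = masked pair).
#' @export
setGeneric("similarityScores", function(x) standardGeneric("similarityScores"))

#' @rdname similarityScores
#' @export
setMethod("similarityScores", "SimilarityMatrix", function(x) x@scores)

#' Score range of a similarity channel or likelihood model
#' @param x a \linkS4class{SimilarityMatrix} or \linkS4class{LikelihoodModel}.
#' @return numeric(2): the defined score range.
#' @export
setGeneric("scoreRange", function(x) standardGeneric("scoreRange"))

#' @rdname scoreRange
#' @export
setMethod("scoreRange", "SimilarityMatrix", function(x) x@range)

#' @rdname scoreRange
#' @export
setMethod("scoreRange", "LikelihoodModel", function(x) x@range)

#' Imputation median of a likelihood model
#' @param x a \linkS4class{LikelihoodModel} or \linkS4class{TLRModel}.
#' @return the stored median(s) of all observed similarity scores.
#' @export
setGeneric("imputationMedian", function(x) standardGeneric("imputationMedian"))

#' @rdname imputationMedian
#' @export
setMethod("imputationMedian", "LikelihoodModel", function(x) x@median)

#' @rdname imputationMedian
#' @export
setMethod("imputationMedian", "TLRModel",
  function(x) vapply(x@models, function(m) m@median, numeric(1)))

#' Per-channel models of a TLRModel
#' @param x a \linkS4class{TLRModel}.
#' @return named list of \linkS4class{LikelihoodModel}.
#' @export
setGeneric("channelModels", function(x) standardGeneric("channelModels"))

#' @rdname channelModels
#' @export
setMethod("channelModels", "TLRModel", function(x) x@models)

#' Evaluate a fitted likelihood curve at similarity score(s)
#'
#' Returns \eqn{a e^{b s}} from the model's exponential fit. Scores
#' marginally outside the channel range (floating-point noise) are clamped
#' to the boundary; scores beyond 5\% of the range span raise an error.
#'
#' @param model a \linkS4class{LikelihoodModel}.
#' @param s numeric vector of similarity scores.
#' @return positive numeric vector of likelihood ratios.
#' @export
setGeneric("likelihoodAt", function(model, s) standardGeneric("likelihoodAt"))

#' Public target annotation of a synthetic universe
#' @param x a \linkS4class{SyntheticUniverse}.
#' @param truth if \code{TRUE} return the full planted assignment including
#'   orphans, otherwise the public table with orphans withheld.
#' @return named list mapping drug ID to character vector of targets.
#' @export
setGeneric("targetTable", function(x, truth = FALSE) standardGeneric("targetTable"))

#' @rdname targetTable
#' @export
setMethod("targetTable", "SyntheticUniverse",
  function(x, truth = FALSE) if (truth) x@truth else x@targetTable)

#' Orphan drugs of a synthetic universe
#' @param x a \linkS4class{SyntheticUniverse}.
#' @return character vector of drug IDs whose annotation was withheld.
#' @export
setGeneric("orphanIds", function(x) standardGeneric("orphanIds"))

#' @rdname orphanIds
#' @export
setMethod("orphanIds", "SyntheticUniverse", function(x) x@orphans)
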