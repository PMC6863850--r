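#' Configuration of a synthetic drug universe
#'
#' Defines the statistical conditions under which the package is exercised:
#' drugs receive planted protein targets (one guaranteed target plus a
#' Poisson number of extras), and each of five evidence channels is
#' generated from channel-specific, mutually independent latent target
#' signatures so that (i) shared-target pairs are stochastically more
#' similar in every channel, with strength set by \code{signal}, and
#' (ii) similarity scores of different channels are uncorrelated.
#'
#' \code{signal} in [0, 1] scales each channel's latent-signature weight;
#' at 0 the channel is pure noise (shared-target pairs are
#' indistinguishable), at the default 0.8 each single channel is a
#' moderately informative classifier, in line with the modest per-channel
#' separations real heterogeneous drug data show. \code{missingness} is
#' the per-channel fraction of drugs lacking the channel entirely.
#'
#' @param nDrugs number of drugs (>= 2).
#' @param nTargets number of protein targets (>= 1).
#' @param extraTargetRate Poisson rate of extra targets per drug beyond
#'   the guaranteed one.
#' @param targetSkew Zipf exponent of target popularity: target t is drawn
#'   with probability proportional to \eqn{t^{-targetSkew}}. Real target
#'   annotation corpora are heavily imbalanced (a few promiscuous target
#'   classes, a long tail of rare targets); 0 gives uniform popularity.
#' @param orphanFraction fraction of drugs whose planted annotation is
#'   withheld from the public target table.
#' @param signal per-channel signal strength in [0, 1]; scalar or named
#'   vector over the channels.
#' @param missingness per-channel fraction of drugs with the channel
#'   missing; scalar or named vector.
#' @param nCellLines,nGenes profile dimensions of the \code{gi50} and
#'   \code{cmap} channels.
#' @param nAssays,nSideEffects vocabulary sizes of the binary channels.
#' @param nFpFeatures size of the structural fingerprint feature universe.
#' @param moaSplit if \code{TRUE}, the first target is planted with two
#'   sub-mechanisms: drugs on it are split into two groups whose latent
#'   signatures differ in every channel, while all of them still share the
#'   target.
#' @param seed integer seed; regeneration from the same config is
#'   bit-identical.
#' @return a validated config list of class \code{"universeConfig"}.
#' @export
universeConfig <- function(nDrugs = 300, nTargets = 50, extraTargetRate = 0.15,
                           targetSkew = 0.5, orphanFraction = 0.1, signal = 0.8,
                           missingness = 0.1, nCellLines = 60, nGenes = 300,
                           nAssays = 300, nSideEffects = 200,
                           nFpFeatures = 150, moaSplit = FALSE, seed = 1) {
  channels <- c("gi50", "cmap", "bioassay", "sideeffect", "structure")
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- structure(rep(x, length(channels)), names = channels)
    if (!all(channels %in% names(x)))
      stopf("'%s' must be a scalar or named over all channels", what)
    x <- x[channels]
    if (any(x < 0 | x > 1)) stopf("'%s' values must lie in [0, 1]", what)
    x
  }
  if (nDrugs < 2L) stopf("nDrugs must be >= 2")
  if (nTargets < 1L) stopf("nTargets must be >= 1")
  if (extraTargetRate < 0) stopf("extraTargetRate must be >= 0")
  if (targetSkew < 0) stopf("targetSkew must be >= 0")
  if (orphanFraction < 0 || orphanFraction > 1)
    stopf("orphanFraction must lie in [0, 1]")
  cfg <- list(nDrugs = as.integer(nDrugs), nTargets = as.integer(nTargets),
              extraTargetRate = extraTargetRate, targetSkew = targetSkew,
              orphanFraction = orphanFraction,
              signal = expand(signal, "signal"),
              missingness = expand(missingness, "missingness"),
              nCellLines = as.integer(nCellLines), nGenes = as.integer(nGenes),
              nAssays = as.integer(nAssays),
              nSideEffects = as.integer(nSideEffects),
              nFpFeatures = as.integer(nFpFeatures),
              moaSplit = isTRUE(moaSplit), seed = as.integer(seed),
              channels = channels)
  class(cfg) <- "universeConfig"
  cfg
}

# Latent drug signatures for a profile-like channel: each target owns an
# independent standard-normal signature; a drug mixes the signatures of its
# targets (variance-normalized); the mechanism-split target contributes a
# sub-mechanism-shifted signature instead.
profileChannel <- function(cfg, assign, moa, dim, signal, stream,
                           gain = 0.45) {
  withSeed(streamSeed(cfg$seed, stream), {
    Z <- matrix(stats::rnorm(cfg$nTargets * dim), cfg$nTargets, dim)
    O <- matrix(stats::rnorm(2 * dim), 2, dim)  # sub-mechanism offsets
    kappa <- min(gain * signal, 0.95)
    X <- matrix(NA_real_, cfg$nDrugs, dim,
                dimnames = list(names(assign),
                                paste0("c", seq_len(dim))))
    for (i in seq_len(cfg$nDrugs)) {
      tg <- assign[[i]]
      sig <- Z[tg, , drop = FALSE]
      d <- names(assign)[i]
      if (cfg$moaSplit && 1L %in% tg && d %in% names(moa)) {
        mech <- if (moa[[d]] == "A") 1L else 2L
        sig[match(1L, tg), ] <- (Z[1L, ] + 1.5 * O[mech, ]) / sqrt(1 + 1.5^2)
      }
      latent <- colSums(sig) / sqrt(nrow(sig))
      X[i, ] <- kappa * latent + sqrt(1 - kappa^2) * stats::rnorm(dim)
    }
    X
  })
}

# Latent feature sets for a binary channel. Each target owns a latent
# positive-feature set; each sub-mechanism of the split target owns a
# variant (a thinned copy of the base set plus mechanism-private extras).
# A drug keeps each latent feature of its targets with probability
# 0.8 * signal and adds background positives at a fixed low rate, so at
# signal 0 positives are pure background.
binaryChannel <- function(cfg, assign, moa, vocabSize, signal, stream,
                          pTarget = 0.12, background = 0.05,
                          gain = 0.32) {
  withSeed(streamSeed(cfg$seed, stream), {
    vocab <- sprintf("f%03d", seq_len(vocabSize))
    latentSize <- max(1L, round(pTarget * vocabSize))
    latent <- lapply(seq_len(cfg$nTargets), function(t)
      sample(vocab, latentSize))
    mechVariant <- lapply(1:2, function(m) {
      keep <- latent[[1L]][stats::runif(length(latent[[1L]])) < 0.5]
      extra <- sample(vocab, max(1L, round(0.75 * latentSize)))
      unique(c(keep, extra))
    })
    retention <- gain * signal
    positives <- lapply(seq_len(cfg$nDrugs), function(i) {
      tg <- assign[[i]]
      d <- names(assign)[i]
      feats <- unlist(lapply(tg, function(t) {
        if (cfg$moaSplit && t == 1L && d %in% names(moa))
          mechVariant[[if (moa[[d]] == "A") 1L else 2L]]
        else latent[[t]]
      }))
      feats <- unique(feats)
      # multi-target drugs sample from their combined repertoire at
      # single-target size, so set size does not encode target count
      if (length(tg) > 1L)
        feats <- feats[stats::runif(length(feats)) < 1 / length(tg)]
      kept <- feats[stats::runif(length(feats)) < retention]
      bg <- vocab[stats::runif(vocabSize) < background]
      sort(unique(c(kept, bg)))
    })
    names(positives) <- names(assign)
    list(positives = positives, vocabulary = vocab)
  })
}

# Structural channel generated directly as fingerprint count vectors:
# each target owns a sparse latent count template; drug fingerprints are
# binomially thinned template counts (retention 0.8 * signal) plus Poisson
# insertion noise. Generating actual molecules with controlled pairwise
# DICE is out of scope; real SMILES fixtures cover the SMILES path.
fingerprintChannel <- function(cfg, assign, moa, nFeatures, signal, stream,
                               density = 0.25, lambdaCount = 1.5,
                               lambdaNoise = 0.8, gain = 0.50) {
  withSeed(streamSeed(cfg$seed, stream), {
    tmpl <- matrix(0L, cfg$nTargets + 2L, nFeatures)  # +2 mechanism variants
    nOn <- max(1L, round(density * nFeatures))
    for (t in seq_len(nrow(tmpl))) {
      on <- sample.int(nFeatures, nOn)
      tmpl[t, on] <- 1L + stats::rpois(nOn, lambdaCount)
    }
    # mechanism variants share part of the base target-1 template
    for (m in 1:2) {
      base <- tmpl[1L, ]
      keep <- stats::runif(nFeatures) < 0.5
      tmpl[cfg$nTargets + m, ] <- ifelse(keep, base, tmpl[cfg$nTargets + m, ])
    }
    retention <- gain * signal
    C <- matrix(0, cfg$nDrugs, nFeatures,
                dimnames = list(names(assign),
                                sprintf("ap%03d", seq_len(nFeatures))))
    for (i in seq_len(cfg$nDrugs)) {
      tg <- assign[[i]]
      d <- names(assign)[i]
      rows <- vapply(tg, function(t) {
        if (cfg$moaSplit && t == 1L && d %in% names(moa))
          cfg$nTargets + (if (moa[[d]] == "A") 1L else 2L)
        else t
      }, integer(1))
      template <- round(colMeans(tmpl[rows, , drop = FALSE]))
      kept <- stats::rbinom(nFeatures, template, retention)
      C[i, ] <- kept + stats::rpois(nFeatures, lambdaNoise)
    }
    C
  })
}

#' Generate a synthetic drug universe with planted ground truth
#'
#' Draws target assignments (one guaranteed target plus
#' \code{rpois(extraTargetRate)} extras, uniformly without replacement),
#' selects orphans, optionally splits the first target into two planted
#' sub-mechanisms, and generates the five feature channels from
#' channel-independent latent target signatures (see
#' \code{\link{universeConfig}}). Channel payloads:
#' \describe{
#'   \item{gi50, cmap}{numeric drug x condition matrices (rows of missing
#'     drugs all-\code{NA}).}
#'   \item{bioassay}{list(positives, tested, vocabulary): tested sets are
#'     random assay subsets forced to contain the positives; missing drugs
#'     are absent from both lists.}
#'   \item{sideeffect}{list(positives, vocabulary): presence/absence over
#'     the full vocabulary; missing drugs absent.}
#'   \item{structure}{fingerprint count matrix (missing drugs all-\code{NA}).}
#' }
#' Each channel draws from its own seed stream, so regeneration from the
#' same config is bit-identical and channels are mutually independent.
#'
#' @param config a \code{\link{universeConfig}}.
#' @return a \linkS4class{SyntheticUniverse}.
#' @export
generateUniverse <- function(config) {
  stopifnot(inherits(config, "universeConfig"))
  cfg <- config
  ids <- sprintf("D%04d", seq_len(cfg$nDrugs))

  pop <- seq_len(cfg$nTargets)^(-cfg$targetSkew)
  pop <- pop / sum(pop)
  assign <- withSeed(streamSeed(cfg$seed, 1L), {
    lapply(seq_len(cfg$nDrugs), function(i) {
      k <- min(1L + stats::rpois(1L, cfg$extraTargetRate), cfg$nTargets)
      sort(sample.int(cfg$nTargets, k, prob = pop))
    })
  })
  names(assign) <- ids

  orphans <- withSeed(streamSeed(cfg$seed, 2L), {
    n <- floor(cfg$orphanFraction * cfg$nDrugs)
    if (n > 0) sort(sample(ids, n)) else character(0)
  })

  moa <- character(0)
  if (cfg$moaSplit) {
    onSplit <- ids[vapply(assign, function(tg) 1L %in% tg, logical(1))]
    moa <- withSeed(streamSeed(cfg$seed, 3L), {
      structure(sample(rep_len(c("A", "B"), length(onSplit))),
                names = onSplit)
    })
  }

  tname <- sprintf("T%02d", seq_len(cfg$nTargets))
  truth <- lapply(assign, function(tg) tname[tg])

  ch <- list(
    gi50 = profileChannel(cfg, assign, moa, cfg$nCellLines,
                          cfg$signal[["gi50"]], 10L, gain = 0.55),
    cmap = profileChannel(cfg, assign, moa, cfg$nGenes,
                          cfg$signal[["cmap"]], 11L, gain = 0.15),
    bioassay = binaryChannel(cfg, assign, moa, cfg$nAssays,
                             cfg$signal[["bioassay"]], 12L, gain = 0.40),
    sideeffect = binaryChannel(cfg, assign, moa, cfg$nSideEffects,
                               cfg$signal[["sideeffect"]], 13L, gain = 0.16),
    structure = fingerprintChannel(cfg, assign, moa, cfg$nFpFeatures,
                                   cfg$signal[["structure"]], 14L))

  # bioassay tested sets: random subsets forced to contain the positives
  ch$bioassay$tested <- withSeed(streamSeed(cfg$seed, 15L), {
    lapply(ch$bioassay$positives, function(pos) {
      t <- ch$bioassay$vocabulary[
        stats::runif(length(ch$bioassay$vocabulary)) < 0.7]
      sort(unique(c(t, pos)))
    })
  })

  # per-channel drug-level missingness
  miss <- withSeed(streamSeed(cfg$seed, 16L), {
    lapply(cfg$channels, function(chn)
      ids[stats::runif(cfg$nDrugs) < cfg$missingness[[chn]]])
  })
  names(miss) <- cfg$channels
  for (chn in c("gi50", "cmap", "structure"))
    ch[[chn]][miss[[chn]], ] <- NA_real_
  for (chn in c("bioassay", "sideeffect")) {
    keep <- setdiff(ids, miss[[chn]])
    ch[[chn]]$positives <- ch[[chn]]$positives[keep]
    if (!is.null(ch[[chn]]$tested)) ch[[chn]]$tested <- ch[[chn]]$tested[keep]
  }

  public <- truth[setdiff(ids, orphans)]
  new("SyntheticUniverse", drugIds = ids, truth = truth,
      targetTable = public, orphans = orphans, channels = ch, moa = moa,
      config = unclass(cfg))
}

#' Pair labels from the planted ground truth
#'
#' Labels every unordered drug pair from the full planted assignment,
#' including orphans -- the scoring reference for voting and prediction.
#'
#' @param universe a \linkS4class{SyntheticUniverse}.
#' @return data.frame(a, b, st), as \code{\link{labelPairs}}.
#' @export
plantedPairLabels <- function(universe) {
  labelPairs(universe@drugIds, universe@truth)
}

#' Similarity matrices of all channels of a synthetic universe
#' @param universe a \linkS4class{SyntheticUniverse}.
#' @param channels channels to compute (default: all five).
#' @return named list of \linkS4class{SimilarityMatrix}.
#' @export
universeSimilarities <- function(universe, channels = names(universe@channels)) {
  out <- lapply(channels, function(chn) {
    p <- universe@channels[[chn]]
    type <- switch(chn, gi50 = , cmap = "profile",
                   bioassay = , sideeffect = "binary",
                   structure = "fingerprint")
    buildSimilarityMatrix(p, chn, type = type)
  })
  names(out) <- channels
  out
}

#' Reference molecules with hand-verifiable atom-pair fingerprints
#'
#' Small molecules used by the structural unit tests: alkanes whose
#' fingerprints are enumerable by hand, plus an aromatic pair and a
#' heteroatom case.
#'
#' @return data.frame with columns \code{name} and \code{smiles}.
#' @export
structureFixtureSet <- function() {
  data.frame(
    name = c("methane", "ethane", "propane", "butane", "benzene",
             "toluene", "ethanol"),
    smiles = c("C", "CC", "CCC", "CCCC", "c1ccccc1", "Cc1ccccc1", "CCO"))
}

#' Write a synthetic universe in the package's on-disk formats
#'
#' Emits \code{targets.tsv} (public annotation), \code{gi50.csv},
#' \code{cmap.csv}, \code{bioassay.tsv}, \code{sideeffect.tsv},
#' \code{structure_fp.csv}, a \code{truth/} directory with the full
#' planted labels (and sub-mechanism labels when planted) and
#' \code{config.json}, so the whole pipeline can run from files.
#'
#' @param universe a \linkS4class{SyntheticUniverse}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeUniverse <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  writeTargetTable(universe@targetTable, file.path(dir, "targets.tsv"))
  writeTargetTable(universe@truth, file.path(dir, "truth", "targets_truth.tsv"))
  writeProfileMatrix(universe@channels$gi50, file.path(dir, "gi50.csv"))
  writeProfileMatrix(universe@channels$cmap, file.path(dir, "cmap.csv"))
  writeBinaryTable(universe@channels$bioassay, file.path(dir, "bioassay.tsv"),
                   mode = "bioassay")
  writeBinaryTable(universe@channels$sideeffect,
                   file.path(dir, "sideeffect.tsv"), mode = "presence")
  writeProfileMatrix(universe@channels$structure,
                     file.path(dir, "structure_fp.csv"))
  if (length(universe@moa))
    utils::write.table(
      data.frame(drug_id = names(universe@moa), mechanism = universe@moa),
      file.path(dir, "truth", "moa.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  writeLines(jsonlite::toJSON(universe@config, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "config.json"))
  invisible(dir)
}
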