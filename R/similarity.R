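#' Pearson correlation of two numeric profiles with missingness
#'
#' Correlation over the jointly observed conditions. Undefined -- returned
#' as \code{NA}, never 0 -- when fewer than 3 conditions are jointly
#' observed or either restricted profile is constant.
#'
#' @param x,y numeric vectors of equal length; \code{NA} = missing.
#' @return correlation in \eqn{[-1, 1]}, or \code{NA} if undefined.
#' @export
profilePearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' Jaccard index of two binary feature sets
#'
#' \eqn{|P_a \cap P_b| / |P_a \cup P_b|} over positive features. In
#' co-tested mode (bioassays) the score is undefined unless the two drugs
#' were tested in at least one common assay. An empty union is undefined,
#' not 0.
#'
#' @param posA,posB character vectors of positive features.
#' @param testedA,testedB character vectors of tested features (ignored
#'   unless \code{requireCotested}).
#' @param requireCotested logical; demand \eqn{|T_a \cap T_b| \ge 1}.
#' @return score in \eqn{[0, 1]} or \code{NA} if undefined.
#' @export
binaryJaccard <- function(posA, posB, testedA = NULL, testedB = NULL,
                          requireCotested = FALSE) {
  if (requireCotested && !length(intersect(testedA, testedB)))
    return(NA_real_)
  u <- length(union(posA, posB))
  if (u == 0L) return(NA_real_)
  length(intersect(posA, posB)) / u
}

# A SMILES is accepted when its parentheses/brackets balance and OpenBabel
# can canonicalize it. The explicit balance check matters because OpenBabel
# silently "repairs" an unclosed branch like "C(".
smilesIsValid <- function(smiles) {
  ch <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (sum(ch == "(") != sum(ch == ")") || sum(ch == "[") != sum(ch == "]"))
    return(FALSE)
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\tmol\n")),
    error = function(e) "")
  nzchar(trimws(out))
}

# number of atoms from the V2000 counts line of a parsed molecule
sdfAtomCount <- function(mol) {
  cl <- ChemmineR::header(mol)[["Counts_Line"]]
  suppressWarnings(as.integer(substr(cl, 1, 3)))
}

# Atom descriptor used by the atom-pair fingerprint:
# element : heavy-neighbor count : aromatic flag (0/1). Hydrogens are
# excluded from atoms, neighbor counts and paths.
atomDescriptors <- function(elements, adjacency, aromaticAtom) {
  paste(elements, rowSums(adjacency), as.integer(aromaticAtom), sep = ":")
}

#' Atom-pair fingerprint of a molecule from its SMILES
#'
#' One feature per unordered pair of heavy atoms, keyed by the two atom
#' descriptors (element, heavy-neighbor count, aromatic flag; order
#' independent) and the shortest topological bond-path length between the
#' atoms (uncapped). Feature counts accumulate over atom pairs. A molecule
#' with fewer than two heavy atoms has a legal empty fingerprint; atoms in
#' different disconnected components contribute no feature.
#'
#' @param smiles a single SMILES string.
#' @return named integer vector of feature counts; names have the form
#'   \code{"<desc_i>|<desc_j>|<pathlen>"} with \code{desc_i <= desc_j}.
#' @export
smilesToAtomPairFP <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!smilesIsValid(smiles)) stopf("unparseable SMILES: '%s'", smiles)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(structure(smiles, names = "mol"))),
    error = function(e) NULL)
  if (is.null(sdf)) stopf("unparseable SMILES: '%s'", smiles)
  mol <- sdf[[1]]
  if (is.na(sdfAtomCount(mol)) || sdfAtomCount(mol) < 2L)
    return(emptyFingerprint())   # single-atom molecules have no atom pair
  ab <- ChemmineR::atomblock(mol)
  atomNames <- rownames(ab)
  nAtoms <- nrow(ab)
  if (is.null(atomNames) || nAtoms < 2L) return(emptyFingerprint())
  elements <- sub("_\\d+$", "", atomNames)
  heavy <- elements != "H"
  if (sum(heavy) < 2L) return(emptyFingerprint())

  bb <- ChemmineR::bondblock(mol)
  edges <- if (is.matrix(bb) && nrow(bb) >= 1L && ncol(bb) >= 2L) {
    e <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
    e[e[, 1L] >= 1L & e[, 2L] >= 1L & e[, 1L] <= nAtoms & e[, 2L] <= nAtoms, ,
      drop = FALSE]
  } else matrix(integer(0), 0, 2)

  # aromatic atoms = members of any ring perceived as aromatic
  aromAtoms <- character(0)
  ringInfo <- tryCatch(
    suppressWarnings(ChemmineR::rings(mol, type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (!is.null(ringInfo) && length(ringInfo$RINGS))
    aromAtoms <- unique(unlist(ringInfo$RINGS[ringInfo$AROMATIC]))

  hIdx <- which(heavy)
  remap <- match(seq_len(nAtoms), hIdx)
  keep <- heavy[edges[, 1L]] & heavy[edges[, 2L]]
  e2 <- cbind(remap[edges[keep, 1L]], remap[edges[keep, 2L]])
  nH <- length(hIdx)
  adj <- matrix(0L, nH, nH)
  if (nrow(e2)) {
    adj[e2] <- 1L
    adj[e2[, c(2, 1), drop = FALSE]] <- 1L
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  desc <- atomDescriptors(elements[hIdx], adj,
                          atomNames[hIdx] %in% aromAtoms)

  pr <- pairIndices(nH)
  plen <- d[pr]
  ok <- is.finite(plen) & plen >= 1
  if (!any(ok)) return(emptyFingerprint())
  di <- desc[pr[ok, 1L]]; dj <- desc[pr[ok, 2L]]
  lo <- pmin(di, dj); hi <- pmax(di, dj)
  keys <- paste(lo, hi, as.integer(plen[ok]), sep = "|")
  tab <- table(keys)
  structure(as.integer(tab), names = names(tab))
}

emptyFingerprint <- function() structure(integer(0), names = character(0))

#' DICE similarity of two count fingerprints
#'
#' \deqn{2 \sum_k \min(c_a(k), c_b(k)) \; / \; (\sum_k c_a(k) + \sum_k c_b(k))}
#' Both fingerprints empty is undefined (\code{NA}); one empty, one not is 0.
#'
#' @param fa,fb named numeric count vectors (as from
#'   \code{\link{smilesToAtomPairFP}}) or plain count vectors over a shared
#'   feature universe.
#' @return score in \eqn{[0, 1]} or \code{NA}.
#' @export
diceSimilarity <- function(fa, fb) {
  ta <- sum(fa); tb <- sum(fb)
  if (ta + tb == 0) return(NA_real_)
  if (!is.null(names(fa)) || !is.null(names(fb))) {
    shared <- intersect(names(fa), names(fb))
    smin <- if (length(shared)) sum(pmin(fa[shared], fb[shared])) else 0
  } else {
    stopifnot(length(fa) == length(fb))
    smin <- sum(pmin(fa, fb))
  }
  2 * smin / (ta + tb)
}

#' Build the pairwise similarity matrix of one data type
#'
#' Dispatches on the payload type to the per-pair score definitions:
#' \describe{
#'   \item{profile}{numeric matrix (drugs x conditions, \code{NA} allowed):
#'     Pearson correlation over pairwise-complete conditions; pairs with
#'     fewer than 3 shared observations or a constant restricted profile
#'     are masked. Range \eqn{[-1, 1]}.}
#'   \item{binary}{list with \code{positives} (named list), optional
#'     \code{tested} (named list; \code{NULL} = full-vocabulary testing)
#'     and \code{vocabulary}: Jaccard index of positives, masked where the
#'     union is empty or (when \code{tested} is given) no assay is
#'     co-tested. Range \eqn{[0, 1]}.}
#'   \item{fingerprint}{count matrix (drugs x features, an all-\code{NA}
#'     row = drug lacks the channel) or named list of named count vectors:
#'     DICE coefficient; masked when both fingerprints are empty or either
#'     drug lacks the channel. Range \eqn{[0, 1]}.}
#'   \item{smiles}{named character vector of SMILES: converted via
#'     \code{\link{smilesToAtomPairFP}}, then as \code{fingerprint}.}
#' }
#'
#' @param payload channel data in one of the forms above.
#' @param channel channel name to attach to the result.
#' @param type payload type: \code{"profile"}, \code{"binary"},
#'   \code{"fingerprint"} or \code{"smiles"}.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
buildSimilarityMatrix <- function(payload, channel,
                                  type = c("profile", "binary", "fingerprint",
                                           "smiles")) {
  type <- match.arg(type)
  switch(type,
    profile = profileSimilarityMatrix(payload, channel),
    binary = binarySimilarityMatrix(payload, channel),
    fingerprint = fingerprintSimilarityMatrix(payload, channel),
    smiles = {
      fps <- lapply(payload, smilesToAtomPairFP)
      names(fps) <- names(payload)
      fingerprintSimilarityMatrix(fps, channel)
    })
}

profileSimilarityMatrix <- function(m, channel) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (nrow(m) < 2L) stopf("need at least 2 drugs with the '%s' channel", channel)
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  obs <- (!is.na(m)) * 1
  shared <- tcrossprod(obs)
  r[shared < 3] <- NA
  r[r > 1] <- 1; r[r < -1] <- -1   # guard float noise
  dimnames(r) <- list(rownames(m), rownames(m))
  new("SimilarityMatrix", channel = channel, scores = r, range = c(-1, 1))
}

binarySimilarityMatrix <- function(payload, channel) {
  stopifnot(is.list(payload), !is.null(payload$positives))
  ids <- names(payload$positives)
  if (length(ids) < 2L) stopf("need at least 2 drugs with the '%s' channel", channel)
  vocab <- payload$vocabulary
  if (is.null(vocab))
    vocab <- sort(unique(c(unlist(payload$positives), unlist(payload$tested))))
  P <- matrix(0, length(ids), length(vocab), dimnames = list(ids, vocab))
  for (d in ids) P[d, intersect(payload$positives[[d]], vocab)] <- 1
  inter <- tcrossprod(P)
  sizes <- rowSums(P)
  un <- outer(sizes, sizes, "+") - inter
  j <- ifelse(un > 0, inter / un, NA_real_)
  if (!is.null(payload$tested)) {
    Tm <- matrix(0, length(ids), length(vocab), dimnames = list(ids, vocab))
    for (d in ids) Tm[d, intersect(payload$tested[[d]], vocab)] <- 1
    cot <- tcrossprod(Tm)
    j[cot < 1] <- NA_real_
  }
  dimnames(j) <- list(ids, ids)
  new("SimilarityMatrix", channel = channel, scores = j, range = c(0, 1))
}

fingerprintSimilarityMatrix <- function(payload, channel) {
  if (is.list(payload)) {
    ids <- names(payload)
    feats <- sort(unique(unlist(lapply(payload, names))))
    C <- matrix(0, length(ids), max(length(feats), 1L),
                dimnames = list(ids, if (length(feats)) feats else "f0"))
    for (d in ids) {
      fp <- payload[[d]]
      if (length(fp)) C[d, names(fp)] <- as.numeric(fp)
    }
  } else {
    stopifnot(is.matrix(payload), !is.null(rownames(payload)))
    C <- payload
    ids <- rownames(C)
  }
  if (length(ids) < 2L) stopf("need at least 2 drugs with the '%s' channel", channel)
  n <- nrow(C)
  miss <- apply(C, 1L, function(r) all(is.na(r)))
  C0 <- C; C0[is.na(C0)] <- 0
  tot <- rowSums(C0)
  D <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (miss[i]) next
    smin <- colSums(pmin(t(C0), C0[i, ]))
    denom <- tot[i] + tot
    D[i, ] <- ifelse(denom > 0, 2 * smin / denom, NA_real_)
  }
  D[miss, ] <- NA_real_
  D[, miss] <- NA_real_
  new("SimilarityMatrix", channel = channel, scores = D, range = c(0, 1))
}
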