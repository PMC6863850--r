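#' Convert a TLR into a mechanism-space distance
#'
#' The distance between two drugs is the reciprocal of their total
#' likelihood ratio: strongly predicted shared-target pairs are close.
#'
#' @param tlr positive numeric TLR(s).
#' @return \code{1 / tlr}.
#' @export
tlrToDistance <- function(tlr) {
  if (any(is.na(tlr)) || any(tlr <= 0)) stopf("TLR must be > 0")
  1 / tlr
}

#' Full 1/TLR distance matrix over a drug set
#'
#' Builds the symmetric distance matrix required by the clustering and
#' embedding steps. Any requested pair missing from the TLR results is a
#' hard error naming the pairs -- silently imputing distances would
#' fabricate mechanism structure; restrict the drug set to drugs with
#' computable TLRs instead.
#'
#' @param tlr data.frame(a, b, tlr) as from \code{\link{pairTLR}}.
#' @param drugs drug IDs to include (default: all drugs in \code{tlr}).
#' @return symmetric numeric matrix of \code{1/TLR} distances, zero
#'   diagonal.
#' @export
tlrDistanceMatrix <- function(tlr, drugs = NULL) {
  if (is.null(drugs)) drugs <- sort(unique(c(tlr$a, tlr$b)))
  drugs <- sort(drugs)
  n <- length(drugs)
  if (n < 2L) stopf("need at least 2 drugs")
  D <- matrix(NA_real_, n, n, dimnames = list(drugs, drugs))
  sel <- tlr$a %in% drugs & tlr$b %in% drugs
  ia <- match(tlr$a[sel], drugs); ib <- match(tlr$b[sel], drugs)
  d <- tlrToDistance(tlr$tlr[sel])
  D[cbind(ia, ib)] <- d
  D[cbind(ib, ia)] <- d
  diag(D) <- 0
  if (anyNA(D)) {
    miss <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stopf("missing TLR for pair(s): %s",
          paste(drugs[miss[, 1]], drugs[miss[, 2]], sep = "~",
                collapse = ", "))
  }
  D
}

#' Average-linkage mechanism-of-action dendrogram
#'
#' Agglomerative (UPGMA-style) clustering of a complete 1/TLR distance
#' matrix. Drugs are ordered lexically before clustering so that equal
#' merge heights resolve deterministically.
#'
#' @param distances complete symmetric distance matrix (e.g. from
#'   \code{\link{tlrDistanceMatrix}}) or a \code{dist}.
#' @param linkage only \code{"average"} is supported.
#' @return an \code{hclust} object.
#' @export
moaDendrogram <- function(distances, linkage = "average") {
  linkage <- match.arg(linkage, "average")
  if (is.matrix(distances)) {
    if (anyNA(distances)) {
      miss <- which(is.na(distances) & upper.tri(distances), arr.ind = TRUE)
      stopf("incomplete distance matrix; missing pair(s): %s",
            paste(rownames(distances)[miss[, 1]],
                  colnames(distances)[miss[, 2]], sep = "~", collapse = ", "))
    }
    ord <- order(rownames(distances))
    distances <- stats::as.dist(distances[ord, ord])
  }
  if (anyNA(distances)) stopf("incomplete distance matrix")
  stats::hclust(distances, method = linkage)
}

#' Export a dendrogram as Newick with branch lengths
#' @param hc an \code{hclust} object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Shared-target network from pairwise TLRs
#'
#' Nodes are drugs (flagged known/orphan from the target table, with
#' optional annotations such as first-level ATC codes); edges are predicted
#' shared-target interactions, i.e. pairs with TLR >= cutoff, weighted by
#' the TLR. An orphan node is retained only if it has at least
#' \code{minKnownEdges} qualifying edges to annotated drugs; annotated
#' nodes are retained whenever they have a qualifying edge. No self-edges.
#'
#' @param tlr data.frame(a, b, tlr).
#' @param targets named list of known targets per drug (defines
#'   known/orphan status).
#' @param cutoff TLR threshold for an edge (default 500).
#' @param minKnownEdges minimum qualifying edges to annotated drugs for an
#'   orphan to enter the network (default 2).
#' @param annotations optional data.frame with a \code{drug_id} column and
#'   extra node attribute columns (e.g. \code{atc_code}).
#' @return an \code{igraph} graph with node attributes \code{is_orphan}
#'   (plus any annotation columns) and edge attribute \code{tlr}; possibly
#'   empty.
#' @export
sharedTargetNetwork <- function(tlr, targets, cutoff = 500,
                                minKnownEdges = 2, annotations = NULL) {
  stopifnot(cutoff > 0)
  e <- tlr[tlr$tlr >= cutoff & tlr$a != tlr$b, , drop = FALSE]
  annotated <- names(targets)[lengths(targets) > 0]
  known <- function(d) d %in% annotated
  nodes <- unique(c(e$a, e$b))
  orphan <- !known(nodes)
  knownEdgeCount <- vapply(nodes, function(d) {
    sum((e$a == d & known(e$b)) | (e$b == d & known(e$a)))
  }, integer(1))
  keep <- ifelse(orphan, knownEdgeCount >= minKnownEdges, TRUE)
  nodes <- nodes[keep]
  e <- e[e$a %in% nodes & e$b %in% nodes, , drop = FALSE]
  nodes <- sort(nodes)
  vdf <- data.frame(name = nodes, is_orphan = !known(nodes))
  if (!is.null(annotations)) {
    m <- match(nodes, annotations$drug_id)
    for (col in setdiff(colnames(annotations), "drug_id"))
      vdf[[col]] <- annotations[[col]][m]
  }
  igraph::graph_from_data_frame(
    data.frame(from = e$a, to = e$b, tlr = e$tlr),
    directed = FALSE, vertices = vdf)
}

#' Write a network as GraphML
#' @param graph an \code{igraph} graph.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGraphML <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Classical MDS embedding of the drug universe
#'
#' Torgerson (classical) multidimensional scaling of the 1/TLR distance
#' matrix, with the eigenvalue spectrum reported.
#'
#' @param distances complete symmetric distance matrix.
#' @param dims embedding dimension (default 2).
#' @return list with \code{points} (drugs x dims coordinate matrix) and
#'   \code{eig} (eigenvalues).
#' @export
universeMds <- function(distances, dims = 2) {
  if (anyNA(distances)) stopf("incomplete distance matrix")
  fit <- stats::cmdscale(stats::as.dist(distances), k = dims, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dims) {  # degenerate configurations can drop dimensions
    pad <- matrix(0, nrow(pts), dims - ncol(pts))
    pts <- cbind(pts, pad)
    rownames(pts) <- rownames(fit$points)
  }
  list(points = pts, eig = fit$eig)
}
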