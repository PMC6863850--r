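# Independent brute-force oracles used to check the package's closed-form
# implementations. These deliberately re-derive each quantity from first
# principles and never call the code path they verify.

brutePearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

bruteAuroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  conc <- 0
  for (p in pos) for (n in neg)
    conc <- conc + (p > n) + 0.5 * (p == n)
  conc / (length(pos) * length(neg))
}

bruteKsD <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# Naive UPGMA agglomeration returning the cophenetic distance matrix:
# repeatedly merge the two clusters with the smallest mean pairwise
# original distance.
bruteUpgmaCophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  cop <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(Inf, 0L, 0L)
    for (i in 2:length(clusters)) for (j in 1:(i - 1L)) {
      dd <- mean(D[clusters[[i]], clusters[[j]]])
      if (dd < best[1]) best <- c(dd, j, i)
    }
    i <- best[3]; j <- best[2]
    cop[clusters[[i]], clusters[[j]]] <- best[1]
    cop[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    clusters[[i]] <- NULL
  }
  dimnames(cop) <- dimnames(D)
  cop
}

# Exact shared-target probability for single-target uniform assignment.
bruteSTProbSingleTarget <- function(nTargets) 1 / nTargets
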