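#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded package internals never perturb user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @export
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream seed below 2^31 from a base seed and a stream index, so
# each synthetic channel draws from its own reproducible stream.
streamSeed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

# Canonical unordered-pair enumeration of n items: upper triangle in
# column-major order, matching M[upper.tri(M)] for an n x n matrix M.
pairIndices <- function(n) {
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = idx[, 1L], j = idx[, 2L])
}

# Upper-triangle vector of a symmetric matrix, canonical pair order.
pairVector <- function(m) m[upper.tri(m)]

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
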