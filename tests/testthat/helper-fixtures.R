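# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# The reference five-channel universe at default study conditions.
defaultUniverse <- function() {
  cachedFixture("universe", generateUniverse(universeConfig(seed = 42)))
}

# A 200-drug universe for the channel-integration benchmarks.
evalUniverse <- function() {
  cachedFixture("evalUniverse",
    generateUniverse(universeConfig(nDrugs = 200, seed = 42)))
}

evalSims <- function() {
  cachedFixture("evalSims", universeSimilarities(evalUniverse()))
}

evalCV <- function() {
  cachedFixture("evalCV",
    cvTLR(evalSims(), targetTable(evalUniverse()), k = 5, seed = 7))
}

defaultSims <- function() {
  cachedFixture("sims", universeSimilarities(defaultUniverse()))
}

defaultCV <- function() {
  cachedFixture("cv",
    cvTLR(defaultSims(), targetTable(defaultUniverse()), k = 5, seed = 7))
}

defaultModel <- function() {
  cachedFixture("model",
    fitTLRModel(defaultSims(), targetTable(defaultUniverse())))
}

defaultPairTLR <- function() {
  cachedFixture("pairtlr", pairTLR(defaultModel(), defaultSims()))
}

# Mechanism-split universe: two planted sub-mechanisms on one shared target
# among eight targets, complete data.
moaUniverse <- function() {
  cachedFixture("moaUniverse", generateUniverse(universeConfig(
    nDrugs = 80, nTargets = 8, extraTargetRate = 0, targetSkew = 0,
    orphanFraction = 0, missingness = 0, moaSplit = TRUE, seed = 11)))
}

moaSims <- function() {
  cachedFixture("moaSims", universeSimilarities(moaUniverse()))
}

# A tiny hand-built single-channel problem where every drug's strongest
# partner shares its only target: 6 drugs, 3 targets, within-target
# similarity ~0.9, cross-target ~0.1.
toySims <- function() {
  cachedFixture("toy", {
    ids <- paste0("d", 1:6)
    tg <- list(d1 = "T1", d2 = "T1", d3 = "T2", d4 = "T2",
               d5 = "T3", d6 = "T3")
    s <- matrix(0.1, 6, 6, dimnames = list(ids, ids))
    same <- rbind(c(1, 2), c(3, 4), c(5, 6))
    s[same] <- 0.9; s[same[, c(2, 1)]] <- 0.9
    diag(s) <- 1
    jit <- matrix(0, 6, 6)
    jit[upper.tri(jit)] <- seq(0, 0.01, length.out = 15)
    jit <- jit + t(jit)
    sim <- new("SimilarityMatrix", channel = "structure",
               scores = pmin(s + jit, 1), range = c(0, 1))
    list(sims = list(structure = sim), targets = tg)
  })
}
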