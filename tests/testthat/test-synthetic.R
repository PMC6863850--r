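test_that("universe generation is bit-identical under a fixed config", {
  cfg <- universeConfig(nDrugs = 50, nTargets = 5, seed = 7)
  u1 <- generateUniverse(cfg)
  u2 <- generateUniverse(cfg)
  expect_identical(u1@truth, u2@truth)
  expect_identical(u1@orphans, u2@orphans)
  expect_identical(u1@channels, u2@channels)
  u3 <- generateUniverse(universeConfig(nDrugs = 50, nTargets = 5, seed = 8))
  expect_false(identical(u1@channels$gi50, u3@channels$gi50))
})

test_that("config validation rejects impossible settings", {
  expect_error(universeConfig(nDrugs = 1), "nDrugs")
  expect_error(universeConfig(nTargets = 0), "nTargets")
  expect_error(universeConfig(orphanFraction = 1.2), "orphanFraction")
  expect_error(universeConfig(signal = 2), "signal")
  expect_error(universeConfig(signal = c(gi50 = 0.5)), "named over all")
})

test_that("planted labels derive from the full truth, orphans included", {
  u <- defaultUniverse()
  lab <- plantedPairLabels(u)
  truth <- targetTable(u, truth = TRUE)
  expect_equal(nrow(lab), choose(length(drugIds(u)), 2))
  orph <- orphanIds(u)[1]
  inOrph <- lab[lab$a == orph | lab$b == orph, ]
  expect_gt(nrow(inOrph), 0)
  k <- sample(nrow(inOrph), 20)
  expect_identical(
    inOrph$st[k],
    vapply(k, function(i)
      length(intersect(truth[[inOrph$a[i]]], truth[[inOrph$b[i]]])) > 0,
      logical(1)))

  # a single-target universe forces every pair to share it
  u1 <- generateUniverse(universeConfig(nDrugs = 10, nTargets = 1, seed = 2))
  expect_true(all(plantedPairLabels(u1)$st))
})

test_that("the ST fraction matches the closed-form assignment expectation", {
  # single uniform target per drug: P(ST) = 1/nTargets, and the pair
  # indicators are pairwise uncorrelated, so the binomial s.e. applies
  u <- generateUniverse(universeConfig(nDrugs = 500, nTargets = 10,
                                       extraTargetRate = 0, targetSkew = 0,
                                       missingness = 0, seed = 13))
  lab <- plantedPairLabels(u)
  p <- bruteSTProbSingleTarget(10)
  se <- sqrt(p * (1 - p) / nrow(lab))
  expect_lt(abs(mean(lab$st) - p), 3 * se)
})

test_that("independently generated channels are mutually uncorrelated", {
  sims <- defaultSims()
  chs <- names(sims)
  for (i in 2:length(chs)) for (j in 1:(i - 1)) {
    cc <- crossTypeCorrelation(sims[[chs[i]]], sims[[chs[j]]])
    expect_lt(abs(cc$pcc), 0.1)
    expect_gt(cc$n, 1000)
  }
})

test_that("per-channel ST separation grows with the configured signal", {
  Ds <- vapply(c(0.2, 0.5, 0.8), function(sg) {
    u <- generateUniverse(universeConfig(nDrugs = 120, signal = sg,
                                         missingness = 0, seed = 29))
    sims <- universeSimilarities(u)
    lab <- plantedPairLabels(u)
    vapply(names(sims), function(ch) {
      sc <- similarityScores(sims[[ch]])[cbind(lab$a, lab$b)]
      ok <- !is.na(sc)
      ksSeparation(sc[ok & lab$st], sc[ok & !lab$st])$D
    }, numeric(1))
  }, numeric(5))
  for (ch in seq_len(5)) expect_true(all(diff(Ds[ch, ]) > 0))
})

test_that("every drug gets a planted target and channels separate classes", {
  u <- defaultUniverse()
  expect_true(all(lengths(targetTable(u, truth = TRUE)) >= 1))
  lab <- plantedPairLabels(u)
  sims <- defaultSims()
  for (ch in names(sims)) {
    sc <- DrugBayes:::lookupPairScores(sims[[ch]], lab$a, lab$b)
    ok <- !is.na(sc)
    expect_gt(ksSeparation(sc[ok & lab$st], sc[ok & !lab$st])$D, 0)
  }
})

test_that("orphan annotations are withheld but features are present", {
  u <- defaultUniverse()
  orph <- orphanIds(u)
  expect_false(any(orph %in% names(targetTable(u))))
  expect_true(all(orph %in% names(targetTable(u, truth = TRUE))))
  cov <- DrugBayes:::channelCoverage(defaultSims(), orph)
  expect_true(all(cov >= 1))
})

test_that("structure fixtures parse and carry known fingerprints", {
  fx <- structureFixtureSet()
  expect_true(all(c("methane", "ethane", "butane") %in% fx$name))
  fps <- lapply(fx$smiles, smilesToAtomPairFP)
  names(fps) <- fx$name
  expect_length(fps$methane, 0L)
  expect_length(fps$ethane, 1L)
  expect_true(all(vapply(fps[fx$name != "methane"], length,
                         integer(1)) > 0))
})

test_that("a written universe reloads into the same similarity structure", {
  u <- generateUniverse(universeConfig(nDrugs = 30, nTargets = 5,
                                       seed = 77))
  d <- withr::local_tempdir()
  writeUniverse(u, d)
  expect_true(all(file.exists(file.path(d, c(
    "targets.tsv", "gi50.csv", "cmap.csv", "bioassay.tsv",
    "sideeffect.tsv", "structure_fp.csv", "config.json",
    file.path("truth", "targets_truth.tsv"))))))
  back <- readUniverseDirectory(d)
  expect_identical(back$targets, targetTable(u))
  simsA <- universeSimilarities(u)
  simsB <- channelSimilarities(back$channels)
  for (ch in names(simsA)) {
    a <- similarityScores(simsA[[ch]])
    b <- similarityScores(simsB[[ch]])
    common <- intersect(rownames(a), rownames(b))
    expect_equal(a[common, common], b[common, common], tolerance = 1e-9)
  }
})
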