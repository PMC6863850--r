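test_that("profile Pearson matches the closed-form oracle and masks", {
  expect_equal(profilePearson(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(profilePearson(c(1, 2, 3), c(3, 2, 1)), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 10)
  expect_equal(profilePearson(x, y), brutePearson(x, y), tolerance = 1e-12)
  expect_equal(brutePearson(x, y), 14 / sqrt(250))

  # fewer than 3 shared observations or a constant profile -> masked, not 0
  expect_true(is.na(profilePearson(c(1, 2, NA), c(1, NA, 3))))
  expect_true(is.na(profilePearson(c(2, 2, 2), c(1, 5, 3))))
})

test_that("profile Pearson is invariant to positive affine transforms", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(profilePearson(a * x + b, y), profilePearson(x, y),
                 tolerance = 1e-10)
  }
})

test_that("binary Jaccard handles identity, disjoint sets and co-testing", {
  expect_equal(binaryJaccard(c("p1", "p2"), c("p1", "p2")), 1)
  expect_equal(binaryJaccard("p1", "p9"), 0)
  expect_equal(binaryJaccard(c("p1", "p2"), c("p2", "p3")), 1 / 3)
  expect_true(is.na(binaryJaccard(character(0), character(0))))
  # bioassay mode: no co-tested assay -> undefined
  expect_true(is.na(binaryJaccard("p1", "p1", testedA = "p1",
                                  testedB = "p2", requireCotested = TRUE)))
})

test_that("atom-pair fingerprints match hand enumeration", {
  expect_length(smilesToAtomPairFP("C"), 0L)          # no heavy-atom pair

  eth <- smilesToAtomPairFP("CC")
  expect_identical(eth, c("C:1:0|C:1:0|1" = 1L))

  prop <- smilesToAtomPairFP("CCC")
  expect_identical(prop[order(names(prop))],
                   c("C:1:0|C:1:0|2" = 1L, "C:1:0|C:2:0|1" = 2L))

  but <- smilesToAtomPairFP("CCCC")
  expect_identical(but[order(names(but))],
                   c("C:1:0|C:1:0|3" = 1L, "C:1:0|C:2:0|1" = 2L,
                     "C:1:0|C:2:0|2" = 2L, "C:2:0|C:2:0|1" = 1L))

  # benzene: six aromatic CH atoms, paths 1/2/3 around the ring
  benz <- smilesToAtomPairFP("c1ccccc1")
  expect_identical(benz[order(names(benz))],
                   c("C:2:1|C:2:1|1" = 6L, "C:2:1|C:2:1|2" = 6L,
                     "C:2:1|C:2:1|3" = 3L))

  expect_error(smilesToAtomPairFP("C("), "unparseable")
})

test_that("fingerprints are invariant to SMILES atom order", {
  pairs <- list(c("CCO", "OCC"), c("Cc1ccccc1", "c1ccc(C)cc1"),
                c("CCCC", "C(C)CC"))
  for (p in pairs) {
    f1 <- smilesToAtomPairFP(p[1]); f2 <- smilesToAtomPairFP(p[2])
    expect_identical(f1[order(names(f1))], f2[order(names(f2))])
  }
})

test_that("DICE similarity matches hand-derived values", {
  f <- smilesToAtomPairFP("CCO")
  expect_equal(diceSimilarity(f, f), 1)
  expect_equal(diceSimilarity(smilesToAtomPairFP("C"),
                              smilesToAtomPairFP("CC")), 0)
  expect_true(is.na(diceSimilarity(smilesToAtomPairFP("C"),
                                   smilesToAtomPairFP("O"))))
  # propane vs butane: sum-min 2 over totals 3 + 6
  expect_equal(diceSimilarity(smilesToAtomPairFP("CCC"),
                              smilesToAtomPairFP("CCCC")), 4 / 9)
})

test_that("set similarities shrink as the intersection is removed", {
  set.seed(8)
  for (i in 1:10) {
    a <- sample(paste0("p", 1:30), 12)
    b <- c(sample(a, 6), sample(setdiff(paste0("p", 1:30), a), 5))
    j0 <- binaryJaccard(a, b)
    shared <- intersect(a, b)
    for (k in seq_along(shared)) {
      jk <- binaryJaccard(a, setdiff(b, shared[1:k]))
      expect_lte(jk, j0 + 1e-12)
      j0 <- jk
    }
    ca <- structure(sample(1:4, 10, TRUE), names = paste0("k", 1:10))
    cb <- ca
    d0 <- diceSimilarity(ca, cb)
    expect_equal(d0, 1)
    for (k in 1:9) {
      cb2 <- cb[-seq_len(k)]
      dk <- diceSimilarity(ca, cb2)
      expect_lte(dk, d0 + 1e-12)
      d0 <- dk
    }
  }
})

test_that("similarity matrices are symmetric, in range and per-pair consistent", {
  u <- defaultUniverse()
  sims <- defaultSims()
  for (ch in names(sims)) {
    s <- similarityScores(sims[[ch]])
    expect_identical(is.na(s), is.na(t(s)))
    expect_equal(s, t(s), tolerance = 1e-12)
    v <- s[!is.na(s)]
    rng <- scoreRange(sims[[ch]])
    expect_gte(min(v), rng[1] - 1e-9)
    expect_lte(max(v), rng[2] + 1e-9)
  }

  # element-wise recomputation by the per-pair operations
  g <- u@channels$gi50
  sg <- similarityScores(sims$gi50)
  set.seed(2)
  ids <- rownames(g)
  for (k in 1:25) {
    ij <- sample(ids, 2)
    expect_equal(sg[ij[1], ij[2]],
                 profilePearson(g[ij[1], ], g[ij[2], ]),
                 tolerance = 1e-12)
  }
  ba <- u@channels$bioassay
  sb <- similarityScores(sims$bioassay)
  present <- names(ba$positives)
  for (k in 1:25) {
    ij <- sample(present, 2)
    expect_equal(sb[ij[1], ij[2]],
                 binaryJaccard(ba$positives[[ij[1]]], ba$positives[[ij[2]]],
                               ba$tested[[ij[1]]], ba$tested[[ij[2]]],
                               requireCotested = TRUE),
                 tolerance = 1e-12)
  }
  fp <- u@channels$structure
  sf <- similarityScores(sims$structure)
  ok <- ids[!apply(fp, 1, function(r) all(is.na(r)))]
  for (k in 1:25) {
    ij <- sample(ok, 2)
    expect_equal(sf[ij[1], ij[2]],
                 diceSimilarity(unname(fp[ij[1], ]), unname(fp[ij[2], ])),
                 tolerance = 1e-12)
  }
})

test_that("drugs lacking a channel are fully masked; unknown types error", {
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("d", 1:4), paste0("c", 1:5)))
  m[2, ] <- NA
  sim <- buildSimilarityMatrix(m, "gi50", type = "profile")
  s <- similarityScores(sim)
  expect_true(all(is.na(s["d2", ])))
  expect_true(all(!is.na(s[c("d1", "d3", "d4"), c("d1", "d3", "d4")])))
  expect_error(buildSimilarityMatrix(m, "gi50", type = "nope"))

  smi <- structure(c("CCC", "CCCC"), names = c("propane", "butane"))
  sim2 <- buildSimilarityMatrix(smi, "structure", type = "smiles")
  expect_equal(similarityScores(sim2)["propane", "butane"], 4 / 9)
})
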