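test_that("target table reader aggregates, deduplicates and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tT1", "A\tT2", "B\tT1"), f)
  tab <- readTargetTable(f)
  expect_identical(tab, list(A = c("T1", "T2"), B = "T1"))

  writeLines(c("drug_id\ttarget_id"), f)
  expect_length(readTargetTable(f), 0L)

  writeLines(c("A\tT1", "A\tT1", "B\tT2"), f)
  expect_message(tab <- readTargetTable(f), "deduplicated 1")
  expect_identical(tab$A, "T1")

  writeLines(c("A\tT1", "B"), f)
  expect_error(readTargetTable(f), "line 2")

  # round trip of an arbitrary table
  tab <- list(X = c("T3", "T1"), Y = "T9", Z = c("T1", "T2", "T5"))
  writeTargetTable(tab, f)
  expect_identical(readTargetTable(f), tab)
})

test_that("profile matrix reader preserves missingness and rejects bad cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug_id,c1,c2,c3", "A,1,2,3", "B,4,,6"), f)
  m <- readProfileMatrix(f)
  expect_equal(dim(m), c(2L, 3L))
  expect_true(is.na(m["B", "c2"]))    # blank is missing, not zero
  expect_equal(m["A", ], c(c1 = 1, c2 = 2, c3 = 3))

  writeLines(c("drug_id,c1,c2", "A,1,2", "B,4,5,6"), f)
  expect_error(readProfileMatrix(f), "ragged")

  writeLines(c("drug_id,c1,c2", "A,1,x"), f)
  expect_error(readProfileMatrix(f), "non-numeric")

  # full-precision round trip
  set.seed(3)
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("A", "B", "C"), paste0("c", 1:4)))
  m[2, 3] <- NA
  writeProfileMatrix(m, f)
  expect_equal(readProfileMatrix(f), m, tolerance = 1e-15)
})

test_that("SMILES reader skips invalid records with a warning", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "C( broken", "c1ccccc1 benzene"), f)
  expect_warning(rec <- readSmilesFile(f), "skipped 1")
  expect_identical(rec$drug_id, c("ethanol", "benzene"))
  expect_identical(rec$smiles[1], "CCO")

  writeLines(character(0), f)
  expect_identical(nrow(readSmilesFile(f)), 0L)

  writeLines(c("CCO a", "CC a"), f)
  expect_error(readSmilesFile(f), "duplicate drug ID")
})

test_that("model serialization round-trips TLRs bit-exactly", {
  sims <- toySims()$sims
  model <- suppressWarnings(fitTLRModel(sims, toySims()$targets))
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(model, f)
  back <- loadModel(f)
  m1 <- channelModels(model)$structure
  m2 <- channelModels(back)$structure
  expect_identical(m1@breaks, m2@breaks)
  expect_identical(m1@ratios, m2@ratios)
  expect_identical(m1@coef, m2@coef)
  expect_identical(m1@median, m2@median)

  set.seed(9)
  s <- runif(100)
  expect_identical(likelihoodAt(m1, s), likelihoodAt(m2, s))

  # truncated file is a hard error, no partial model
  txt <- readLines(f)
  writeLines(txt[1:(length(txt) %/% 2)], f)
  expect_error(loadModel(f), "corrupt")

  # version mismatch is a hard error
  saveModel(model, f)
  txt <- sub('"version": "1"', '"version": "99"', readLines(f))
  writeLines(txt, f)
  expect_error(loadModel(f), "version")

  # a single-channel model loads with that single channel
  one <- new("TLRModel", models = channelModels(model)["structure"],
             version = "1")
  saveModel(one, f)
  expect_identical(channelNames(loadModel(f)), "structure")
})

test_that("similarity matrices round-trip through value + mask CSVs", {
  sim <- toySims()$sims$structure
  sim@scores[1, 3] <- NA; sim@scores[3, 1] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  writeSimilarityMatrix(sim, f)
  back <- readSimilarityMatrix(f, "structure", c(0, 1))
  expect_equal(similarityScores(back), similarityScores(sim),
               tolerance = 1e-15)
  expect_true(file.exists(sub("\\.csv$", "_mask.csv", f)))
})

test_that("binary feature tables round-trip in both dialects", {
  x <- list(positives = list(A = c("f1", "f2"), B = "f2", C = character(0)),
            tested = list(A = c("f1", "f2", "f3"), B = c("f2", "f4"),
                          C = "f1"),
            vocabulary = paste0("f", 1:4))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeBinaryTable(x, f, mode = "bioassay")
  back <- readBinaryTable(f, mode = "bioassay")
  expect_identical(back$positives[c("A", "B")], x$positives[c("A", "B")])
  expect_identical(back$tested, x$tested)

  y <- list(positives = list(A = c("se1", "se3"), B = "se2"))
  writeBinaryTable(y, f, mode = "presence")
  back <- readBinaryTable(f, mode = "presence")
  expect_identical(back$positives, y$positives)
  expect_null(back$tested)
})

test_that("readers survive fuzzed well-formed files (round-trip identity)", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(11)
  for (rep in 1:10) {
    nd <- sample(1:8, 1)
    tab <- lapply(seq_len(nd), function(i)
      sort(sample(paste0("T", 1:9), sample(1:4, 1))))
    names(tab) <- paste0("drug", sample(1000:9999, nd))
    writeTargetTable(tab, f)
    expect_identical(readTargetTable(f), tab)

    m <- matrix(round(rnorm(nd * 5), 6), nd, 5,
                dimnames = list(names(tab), paste0("c", 1:5)))
    m[runif(length(m)) < 0.2] <- NA
    writeProfileMatrix(m, f)
    expect_equal(readProfileMatrix(f), m, tolerance = 1e-12)
  }
})
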