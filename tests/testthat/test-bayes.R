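test_that("pair labeling follows target-set intersection", {
  tg <- list(A = "T1", B = c("T1", "T2"), C = "T3")
  lab <- labelPairs(c("A", "B", "C"), tg)
  expect_true(lab$st[lab$a == "A" & lab$b == "B"])
  expect_false(lab$st[lab$a == "A" & lab$b == "C"])

  # complete graph when everyone shares one target
  tg4 <- list(A = "T1", B = "T1", C = c("T1", "T9"), D = "T1")
  lab4 <- labelPairs(c("A", "B", "C", "D"), tg4)
  expect_equal(nrow(lab4), 6L)
  expect_true(all(lab4$st))

  # orphans are excluded with a warning, not treated as negatives
  expect_warning(lab2 <- labelPairs(c("A", "B", "X"), tg), "excluded 1")
  expect_false("X" %in% c(lab2$a, lab2$b))
})

test_that("per-bin likelihood ratios follow the count-fraction definition", {
  # identical empirical histograms -> every ratio exactly 1, alpha included
  sc <- rep(c(0.1, 0.5, 0.9), times = 4)
  st <- rep(c(TRUE, FALSE), each = 6)
  m <- fitLikelihoodModel(sc, st, "x", c(0, 1), nBins = 5, alpha = 1)
  expect_equal(m@ratios, rep(1, 5))
  expect_equal(likelihoodAt(m, c(0.05, 0.5, 0.95)), rep(1, 3),
               tolerance = 1e-9)

  # two bins over [0,1], alpha = 0: upper bin (2/4)/(1/4) = 2
  m2 <- fitLikelihoodModel(c(0.9, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1, 0.9),
                           c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                             FALSE),
                           "x", c(0, 1), nBins = 2, alpha = 0)
  expect_equal(m2@ratios[2], 2)
  expect_equal(m2@ratios[1], (2 / 4) / (3 / 4))

  # a bin holding 40% of ST and 10% of non-ST -> ratio 4
  scores <- c(rep(0.95, 4), rep(0.05, 6), rep(0.95, 1), rep(0.05, 9))
  labels <- rep(c(TRUE, FALSE), c(10, 10))
  m3 <- fitLikelihoodModel(scores, labels, "x", c(0, 1), nBins = 10,
                           alpha = 0)
  expect_equal(m3@ratios[10], 4)
})

test_that("degenerate inputs give a constant, still-valid model", {
  m <- fitLikelihoodModel(rep(0.4, 10), rep(c(TRUE, FALSE), 5), "x",
                          c(0, 1), nBins = 20, alpha = 1)
  expect_equal(m@coef[["b"]], 0)
  expect_equal(likelihoodAt(m, 0.1), likelihoodAt(m, 0.9))
  expect_gt(likelihoodAt(m, 0.5), 0)
})

test_that("fitted likelihood is monotone when the slope is positive", {
  set.seed(5)
  st <- rbeta(400, 4, 2); non <- rbeta(400, 2, 4)
  m <- fitLikelihoodModel(c(st, non), rep(c(TRUE, FALSE), each = 400), "x",
                          c(0, 1))
  expect_gt(m@coef[["b"]], 0)
  s <- seq(0, 1, by = 0.05)
  expect_true(all(diff(likelihoodAt(m, s)) > 0))
  # imputation likelihood is the curve at the stored median by definition
  expect_identical(likelihoodAt(m, imputationMedian(m)),
                   m@coef[["a"]] * exp(m@coef[["b"]] * imputationMedian(m)))
})

test_that("scores far outside the range error; marginal ones clamp", {
  m <- fitLikelihoodModel(c(0.2, 0.8), c(TRUE, FALSE), "x", c(0, 1),
                          nBins = 2)
  expect_error(likelihoodAt(m, 1.5), "far outside")
  expect_equal(suppressWarnings(likelihoodAt(m, 1 + 1e-12)),
               likelihoodAt(m, 1))
})

test_that("the TLR is the product of per-channel likelihoods", {
  mk <- function(ch, a, b, med = 0.5)
    new("LikelihoodModel", channel = ch, breaks = seq(0, 1, 0.05),
        ratios = rep(1, 20), counts = rbind(ST = rep(1, 20),
                                            nonST = rep(1, 20)),
        coef = c(a = a, b = b), median = med, alpha = 1, range = c(0, 1))
  # five strictly neutral channels -> TLR 1
  neutral <- lapply(paste0("c", 1:5), mk, a = 1, b = 0)
  names(neutral) <- paste0("c", 1:5)
  mod <- new("TLRModel", models = neutral, version = "1")
  s <- structure(runif(5), names = paste0("c", 1:5))
  expect_equal(totalLikelihoodRatio(mod, s)$tlr, 1)

  # constant channels with likelihoods 2, 3, 0.5 -> product 3
  mod3 <- new("TLRModel", version = "1",
              models = list(x = mk("x", 2, 0), y = mk("y", 3, 0),
                            z = mk("z", 0.5, 0)))
  r <- totalLikelihoodRatio(mod3, c(x = 0.2, y = 0.9, z = 0.4))
  expect_equal(r$tlr, 3)
  expect_identical(r$evidence$imputed, rep(FALSE, 3))

  # a missing channel contributes exactly likelihoodAt(median)
  mod2 <- new("TLRModel", version = "1",
              models = list(x = mk("x", 2, 1, med = 0.3),
                            y = mk("y", 1.5, 0)))
  r2 <- totalLikelihoodRatio(mod2, c(y = 0.8))
  lx <- likelihoodAt(mod2@models$x, 0.3)
  expect_equal(r2$tlr, lx * 1.5)
  expect_identical(r2$evidence$imputed, c(TRUE, FALSE))

  # all channels missing still yields a TLR, with a warning
  expect_warning(r3 <- totalLikelihoodRatio(mod2), "fully imputed")
  expect_equal(r3$tlr, likelihoodAt(mod2@models$x, 0.3) * 1.5)
})

test_that("adding a strictly neutral channel never changes the TLR", {
  sims <- defaultSims()
  u <- defaultUniverse()
  model <- defaultModel()
  neutral <- new("LikelihoodModel", channel = "noop",
                 breaks = seq(0, 1, 0.05), ratios = rep(1, 20),
                 counts = rbind(ST = rep(1, 20), nonST = rep(1, 20)),
                 coef = c(a = 1, b = 0), median = 0.5, alpha = 1,
                 range = c(0, 1))
  aug <- new("TLRModel", version = "1",
             models = c(channelModels(model), list(noop = neutral)))
  pr <- data.frame(a = drugIds(u)[1:20], b = drugIds(u)[21:40])
  expect_equal(pairTLR(aug, sims, pr)$tlr, pairTLR(model, sims, pr)$tlr,
               tolerance = 1e-12)
})

test_that("log-TLR is additive over channels and monotone in similarity", {
  model <- defaultModel()
  sims <- defaultSims()
  u <- defaultUniverse()
  pr <- data.frame(a = drugIds(u)[1:50], b = drugIds(u)[51:100])
  ev <- pairTLR(model, sims, pr, evidence = TRUE)
  likCols <- grep("^lik_", names(ev))
  expect_equal(log(ev$tlr), rowSums(log(as.matrix(ev[likCols]))),
               tolerance = 1e-12)

  # raising a score in a positive-slope channel never lowers the TLR
  for (ch in channelNames(model)) {
    m <- channelModels(model)[[ch]]
    if (m@coef[["b"]] <= 0) next
    s <- seq(scoreRange(m)[1], scoreRange(m)[2], length.out = 11)
    expect_true(all(diff(likelihoodAt(m, s)) >= 0))
  }
})

test_that("fold-refit TLRs rank like exact posterior odds on a discrete problem", {
  # Two independent discrete channels on a 20-point grid whose true
  # class-conditional likelihood ratio is exponential in the score.
  centers <- (seq_len(20) - 0.5) / 20
  q <- exp(-1.5 * centers); q <- q / sum(q)
  p <- q * exp(2.5 * centers); p <- p / sum(p)
  n <- 5000
  draws <- withSeed(77, {
    st <- runif(n) < 0.3
    s1 <- ifelse(st, sample(centers, n, TRUE, p), sample(centers, n, TRUE, q))
    s2 <- ifelse(st, sample(centers, n, TRUE, p), sample(centers, n, TRUE, q))
    list(st = st, s1 = s1, s2 = s2)
  })
  m1 <- fitLikelihoodModel(draws$s1, draws$st, "ch1", c(0, 1))
  m2 <- fitLikelihoodModel(draws$s2, draws$st, "ch2", c(0, 1))
  tlr <- likelihoodAt(m1, draws$s1) * likelihoodAt(m2, draws$s2)
  # exact posterior odds by enumeration from the true conditionals
  i1 <- match(draws$s1, centers); i2 <- match(draws$s2, centers)
  odds <- (p[i1] / q[i1]) * (p[i2] / q[i2])
  expect_gt(cor(tlr, odds, method = "spearman"), 0.99)
  # and the fitted slopes recover the true log-linear rate
  expect_equal(m1@coef[["b"]], 2.5, tolerance = 0.35)
  expect_equal(m2@coef[["b"]], 2.5, tolerance = 0.35)
})
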