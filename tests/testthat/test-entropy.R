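test_that("constant signals carry zero joint entropy", {
  b <- makeBinning("speed", values = rep(3, 10))
  h <- jointEntropy(rep(3, 10), rep(3, 10), b)
  expect_equal(as.numeric(h), 0)
  expect_equal(attr(h, "n"), 10L)
})

test_that("one sample per cell over k cells gives exactly log2(k) bits", {
  for (k in c(2L, 4L, 8L, 16L)) {
    b <- binningSpec("speed", seq(0, 1, length.out = k + 1L))
    mids <- (seq_len(k) - 0.5) / k
    expect_equal(as.numeric(jointEntropy(mids, mids, b)), log2(k))
  }
})

test_that("independent uniform pairs on 4x4 bins approach 4 bits and match the oracle", {
  b <- binningSpec("speed", seq(0, 1, length.out = 5))
  withr::with_seed(2024, {
    x <- runif(10000); y <- runif(10000)
  })
  h <- jointEntropy(x, y, b)
  expect_lt(abs(as.numeric(h) - 4), 0.02)
  expect_equal(as.numeric(h), jointEntropyOracle(x, y, b@edges),
               tolerance = 1e-12)
})

test_that("plug-in joint entropy equals brute-force cell enumeration", {
  withr::with_seed(77, {
    for (i in 1:30) {
      n <- sample(1:100, 1)
      nb <- sample(2:12, 1)
      x <- rnorm(n); y <- rnorm(n, sd = 3)
      edges <- seq(-3, 3, length.out = nb + 1L)
      b <- binningSpec("speed", edges)
      expect_equal(as.numeric(jointEntropy(x, y, b)),
                   jointEntropyOracle(x, y, edges), tolerance = 1e-12)
      expect_equal(as.numeric(shannonEntropy(x, b)),
                   marginalEntropyOracle(x, edges), tolerance = 1e-12)
    }
  })
})

test_that("entropy bounds, subadditivity and permutation invariance hold on random draws", {
  withr::with_seed(123, {
    for (i in 1:200) {
      n <- sample(5:200, 1)
      nb <- sample(2:16, 1)
      gen <- sample(1:3, 1)
      x <- switch(gen, runif(n), rnorm(n), exp(rnorm(n)))
      y <- switch(sample(1:3, 1), runif(n), rnorm(n), x + rnorm(n, sd = 0.3))
      b <- makeBinning("speed", values = c(x, y), nBins = nb)
      h <- as.numeric(jointEntropy(x, y, b))
      expect_gte(h, 0)
      expect_lte(h, log2(nb^2) + 1e-9)
      hx <- as.numeric(shannonEntropy(x, b))
      hy <- as.numeric(shannonEntropy(y, b))
      expect_lte(h, hx + hy + 1e-9)
      perm <- sample.int(n)
      expect_equal(as.numeric(jointEntropy(x[perm], y[perm], b)), h,
                   tolerance = 1e-12)
    }
  })
})

test_that("degenerate and malformed inputs are rejected", {
  b <- binningSpec("speed", c(0, 1, 2))
  expect_error(jointEntropy(1:3, 1:4, b), "equal length")
  expect_error(jointEntropy(NA_real_, NA_real_, b), "valid")
  expect_error(binningSpec("speed", c(0, 0, 1)))   # non-increasing edges
  expect_error(binningSpec("speed", c(0, 1)))      # a single bin is refused
})

test_that("identical series collapse the joint support onto the diagonal", {
  p <- data.frame(t = 0:59, x = cumsum(rnorm(60, 5, 4)),
                  y = cumsum(rnorm(60, 0, 4)), valid = TRUE)
  ks <- computeKinematics(p, "dominant")
  tr <- operatorEntropy(ks, ks)
  expect_equal(speedH(tr),
               as.numeric(shannonEntropy(speed(ks), binning(tr)$speed)),
               tolerance = 1e-12)
})

test_that("a hand with no valid data yields an undefined triplet, not zero", {
  pd <- data.frame(t = 0:9, x = NA_real_, y = NA_real_, valid = FALSE)
  pn <- data.frame(t = 0:9, x = 1:10, y = 1, valid = TRUE)
  tr <- operatorEntropy(computeKinematics(pd, "dominant"),
                        computeKinematics(pn, "nondominant"))
  expect_true(is.na(speedH(tr)))
  expect_true(is.na(accelerationH(tr)))
  expect_true(is.na(directionH(tr)))
  expect_match(tr@status[["speed"]], "no pairwise-valid")
  expect_equal(unname(nSamples(tr)), rep(0L, 3))
})

test_that("series on different grids are refused", {
  a <- computeKinematics(data.frame(t = 0:5, x = 1:6, y = 1, valid = TRUE), "a")
  b <- computeKinematics(data.frame(t = 0:4, x = 1:5, y = 1, valid = TRUE), "b")
  expect_error(operatorEntropy(a, b), "grid")
})

test_that("speed entropy orders an expert against a novice profile", {
  sc <- syntheticScene(frameSize = c(3840, 2160))
  hs <- vapply(c(expert = "expert", novice = "novice"), function(sk) {
    tr <- generateTrajectory(motionProfile(sk, duration = 300, seed = 17), sc)
    speedH(operatorEntropy(kinematicSeries(tr$dominant),
                           kinematicSeries(tr$nondominant)))
  }, numeric(1))
  expect_lt(hs["expert"], hs["novice"])
})

test_that("entropy rises monotonically along a jitter ladder", {
  sc <- syntheticScene(frameSize = c(3840, 2160))
  ladder <- c(1, 2, 5, 10, 20)
  hs <- vapply(ladder, function(j) {
    mean(vapply(1:2, function(s) {
      p <- motionProfile("resident", jitterSd = j, duration = 300,
                         seed = 400 + 10 * s + j)
      tr <- generateTrajectory(p, sc)
      speedH(operatorEntropy(kinematicSeries(tr$dominant),
                             kinematicSeries(tr$nondominant)))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(ladder, hs, method = "spearman"), 0.9)
})
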