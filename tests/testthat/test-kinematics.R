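constTrack <- function(x, y, nSec = 3, fr = 50, valid = NULL) {
  n <- nSec * fr
  if (is.null(valid)) valid <- rep(TRUE, n)
  handTrack("dominant", fr,
            data.frame(frame_index = 0:(n - 1L), hand = "dominant",
                       valid = valid, x = ifelse(valid, x, NA),
                       y = ifelse(valid, y, NA)))
}

test_that("a constant-position track resamples to its position every second", {
  r <- resampleTrack(constTrack(10, 10, nSec = 5))
  expect_equal(nrow(r), 5L)
  expect_true(all(r$valid))
  expect_equal(r$x, rep(10, 5))
  expect_equal(r$y, rep(10, 5))
})

test_that("seconds with mostly-invalid frames are invalid, no interpolation", {
  valid <- rep(TRUE, 150)
  valid[51:100] <- FALSE          # second 1 fully invalid
  valid[101:127] <- FALSE         # second 2: 23/50 valid (< 50%)
  tr <- constTrack(5, 5, nSec = 3, valid = valid)
  r <- resampleTrack(tr)
  expect_equal(r$valid, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(r$x[2:3])))
})

test_that("linear motion at 2 px/frame advances 100 px per second", {
  n <- 250L; fr <- 50
  tr <- handTrack("dominant", fr,
                  data.frame(frame_index = 0:(n - 1L), hand = "dominant",
                             valid = TRUE, x = 2 * (0:(n - 1L)), y = 7))
  r <- resampleTrack(tr)
  expect_equal(diff(r$x), rep(100, 4))
  ks <- computeKinematics(r, "dominant")
  expect_equal(speed(ks)[1:4], rep(100, 4))
  expect_equal(acceleration(ks)[1:3], rep(0, 3))
  expect_equal(directionChange(ks)[1:3], rep(0, 3))
})

test_that("collinear and perpendicular displacements give 0 and 90 degrees", {
  p <- data.frame(t = 0:2, x = c(0, 100, 200), y = 0, valid = TRUE)
  ks <- computeKinematics(p, "h")
  expect_equal(speed(ks), c(100, 100, NA_real_))
  expect_equal(acceleration(ks), c(0, NA_real_, NA_real_))
  expect_equal(directionChange(ks), c(0, NA_real_, NA_real_))
  p2 <- data.frame(t = 0:2, x = c(0, 100, 100), y = c(0, 0, 100), valid = TRUE)
  expect_equal(directionChange(computeKinematics(p2, "h"))[1], 90)
})

test_that("a stationary hand has zero speed and undefined direction", {
  ks <- kinematicSeries(constTrack(10, 10, nSec = 5))
  expect_equal(speed(ks)[1:4], rep(0, 4))
  expect_equal(acceleration(ks)[1:3], rep(0, 3))
  expect_true(all(is.na(directionChange(ks))))
})

test_that("samples touching an invalid second are invalid", {
  p <- data.frame(t = 0:5, x = c(0, 10, NA, 30, 40, 50), y = 0,
                  valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  ks <- computeKinematics(p, "h")
  expect_equal(is.na(speed(ks)), c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(is.na(acceleration(ks)),
               c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(is.na(directionChange(ks)),
               c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
})

test_that("kinematics are invariant under rigid transforms and equivariant under scaling", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(5:30, 1)
      p <- data.frame(t = 0:(n - 1), x = cumsum(rnorm(n, 0, 20)),
                      y = cumsum(rnorm(n, 0, 20)),
                      valid = runif(n) > 0.15)
      base <- computeKinematics(p, "h")
      a <- runif(1, 0, 2 * pi); dx <- runif(1, -500, 500); dy <- runif(1, -500, 500)
      q <- p
      q$x <- cos(a) * p$x - sin(a) * p$y + dx
      q$y <- sin(a) * p$x + cos(a) * p$y + dy
      rig <- computeKinematics(q, "h")
      expect_equal(speed(rig), speed(base), tolerance = 1e-9)
      expect_equal(acceleration(rig), acceleration(base), tolerance = 1e-9)
      expect_equal(directionChange(rig), directionChange(base),
                   tolerance = 1e-9)
      cc <- runif(1, 0.1, 10)
      s <- p; s$x <- cc * p$x; s$y <- cc * p$y
      scl <- computeKinematics(s, "h")
      expect_equal(speed(scl), cc * speed(base), tolerance = 1e-9)
      expect_equal(acceleration(scl), cc * acceleration(base),
                   tolerance = 1e-9)
      expect_equal(directionChange(scl), directionChange(base),
                   tolerance = 1e-9)
    }
  })
})
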