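test_that("the noise-free limit is a straight constant-velocity track", {
  sc <- syntheticScene(frameSize = c(1000, 1000))
  p <- motionProfile("expert", baseSpeed = 100, jitterSd = 0,
                     directionChangeRate = 0, idleFraction = 0,
                     duration = 1, frameRate = 50, seed = 1)
  tr <- generateTrajectory(p, sc)
  d <- detections(tr$dominant)
  disp <- cbind(diff(d$x), diff(d$y))
  expect_equal(sqrt(rowSums(disp^2)), rep(2, 49))  # 100 px/s at 50 fps
  # all steps identical: straight line
  expect_lt(max(abs(sweep(disp, 2, disp[1, ]))), 1e-9)
})

test_that("a fixed seed reproduces trajectories bit for bit", {
  sc <- syntheticScene()
  p <- motionProfile("novice", duration = 10, seed = 99)
  a <- generateTrajectory(p, sc)
  b <- generateTrajectory(p, sc)
  expect_identical(detections(a$dominant), detections(b$dominant))
  expect_identical(detections(a$nondominant), detections(b$nondominant))
  p2 <- motionProfile("novice", duration = 10, seed = 100)
  expect_false(identical(detections(generateTrajectory(p2, sc)$dominant),
                         detections(a$dominant)))
})

test_that("realised out-of-frame time tracks the idle fraction", {
  sc <- syntheticScene(frameSize = c(1280, 720))
  p <- motionProfile("resident", idleFraction = 0.5, duration = 100, seed = 7)
  tr <- generateTrajectory(p, sc)
  outSec <- sum(!detections(tr$dominant)$valid) / frameRate(tr$dominant)
  expect_lt(abs(outSec - 50), 5)
  for (f in c(0, 0.1, 0.9)) {
    pf <- motionProfile("resident", idleFraction = f, duration = 60, seed = 11)
    frac <- mean(!detections(generateTrajectory(pf, sc)$dominant)$valid)
    expect_lt(abs(frac - f), 0.05)
  }
})

test_that("step statistics follow baseSpeed and jitterSd", {
  sc <- syntheticScene(frameSize = c(4000, 4000))
  ## drift-free profile: the steps are pure per-frame jitter
  p <- motionProfile("resident", baseSpeed = 0, jitterSd = 6,
                     directionChangeRate = 0, idleFraction = 0,
                     duration = 20, seed = 5)
  d <- detections(generateTrajectory(p, sc)$dominant)
  steps <- cbind(diff(d$x), diff(d$y))
  expect_lt(abs(sd(as.vector(steps)) - 6), 0.3)
  expect_lt(abs(mean(steps)), 0.5)
})

test_that("in-frame positions respect the frame bounds and hand regions", {
  sc <- syntheticScene(frameSize = c(320, 240), blobRadius = 10)
  tr <- generateTrajectory(motionProfile("novice", duration = 30, seed = 3), sc)
  dd <- detections(tr$dominant); dn <- detections(tr$nondominant)
  expect_true(all(dd$x[dd$valid] >= 10 & dd$x[dd$valid] <= 150))
  expect_true(all(dn$x[dn$valid] >= 170 & dn$x[dn$valid] <= 309))
  for (d in list(dd, dn))
    expect_true(all(d$y[d$valid] >= 10 & d$y[d$valid] <= 229))
  # the two blobs can touch but never overlap
  both <- dd$valid & dn$valid
  dist <- sqrt((dd$x - dn$x)^2 + (dd$y - dn$y)^2)[both]
  expect_true(all(dist >= 2 * 10))
})

test_that("invalid motion profiles are rejected", {
  expect_error(motionProfile("expert", idleFraction = 1.5), "idleFraction")
  expect_error(motionProfile("expert", jitterSd = -1), "jitterSd")
  expect_error(motionProfile("expert", duration = 0), "duration")
  expect_error(motionProfile("expert", frameRate = -50), "frameRate")
})

test_that("gap list of a generated track partitions the idle frames", {
  sc <- syntheticScene()
  tr <- generateTrajectory(motionProfile("resident", idleFraction = 0.3,
                                         duration = 20, seed = 13), sc)
  d <- detections(tr$dominant)
  g <- gaps(tr$dominant)
  covered <- unlist(apply(g, 1, function(r) r[1]:r[2], simplify = FALSE))
  expect_setequal(covered, d$frame_index[!d$valid])
  expect_true(all(d$valid[setdiff(d$frame_index, covered) + 1L]))
})
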