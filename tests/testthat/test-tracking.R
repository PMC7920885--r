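test_that("bounding-box centre of a solid square is its geometric centre", {
  f <- makeFrame(100, 100, list(list(x0 = 45, y0 = 45, x1 = 54, y1 = 54,
                                     col = GREEN)))
  d <- detectHand(f, greenSpec())
  expect_true(d$valid)
  expect_equal(c(d$x, d$y), c(49.5, 49.5))
  expect_equal(c(d$bbox_x0, d$bbox_y0, d$bbox_x1, d$bbox_y1),
               c(45, 45, 54, 54))
  expect_equal(d$pixel_count, 100L)
})

test_that("a frame without in-range pixels yields an invalid detection", {
  f <- makeFrame(60, 60, list())
  d <- detectHand(f, greenSpec())
  expect_false(d$valid)
  expect_true(is.na(d$x) && is.na(d$y))
  expect_equal(d$pixel_count, 0L)
})

test_that("detection keeps the largest component and honours minPixels", {
  f <- makeFrame(80, 80, list(
    list(x0 = 10, y0 = 10, x1 = 29, y1 = 29, col = GREEN),  # 400 px
    list(x0 = 60, y0 = 60, x1 = 64, y1 = 64, col = GREEN))) # 25 px speck
  d <- detectHand(f, greenSpec(), minPixels = 30)
  expect_equal(c(d$bbox_x0, d$bbox_x1), c(10, 29))
  expect_equal(d$pixel_count, 400L)
  small <- makeFrame(40, 40, list(list(x0 = 5, y0 = 5, x1 = 8, y1 = 8,
                                       col = GREEN)))
  expect_false(detectHand(small, greenSpec(), minPixels = 30)$valid)
})

test_that("a distractor blob of another colour leaves the detection unchanged", {
  base <- list(list(x0 = 20, y0 = 30, x1 = 39, y1 = 49, col = GREEN))
  withD <- c(base, list(list(x0 = 60, y0 = 10, x1 = 75, y1 = 25, col = BLUE)))
  d0 <- detectHand(makeFrame(100, 100, base), greenSpec())
  d1 <- detectHand(makeFrame(100, 100, withD), greenSpec())
  expect_identical(d0, d1)
  expect_equal(c(d0$x, d0$y), c(29.5, 39.5))
})

test_that("detected bbox equals the brute-force largest-component bbox", {
  withr::with_seed(42, {
    for (i in 1:15) {
      nRect <- sample(1:4, 1)
      rects <- lapply(seq_len(nRect), function(j) {
        x0 <- sample(0:50, 1); y0 <- sample(0:50, 1)
        list(x0 = x0, y0 = y0, x1 = x0 + sample(2:20, 1),
             y1 = y0 + sample(2:20, 1), col = GREEN)
      })
      f <- makeFrame(75, 75, rects)
      ref <- bruteLargestComponent(f[, , 2] > 0.5)
      d <- detectHand(f, greenSpec(), minPixels = 1)
      expect_equal(c(d$bbox_x0, d$bbox_y0, d$bbox_x1, d$bbox_y1),
                   c(ref$x0, ref$y0, ref$x1, ref$y1))
      expect_equal(d$pixel_count, ref$size)
    }
  })
})

test_that("tracking a frame list is deterministic and reports gaps truthfully", {
  mkframe <- function(gx, showGreen) {
    rects <- list(list(x0 = 70, y0 = 40, x1 = 79, y1 = 49, col = ORANGE))
    if (showGreen)
      rects <- c(rects, list(list(x0 = gx, y0 = 10, x1 = gx + 9, y1 = 19,
                                  col = GREEN)))
    makeFrame(100, 60, rects)  # 100 px wide, 60 px high
  }
  frames <- lapply(0:9, function(i) mkframe(2 * i, !(i %in% 3:5)))
  tr <- trackVideo(frames, greenSpec(), orangeSpec(), frameRate = 10)
  tr2 <- trackVideo(frames, greenSpec(), orangeSpec(), frameRate = 10)
  expect_identical(detections(tr$dominant), detections(tr2$dominant))
  expect_equal(unname(gaps(tr$dominant)[1, ]), c(3L, 5L))
  expect_equal(nrow(gaps(tr$nondominant)), 0L)
  dd <- detections(tr$dominant)
  expect_equal(dd$valid, !(0:9 %in% 3:5))
  expect_equal(dd$x[dd$valid], 2 * (0:9)[!(0:9 %in% 3:5)] + 4.5)
})

test_that("overlapping glove specifications are refused", {
  frames <- list(makeFrame(20, 20, list()))
  expect_error(trackVideo(frames, greenSpec(), colorSpec("x", c(100, 160))),
               "overlap")
})

test_that("track CSV round trip preserves detections", {
  f <- makeFrame(50, 50, list(list(x0 = 10, y0 = 10, x1 = 19, y1 = 19,
                                   col = GREEN)))
  tr <- trackVideo(list(f, f), greenSpec(), orangeSpec(), frameRate = 2)
  path <- tempfile(fileext = ".csv")
  writeTrack(tr, path)
  back <- readTrack(path, frameRate = 2)
  expect_equal(detections(back$dominant), detections(tr$dominant))
  expect_equal(hand(back$nondominant), "nondominant")
})
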