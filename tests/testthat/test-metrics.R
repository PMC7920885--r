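## the worked interval example: incision at 0, vessel loop at 100 s,
## instruments out during [10, 20) and [50, 55), otherwise active
toyTimeline <- function() {
  procedureTimeline(data.frame(
    time_s = c(0, 100, 10, 20, 50, 55, 0, 10, 20, 50, 55, 100),
    kind = c("milestone", "milestone",
             "instrument_out", "instrument_in",
             "instrument_out", "instrument_in",
             rep(c("contact_start", "contact_end"), 3)),
    detail = c("skin_incision", "vessel_loop_passed",
               rep("instruments", 4),
               rep("hands", 6))))
}

test_that("the worked interval example yields total 100, idle 15, active 85", {
  m <- computeMetrics(toyTimeline())
  expect_identical(totalTime(m), 100)
  expect_identical(idleTime(m), 15)
  expect_identical(activeTime(m), 85)
  expect_equal(m@idlePctOfActive, 100 * 15 / 85)  # about 17.6 %
  expect_equal(m@activeIdleRatio, 85 / 15)
  expect_true(isCompleted(m))
})

test_that("instrument changes count transitions between distinct instruments", {
  ev <- rbind(events(toyTimeline()),
              data.frame(time_s = c(5, 30, 60, 80),
                         kind = "instrument_pickup",
                         detail = c("scalpel", "forceps", "scalpel",
                                    "retractor")))
  m <- computeMetrics(procedureTimeline(ev))
  expect_identical(instrumentChanges(m), 3L)
  expect_equal(m@instrumentDurations[["scalpel"]], 25 + 20)
  # re-picking the same instrument is not a change
  ev2 <- rbind(events(toyTimeline()),
               data.frame(time_s = c(5, 30), kind = "instrument_pickup",
                          detail = "forceps"))
  expect_identical(instrumentChanges(computeMetrics(procedureTimeline(ev2))), 0L)
})

test_that("a missing vessel-loop milestone censors the total at the limit", {
  ev <- data.frame(time_s = c(0, 100, 300),
                   kind = c("milestone", "contact_start", "contact_end"),
                   detail = c("skin_incision", "hands", "hands"))
  m <- computeMetrics(procedureTimeline(ev, timeLimit = 1200))
  expect_false(isCompleted(m))
  expect_identical(totalTime(m), 1200)
  expect_identical(activeTime(m), 200)
})

test_that("validation lists unmatched intervals and milestone order violations", {
  expect_length(validateTimeline(toyTimeline()), 0L)
  bad1 <- procedureTimeline(data.frame(
    time_s = c(0, 40, 90),
    kind = c("milestone", "dissection_start", "milestone"),
    detail = c("skin_incision", "blunt", "vessel_loop_passed")))
  expect_match(validateTimeline(bad1), "never closed", all = FALSE)
  bad2 <- procedureTimeline(data.frame(
    time_s = c(5, 2), kind = "milestone",
    detail = c("skin_incision", "vessel_loop_passed")))
  expect_match(validateTimeline(bad2), "precede", all = FALSE)
  bad3 <- procedureTimeline(data.frame(
    time_s = 0, kind = "milestone", detail = "vessel_loop_passed"))
  expect_match(validateTimeline(bad3), "skin_incision", all = FALSE)
  expect_error(computeMetrics(bad1), "validation")
})

test_that("dissection modes must not overlap", {
  ev <- data.frame(
    time_s = c(0, 10, 30, 20, 40, 100),
    kind = c("milestone", "dissection_start", "dissection_end",
             "dissection_start", "dissection_end", "milestone"),
    detail = c("skin_incision", "blunt", "blunt", "sharp", "sharp",
               "vessel_loop_passed"))
  expect_match(validateTimeline(procedureTimeline(ev)), "disjoint",
               all = FALSE)
})

test_that("idle and active accounting is invariant to splitting intervals", {
  base <- computeMetrics(toyTimeline())
  ## same procedure, but [10, 20) annotated as [10, 15) + [15, 20): the
  ## closing instrument_in at 15 precedes the re-opening instrument_out
  split <- data.frame(
    time_s = c(0, 100, 10, 15, 15, 20, 50, 55, 0, 10, 20, 50, 55, 100),
    kind = c("milestone", "milestone",
             "instrument_out", "instrument_in",
             "instrument_out", "instrument_in",
             "instrument_out", "instrument_in",
             rep(c("contact_start", "contact_end"), 3)),
    detail = c("skin_incision", "vessel_loop_passed",
               rep("instruments", 6), rep("hands", 6)))
  m <- computeMetrics(procedureTimeline(split))
  expect_identical(idleTime(m), idleTime(base))
  expect_identical(activeTime(m), activeTime(base))
})

test_that("adding an instrument-out interval never decreases idle time", {
  withr::with_seed(5, {
    for (i in 1:25) {
      tl <- generateTimeline(totalTime = 600, idleTime = sample(0:100, 1),
                             activeTime = sample(0:500, 1), seed = i)
      m0 <- computeMetrics(tl)
      s <- sort(sample(0:599, 2))
      ev <- rbind(events(tl),
                  data.frame(time_s = s, kind = c("instrument_out",
                                                  "instrument_in"),
                             detail = "extra_probe"))
      m1 <- computeMetrics(procedureTimeline(ev))
      expect_gte(idleTime(m1), idleTime(m0))
    }
  })
})

test_that("generated timelines reproduce the requested metrics exactly", {
  tl <- generateTimeline(totalTime = 100, idleTime = 15, activeTime = 85,
                         instrumentChanges = 3, seed = 7)
  m <- computeMetrics(tl)
  expect_identical(c(totalTime(m), idleTime(m), activeTime(m)),
                   c(100, 15, 85))
  expect_identical(instrumentChanges(m), 3L)
  # seeded determinism
  expect_identical(events(generateTimeline(totalTime = 100, idleTime = 15,
                                           activeTime = 85,
                                           instrumentChanges = 3, seed = 7)),
                   events(tl))
  # inconsistent requests are refused
  expect_error(generateTimeline(totalTime = 10, idleTime = 11, seed = 1),
               "exceeds")
  expect_error(generateTimeline(totalTime = 100, bluntTime = 60,
                                sharpTime = 50, seed = 1), "exceeds")
  expect_error(generateTimeline(completed = FALSE, totalTime = NULL,
                                idleTime = 1300, seed = 1), "exceeds")
  expect_error(generateTimeline(totalTime = 10.0001234, seed = 1),
               "milliseconds")
})

test_that("group summaries average uncensored values and flag censored ones", {
  mk <- function(tt, completed = TRUE)
    computeMetrics(generateTimeline(
      totalTime = if (completed) tt else NULL, idleTime = 9,
      activeTime = if (completed) tt - 8 else 1100,
      completed = completed, seed = round(tt)))
  s <- summarizeGroup(list(mk(303), mk(328)))
  tot <- s[s$field == "totalTime", ]
  expect_equal(tot$mean, 315.5)
  expect_equal(c(tot$min, tot$max), c(303, 328))
  expect_equal(tot$n_censored, 0L)
  one <- summarizeGroup(list(mk(500)))
  expect_equal(one[one$field == "totalTime", c("mean", "min", "max")],
               data.frame(mean = 500, min = 500, max = 500),
               ignore_attr = TRUE)
  cen <- summarizeGroup(list(mk(400), mk(0, completed = FALSE)))
  tot2 <- cen[cen$field == "totalTime", ]
  expect_equal(tot2$mean, 400)
  expect_equal(tot2$n_censored, 1L)
  allc <- summarizeGroup(list(mk(0, completed = FALSE)))
  expect_true(is.na(allc[allc$field == "totalTime", "mean"]))
  expect_error(summarizeGroup(list()), "empty")
})

test_that("timeline CSV round trip preserves events", {
  tl <- generateTimeline(totalTime = 200, idleTime = 20, activeTime = 150,
                         bluntTime = 30, sharpTime = 40, seed = 9)
  path <- tempfile(fileext = ".csv")
  writeTimeline(tl, path)
  back <- readTimeline(path)
  expect_equal(events(back), events(tl))
  expect_identical(computeMetrics(back)@sharpBluntRatio, 40 / 30)
})
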