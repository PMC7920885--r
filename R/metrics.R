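#' Construct a procedure timeline
#'
#' @param events data.frame with columns \code{time_s} (seconds from video
#'   start, decimals allowed), \code{kind} (see
#'   \code{\linkS4class{ProcedureTimeline}}) and \code{detail}. Events are
#'   sorted by time; within a tie the given order is kept.
#' @param timeLimit procedure cap in seconds (default 1200, the 20-minute
#'   limit at which totals are censored).
#' @return A \code{\linkS4class{ProcedureTimeline}}.
#' @examples
#' tl <- procedureTimeline(data.frame(
#'   time_s = c(0, 100), kind = "milestone",
#'   detail = c("skin_incision", "vessel_loop_passed")))
#' validateTimeline(tl)
#' @export
procedureTimeline <- function(events, timeLimit = 1200) {
  events <- as.data.frame(events)[c("time_s", "kind", "detail")]
  events$time_s <- as.numeric(events$time_s)
  events$kind <- as.character(events$kind)
  events$detail <- as.character(events$detail)
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  new("ProcedureTimeline", events = events, timeLimit = as.numeric(timeLimit))
}

#' Read / write a timeline CSV
#'
#' The timeline CSV schema is \code{time_s, kind, detail}, one row per
#' event, times in seconds as decimal numbers from video start.
#'
#' @param path CSV path.
#' @param timeLimit seconds; attached to the timeline on read.
#' @return \code{readTimeline}: a \code{\linkS4class{ProcedureTimeline}}.
#' @export
readTimeline <- function(path, timeLimit = 1200) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  procedureTimeline(d, timeLimit = timeLimit)
}

#' @rdname readTimeline
#' @param timeline a \code{\linkS4class{ProcedureTimeline}}.
#' @export
writeTimeline <- function(timeline, path) {
  stopifnot(is(timeline, "ProcedureTimeline"))
  write.csv(events(timeline), path, row.names = FALSE)
  invisible(path)
}

## interval pairing for one alternating start/stop stream; returns a matrix
## of [start, end) in ms, or NULL (with messages appended) on violation
.pairIntervals <- function(times, kinds, startKind, endKind, label) {
  viol <- character()
  open <- NA_real_
  ivs <- NULL
  for (i in seq_along(times)) {
    if (kinds[i] == startKind) {
      if (!is.na(open))
        viol <- c(viol, sprintf("%s: '%s' at %.3f s while a previous one at %.3f s is unclosed",
                                label, startKind, times[i] / 1000, open / 1000))
      open <- times[i]
    } else {
      if (is.na(open))
        viol <- c(viol, sprintf("%s: '%s' at %.3f s with no matching '%s' before it",
                                label, endKind, times[i] / 1000, startKind))
      else {
        ivs <- rbind(ivs, c(open, times[i]))
        open <- NA_real_
      }
    }
  }
  if (!is.na(open))
    viol <- c(viol, sprintf("%s: '%s' at %.3f s never closed by '%s'",
                            label, startKind, open / 1000, endKind))
  list(intervals = ivs, violations = viol)
}

## ms-grid view of a timeline: integer millisecond times
.eventsMs <- function(timeline) {
  e <- events(timeline)
  e$tms <- round(e$time_s * 1000)
  e
}

#' Validate a procedure timeline
#'
#' Checks the structural rules an annotated timeline must satisfy before
#' metrics are computed: a single \code{skin_incision} milestone present and
#' preceding all other events; milestones in procedural order (incision,
#' pectoralis-minor division, vessel-loop passage); every interval start
#' (contact, instrument-out, dissection) closed by a matching later end,
#' with instrument in/out alternating per instrument label and dissection
#' modes restricted to \code{blunt}/\code{sharp}.
#'
#' @param timeline a \code{\linkS4class{ProcedureTimeline}}.
#' @return Character vector of violation messages; empty when the timeline
#'   is well-formed.
#' @export
validateTimeline <- function(timeline) {
  stopifnot(is(timeline, "ProcedureTimeline"))
  e <- .eventsMs(timeline)
  viol <- character()
  mil <- e[e$kind == "milestone", ]
  inc <- mil[mil$detail == "skin_incision", ]
  if (nrow(inc) != 1L)
    viol <- c(viol, sprintf("expected exactly one skin_incision milestone, found %d", nrow(inc)))
  else if (any(e$tms < inc$tms))
    viol <- c(viol, "skin_incision must precede all other events")
  for (d in c("pectoralis_minor_divided", "vessel_loop_passed"))
    if (sum(mil$detail == d) > 1L)
      viol <- c(viol, paste("duplicated milestone:", d))
  ord <- c("skin_incision", "pectoralis_minor_divided", "vessel_loop_passed")
  mt <- vapply(ord, function(d) {
    t <- mil$tms[mil$detail == d]
    if (length(t)) t[1] else NA_real_
  }, numeric(1))
  if (is.unsorted(mt[!is.na(mt)]))
    viol <- c(viol, "milestones out of procedural order")
  bad <- setdiff(mil$detail, ord)
  if (length(bad))
    viol <- c(viol, paste("unknown milestone(s):", paste(bad, collapse = ", ")))

  ct <- e[e$kind %in% c("contact_start", "contact_end"), ]
  viol <- c(viol, .pairIntervals(ct$tms, ct$kind, "contact_start",
                                 "contact_end", "contact")$violations)
  io <- e[e$kind %in% c("instrument_out", "instrument_in"), ]
  for (d in unique(io$detail)) {
    s <- io[io$detail == d, ]
    viol <- c(viol, .pairIntervals(s$tms, s$kind, "instrument_out",
                                   "instrument_in",
                                   paste0("instrument '", d, "'"))$violations)
  }
  ds <- e[e$kind %in% c("dissection_start", "dissection_end"), ]
  badMode <- setdiff(unique(ds$detail[ds$kind == "dissection_start"]),
                     c("blunt", "sharp"))
  if (length(badMode))
    viol <- c(viol, paste("unknown dissection mode(s):",
                          paste(badMode, collapse = ", ")))
  allIvs <- NULL
  for (mode in unique(ds$detail)) {
    idx <- ds$detail == mode
    pr <- .pairIntervals(ds$tms[idx], ds$kind[idx], "dissection_start",
                         "dissection_end", paste0("dissection '", mode, "'"))
    viol <- c(viol, pr$violations)
    allIvs <- rbind(allIvs, pr$intervals)
  }
  if (!is.null(allIvs) && nrow(allIvs) > 1L) {
    o <- order(allIvs[, 1])
    if (any(allIvs[o, 1][-1] < allIvs[o, 2][-nrow(allIvs)]))
      viol <- c(viol, "dissection-mode intervals must be disjoint")
  }
  viol
}

## total length of the union of [start, end) intervals clipped to [lo, hi]
.unionLength <- function(ivs, lo, hi) {
  if (is.null(ivs) || !nrow(ivs)) return(0)
  s <- pmax(ivs[, 1], lo); en <- pmin(ivs[, 2], hi)
  keep <- en > s
  if (!any(keep)) return(0)
  s <- s[keep]; en <- en[keep]
  o <- order(s)
  s <- s[o]; en <- en[o]
  tot <- 0; cs <- s[1]; ce <- en[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) { tot <- tot + (ce - cs); cs <- s[i]; ce <- en[i] }
    else ce <- max(ce, en[i])
  }
  tot + (ce - cs)
}

#' Compute the eight observational procedure metrics
#'
#' From a validated timeline, computes: (1) total time, skin incision to
#' vessel-loop passage; (2) idle time, the summed (union) length of
#' intervals during which instruments were out of the incision; (3) active
#' time, the union of hand/instrument contact intervals (simultaneous
#' bimanual activity is not double-counted); (4) time from incision to
#' pectoralis-minor division; (5) number of instrument changes (transitions
#' between distinct instruments in pickup order); (6) blunt and (7) sharp
#' dissection time; (8) per-instrument use durations (pickup to next
#' pickup). Derived ratios (active/idle, sharp/blunt, idle as a percent of
#' active) are \code{NA} when their denominator is zero. Idle and active
#' come from different event families and need not sum to the total.
#'
#' If the vessel-loop milestone is absent the procedure was not completed
#' within the time limit: \code{completed} is \code{FALSE} and
#' \code{totalTime} carries the limit as a "greater than" sentinel. All
#' interval arithmetic is done on an integer millisecond grid, so metrics
#' are exact for timelines annotated at millisecond resolution.
#'
#' @param timeline a \code{\linkS4class{ProcedureTimeline}}.
#' @return A \code{\linkS4class{ProcedureMetrics}}.
#' @examples
#' tl <- generateTimeline(totalTime = 100, idleTime = 15, activeTime = 85,
#'                        seed = 7)
#' computeMetrics(tl)
#' @export
computeMetrics <- function(timeline) {
  stopifnot(is(timeline, "ProcedureTimeline"))
  viol <- validateTimeline(timeline)
  if (length(viol))
    stop("timeline fails validation:\n  ", paste(viol, collapse = "\n  "))
  e <- .eventsMs(timeline)
  limitMs <- round(timeLimit(timeline) * 1000)
  mil <- e[e$kind == "milestone", ]
  t0 <- mil$tms[mil$detail == "skin_incision"][1]
  loop <- mil$tms[mil$detail == "vessel_loop_passed"]
  completed <- length(loop) == 1L
  totalMs <- if (completed) loop - t0 else limitMs
  tEnd <- t0 + totalMs

  pect <- mil$tms[mil$detail == "pectoralis_minor_divided"]
  pectMs <- if (length(pect)) pect[1] - t0 else NA_real_

  io <- e[e$kind %in% c("instrument_out", "instrument_in"), ]
  idleIvs <- NULL
  for (d in unique(io$detail)) {
    s <- io[io$detail == d, ]
    idleIvs <- rbind(idleIvs, .pairIntervals(s$tms, s$kind, "instrument_out",
                                             "instrument_in", d)$intervals)
  }
  idleMs <- .unionLength(idleIvs, t0, tEnd)

  ct <- e[e$kind %in% c("contact_start", "contact_end"), ]
  activeMs <- .unionLength(.pairIntervals(ct$tms, ct$kind, "contact_start",
                                          "contact_end", "contact")$intervals,
                           t0, tEnd)

  ds <- e[e$kind %in% c("dissection_start", "dissection_end"), ]
  modeMs <- c(blunt = 0, sharp = 0)
  for (mode in c("blunt", "sharp")) {
    idx <- ds$detail == mode
    modeMs[mode] <- .unionLength(
      .pairIntervals(ds$tms[idx], ds$kind[idx], "dissection_start",
                     "dissection_end", mode)$intervals, t0, tEnd)
  }

  pk <- e[e$kind == "instrument_pickup", ]
  changes <- if (nrow(pk) >= 2L) sum(pk$detail[-1L] != pk$detail[-nrow(pk)]) else 0L
  durations <- numeric()
  if (nrow(pk)) {
    useEnd <- c(pk$tms[-1L], tEnd)
    useLen <- pmax(0, pmin(useEnd, tEnd) - pmax(pk$tms, t0))
    durations <- vapply(split(useLen, pk$detail), sum, numeric(1)) / 1000
  }

  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  new("ProcedureMetrics",
      totalTime = totalMs / 1000, idleTime = idleMs / 1000,
      activeTime = activeMs / 1000,
      timeToPectoralisMinor = pectMs / 1000,
      instrumentChanges = as.integer(changes),
      bluntTime = unname(modeMs["blunt"]) / 1000,
      sharpTime = unname(modeMs["sharp"]) / 1000,
      instrumentDurations = durations,
      activeIdleRatio = ratio(activeMs, idleMs),
      sharpBluntRatio = ratio(modeMs[["sharp"]], modeMs[["blunt"]]),
      idlePctOfActive = if (activeMs > 0) 100 * idleMs / activeMs else NA_real_,
      completed = completed, timeLimit = timeLimit(timeline))
}

#' Summarise procedure metrics over a group of operators
#'
#' Per metric field, reports the mean and the [min, max] range, the Table-
#' style panel layout for an operator group. Censored totals (procedures not
#' completed within the time limit, whose total time is only known to exceed
#' it) are excluded from the mean and range and counted in
#' \code{n_censored}; they are never averaged silently. \code{NA} values
#' (e.g. a milestone never reached) are likewise excluded and reflected in
#' \code{n}.
#'
#' @param metricsList list of \code{\linkS4class{ProcedureMetrics}}.
#' @return data.frame with columns \code{field}, \code{mean}, \code{min},
#'   \code{max}, \code{n}, \code{n_censored}.
#' @examples
#' tls <- lapply(c(303, 328), function(tt)
#'   generateTimeline(totalTime = tt, idleTime = 9, activeTime = tt - 8,
#'                    seed = tt))
#' summarizeGroup(lapply(tls, computeMetrics))
#' @export
summarizeGroup <- function(metricsList) {
  if (!length(metricsList)) stop("empty metrics list")
  stopifnot(all(vapply(metricsList, is, logical(1), "ProcedureMetrics")))
  fields <- c("totalTime", "idleTime", "activeTime", "timeToPectoralisMinor",
              "instrumentChanges", "bluntTime", "sharpTime",
              "activeIdleRatio", "sharpBluntRatio", "idlePctOfActive")
  censorable <- c("totalTime", "activeTime")
  rows <- lapply(fields, function(f) {
    vals <- vapply(metricsList, function(m) as.numeric(slot(m, f)), numeric(1))
    cens <- if (f %in% censorable)
      vapply(metricsList, function(m) !m@completed, logical(1))
    else rep(FALSE, length(vals))
    use <- !cens & !is.na(vals)
    data.frame(field = f,
               mean = if (any(use)) mean(vals[use]) else NA_real_,
               min = if (any(use)) min(vals[use]) else NA_real_,
               max = if (any(use)) max(vals[use]) else NA_real_,
               n = sum(use), n_censored = sum(cens))
  })
  do.call(rbind, rows)
}
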