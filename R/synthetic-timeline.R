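## Timeline generator: emits a well-formed ProcedureTimeline whose computed
## metrics reproduce the requested values exactly. All times are drawn on an
## integer millisecond grid (the same grid computeMetrics uses internally),
## which is what makes the round trip exact in floating point.

## check a requested duration sits on the ms grid and return it in ms
.asMs <- function(x, what) {
  if (is.na(x)) return(NA_real_)
  ms <- round(x * 1000)
  if (abs(x * 1000 - ms) > 1e-6)
    stop("'", what, "' must be a whole number of milliseconds, got ", x)
  ms
}

## randomly place bouts of the given ms lengths as disjoint [start, end)
## intervals in [0, span_ms], with at least 1 ms between consecutive bouts
## so start/stop events can never collide on the annotation grid
.placeLengths <- function(lens, span_ms) {
  k <- length(lens)
  free <- span_ms - sum(lens) - (k - 1L)
  stopifnot(free >= 0)
  gapsFree <- as.vector(rmultinom(1L, free, rep(1, k + 1L)))
  if (k > 1L) gapsFree[2:k] <- gapsFree[2:k] + 1L
  starts <- cumsum(c(0, lens[-k])) + cumsum(gapsFree[seq_len(k)])
  cbind(starts, starts + lens)
}

## split total_ms across up to 3 random disjoint bouts in [0, span_ms]
.placeBouts <- function(total_ms, span_ms, meanBout_ms = 5000) {
  if (total_ms == 0) return(NULL)
  k <- max(1L, min(as.integer(total_ms %/% meanBout_ms) + 1L, 3L,
                   as.integer(total_ms), as.integer(span_ms - total_ms) + 1L))
  .placeLengths(.composition(total_ms, k), span_ms)
}

#' Generate a procedure timeline with prescribed metrics
#'
#' Constructs a random, well-formed \code{\linkS4class{ProcedureTimeline}}
#' whose \code{\link{computeMetrics}} output reproduces the requested values
#' exactly: the inverse operation of metric extraction, used to exercise the
#' metrics stage without annotated video. Idle, active and dissection time
#' are realised as randomly placed disjoint bouts summing exactly to the
#' request; instrument changes as a pickup sequence with exactly that many
#' transitions between distinct instruments. All requested durations must be
#' whole milliseconds (the annotation grid). A fixed seed reproduces the
#' timeline exactly.
#'
#' @param totalTime s, incision to vessel-loop passage; required when
#'   \code{completed = TRUE}, ignored otherwise.
#' @param idleTime s of instrument-out time; must not exceed the procedure
#'   span.
#' @param activeTime s of contact time.
#' @param timeToPectoralisMinor s, or \code{NA} if the landmark is never
#'   reached.
#' @param instrumentChanges count of transitions between distinct
#'   instruments.
#' @param bluntTime,sharpTime s of dissection by mode.
#' @param completed logical; \code{FALSE} emits a censored timeline with no
#'   vessel-loop milestone, spanning the full \code{timeLimit}.
#' @param timeLimit s (default 1200).
#' @param seed integer seed.
#' @return A \code{\linkS4class{ProcedureTimeline}}.
#' @examples
#' tl <- generateTimeline(totalTime = 100, idleTime = 15, activeTime = 85,
#'                        instrumentChanges = 3, seed = 7)
#' m <- computeMetrics(tl)
#' c(totalTime(m), idleTime(m), activeTime(m), instrumentChanges(m))
#' @export
generateTimeline <- function(totalTime = NULL, idleTime = 0, activeTime = 0,
                             timeToPectoralisMinor = NA, instrumentChanges = 0L,
                             bluntTime = 0, sharpTime = 0, completed = TRUE,
                             timeLimit = 1200, seed = 1L) {
  if (completed && is.null(totalTime))
    stop("'totalTime' is required for a completed procedure")
  spanMs <- if (completed) .asMs(totalTime, "totalTime")
            else .asMs(timeLimit, "timeLimit")
  idleMs <- .asMs(idleTime, "idleTime")
  activeMs <- .asMs(activeTime, "activeTime")
  pectMs <- .asMs(timeToPectoralisMinor, "timeToPectoralisMinor")
  bluntMs <- .asMs(bluntTime, "bluntTime")
  sharpMs <- .asMs(sharpTime, "sharpTime")
  if (spanMs <= 0) stop("procedure span must be positive")
  if (idleMs > spanMs) stop("idleTime exceeds the procedure span")
  if (activeMs > spanMs) stop("activeTime exceeds the procedure span")
  if (bluntMs + sharpMs > spanMs)
    stop("bluntTime + sharpTime exceeds the procedure span")
  if (!is.na(pectMs) && (pectMs <= 0 || pectMs > spanMs))
    stop("timeToPectoralisMinor must lie inside the procedure span")
  instrumentChanges <- as.integer(instrumentChanges)
  if (instrumentChanges < 0L) stop("instrumentChanges must be >= 0")
  nPickups <- instrumentChanges + 1L
  if (nPickups > spanMs - 1) stop("procedure span too short for the pickups")

  pool <- c("scalpel", "forceps", "scissors", "retractor")
  withr::with_seed(as.integer(seed), {
    ev <- data.frame(time_s = 0, kind = "milestone", detail = "skin_incision")
    if (completed)
      ev <- rbind(ev, data.frame(time_s = spanMs / 1000, kind = "milestone",
                                 detail = "vessel_loop_passed"))
    if (!is.na(pectMs))
      ev <- rbind(ev, data.frame(time_s = pectMs / 1000, kind = "milestone",
                                 detail = "pectoralis_minor_divided"))
    idleIvs <- .placeBouts(idleMs, spanMs)
    if (!is.null(idleIvs))
      ev <- rbind(ev,
        data.frame(time_s = idleIvs[, 1] / 1000, kind = "instrument_out",
                   detail = "instruments"),
        data.frame(time_s = idleIvs[, 2] / 1000, kind = "instrument_in",
                   detail = "instruments"))
    actIvs <- .placeBouts(activeMs, spanMs, meanBout_ms = 30000)
    if (!is.null(actIvs))
      ev <- rbind(ev,
        data.frame(time_s = actIvs[, 1] / 1000, kind = "contact_start",
                   detail = "hands"),
        data.frame(time_s = actIvs[, 2] / 1000, kind = "contact_end",
                   detail = "hands"))
    if (bluntMs + sharpMs > 0) {
      lens <- c(blunt = bluntMs, sharp = sharpMs)
      lens <- lens[lens > 0]
      modes <- names(lens)
      if (length(lens) > 1L) {
        ord <- sample.int(length(lens))
        lens <- lens[ord]; modes <- modes[ord]
      }
      if (spanMs - sum(lens) - (length(lens) - 1L) < 0)
        stop("bluntTime + sharpTime leaves no room between dissection bouts")
      ivs <- .placeLengths(as.numeric(lens), spanMs)
      ev <- rbind(ev,
        data.frame(time_s = ivs[, 1] / 1000, kind = "dissection_start",
                   detail = modes),
        data.frame(time_s = ivs[, 2] / 1000, kind = "dissection_end",
                   detail = modes))
    }
    pkTimes <- sort(sample.int(spanMs - 1L, nPickups))
    pkInst <- pool[(seq_len(nPickups) - 1L) %% length(pool) + 1L]
    ev <- rbind(ev, data.frame(time_s = pkTimes / 1000,
                               kind = "instrument_pickup", detail = pkInst))
    procedureTimeline(ev, timeLimit = timeLimit)
  })
}
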