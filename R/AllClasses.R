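## Central S4 classes. Constructors with argument checking live in the
## module files; validity methods here enforce structural invariants only.

#' ColorSpec: an HSV colour range identifying one glove
#'
#' Describes the hue/saturation/value box used to segment one glove colour.
#' Hue is in degrees and the range may wrap around 0/360 (\code{hueRange[1] >
#' hueRange[2]} means the interval crosses 0). Saturation and value are in
#' [0, 1]. An HSV box rather than an RGB distance is used so that detection is
#' robust to brightness changes across the operating field.
#'
#' @slot name label, conventionally \code{"dominant"} or \code{"nondominant"}.
#' @slot hueRange numeric(2), degrees in [0, 360].
#' @slot satRange numeric(2) in [0, 1], low then high.
#' @slot valRange numeric(2) in [0, 1], low then high.
#' @seealso \code{\link{colorSpec}}, \code{\link{specForColor}}
#' @exportClass ColorSpec
setClass("ColorSpec",
  representation(name = "character", hueRange = "numeric",
                 satRange = "numeric", valRange = "numeric"))

setValidity("ColorSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single label")
  if (length(object@hueRange) != 2L || any(!is.finite(object@hueRange)) ||
      any(object@hueRange < 0) || any(object@hueRange > 360))
    msg <- c(msg, "'hueRange' must be two finite degrees in [0, 360]")
  for (s in c("satRange", "valRange")) {
    r <- slot(object, s)
    if (length(r) != 2L || any(!is.finite(r)) || any(r < 0) || any(r > 1) ||
        r[1] > r[2])
      msg <- c(msg, sprintf("'%s' must be an ordered pair in [0, 1]", s))
  }
  if (length(msg)) msg else TRUE
})

#' MotionProfile: parameters of one synthetic hand-motion trajectory
#'
#' The generative model is a constant-speed heading walk with Poisson
#' direction-change events, per-frame Gaussian positional jitter, and
#' randomly placed idle bouts during which the hand leaves the frame. The
#' jitter scale is the skill dial: smoother (expert-like) motion has small
#' \code{jitterSd}, erratic (novice-like) motion has large \code{jitterSd}.
#'
#' @slot skillLevel one of \code{"expert"}, \code{"resident"}, \code{"novice"}.
#' @slot baseSpeed nominal hand speed, pixels/s.
#' @slot jitterSd per-frame Gaussian perturbation of the step, pixels.
#' @slot directionChangeRate Poisson rate of heading resets, events/s.
#' @slot idleFraction fraction of time the hand is out of frame, in [0, 1].
#' @slot duration trajectory length, s.
#' @slot frameRate frames/s.
#' @slot seed integer seed; a fixed seed gives a bit-identical trajectory.
#' @seealso \code{\link{motionProfile}}, \code{\link{generateTrajectory}}
#' @exportClass MotionProfile
setClass("MotionProfile",
  representation(skillLevel = "character", baseSpeed = "numeric",
                 jitterSd = "numeric", directionChangeRate = "numeric",
                 idleFraction = "numeric", duration = "numeric",
                 frameRate = "numeric", seed = "integer"))

setValidity("MotionProfile", function(object) {
  msg <- character()
  if (!object@skillLevel %in% c("expert", "resident", "novice"))
    msg <- c(msg, "'skillLevel' must be expert, resident or novice")
  if (object@baseSpeed < 0) msg <- c(msg, "'baseSpeed' must be >= 0")
  if (object@jitterSd < 0) msg <- c(msg, "'jitterSd' must be >= 0")
  if (object@directionChangeRate < 0)
    msg <- c(msg, "'directionChangeRate' must be >= 0")
  if (object@idleFraction < 0 || object@idleFraction > 1)
    msg <- c(msg, "'idleFraction' must be in [0, 1]")
  if (object@duration <= 0) msg <- c(msg, "'duration' must be > 0")
  if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be > 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' SyntheticScene: rendering parameters for synthetic glove videos
#'
#' @slot frameSize integer(2), width and height in pixels.
#' @slot gloveColors 2 x 3 RGB matrix in [0, 1], rows named
#'   \code{"dominant"} and \code{"nondominant"}.
#' @slot distractorColors n x 3 RGB matrix (possibly 0 rows) of additional
#'   blob colours that must not be confused with the gloves.
#' @slot blobRadius glove blob radius, pixels.
#' @slot background length-3 RGB background colour.
#' @slot hueHalfWidth half-width, degrees, of the hue window implied around
#'   each colour; all glove and distractor hues must be pairwise separable
#'   under these windows (checked by validity).
#' @seealso \code{\link{syntheticScene}}, \code{\link{renderVideo}}
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(frameSize = "integer", gloveColors = "matrix",
                 distractorColors = "matrix", blobRadius = "numeric",
                 background = "numeric", hueHalfWidth = "numeric"))

setValidity("SyntheticScene", function(object) {
  msg <- character()
  if (length(object@frameSize) != 2L || any(object@frameSize < 16L))
    msg <- c(msg, "'frameSize' must be width, height >= 16 pixels")
  gc <- object@gloveColors
  if (!is.numeric(gc) || nrow(gc) != 2L || ncol(gc) != 3L ||
      !identical(rownames(gc), c("dominant", "nondominant")))
    msg <- c(msg, "'gloveColors' must be a 2x3 RGB matrix with rows dominant, nondominant")
  dc <- object@distractorColors
  if (!is.numeric(dc) || ncol(dc) != 3L)
    msg <- c(msg, "'distractorColors' must be an n x 3 RGB matrix")
  if (object@blobRadius <= 0) msg <- c(msg, "'blobRadius' must be > 0")
  if (object@blobRadius * 2 >= min(object@frameSize))
    msg <- c(msg, "'blobRadius' too large for the frame")
  if (length(object@background) != 3L)
    msg <- c(msg, "'background' must be a length-3 RGB colour")
  if (!length(msg)) {
    cols <- rbind(gc, dc)
    hues <- apply(cols, 1L, function(p)
      360 * grDevices::rgb2hsv(p[1], p[2], p[3], maxColorValue = 1)[1, 1])
    hw <- object@hueHalfWidth
    for (i in seq_along(hues)) for (j in seq_len(i - 1L)) {
      d <- abs(hues[i] - hues[j]); d <- min(d, 360 - d)
      if (d < 2 * hw)
        msg <- c(msg, sprintf(
          "colours %d and %d are not hue-separable (hues %.1f and %.1f within 2x%.0f deg)",
          i, j, hues[i], hues[j], hw))
    }
  }
  if (length(msg)) msg else TRUE
})

#' HandTrack: per-frame positions of one hand
#'
#' One record per video frame, valid or not. Both the tracker output and the
#' synthetic ground truth use this container; ground-truth tracks leave the
#' bounding-box and pixel-count columns \code{NA}. Coordinates are pixels,
#' origin at the top-left corner, x rightwards, y downwards, frame indices
#' 0-based. \code{gaps} lists the maximal runs of invalid frames as 0-based
#' inclusive [start, end] intervals and exactly partitions the invalid frames.
#'
#' @slot hand label, \code{"dominant"} or \code{"nondominant"}.
#' @slot frameRate frames/s.
#' @slot detections data.frame with columns \code{frame_index}, \code{hand},
#'   \code{valid}, \code{x}, \code{y}, \code{bbox_x0}, \code{bbox_y0},
#'   \code{bbox_x1}, \code{bbox_y1}, \code{pixel_count}.
#' @slot gaps integer matrix with columns \code{start}, \code{end}.
#' @seealso \code{\link{handTrack}}, \code{\link{trackVideo}}
#' @exportClass HandTrack
setClass("HandTrack",
  representation(hand = "character", frameRate = "numeric",
                 detections = "data.frame", gaps = "matrix"))

setValidity("HandTrack", function(object) {
  msg <- character()
  d <- object@detections
  need <- c("frame_index", "hand", "valid", "x", "y", "bbox_x0", "bbox_y0",
            "bbox_x1", "bbox_y1", "pixel_count")
  if (!all(need %in% names(d)))
    return(paste("detections must have columns:", paste(need, collapse = ", ")))
  n <- nrow(d)
  if (n > 0L && !identical(as.integer(d$frame_index), 0:(n - 1L)))
    msg <- c(msg, "exactly one detection per frame: frame_index must be 0..n-1")
  if (any(!d$valid & (!is.na(d$x) | !is.na(d$y))))
    msg <- c(msg, "invalid detections must have NA centroid")
  if (any(d$valid & (is.na(d$x) | is.na(d$y))))
    msg <- c(msg, "valid detections must have a finite centroid")
  if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be > 0")
  exp_gaps <- .invalidRuns(d$valid)
  if (!identical(object@gaps, exp_gaps))
    msg <- c(msg, "'gaps' must exactly partition the invalid frames")
  if (length(msg)) msg else TRUE
})

#' KinematicSeries: 1 Hz kinematics of one hand
#'
#' All three series live on the same 1 Hz grid of \code{floor(duration)}
#' samples at times 0, 1, ... s. \code{speed[k]} is the displacement between
#' the second-k and second-(k+1) mean positions (pixels/s);
#' \code{acceleration[k] = speed[k+1] - speed[k]}; \code{directionChange[k]}
#' is the unsigned angle in degrees, in [0, 180], between the displacement
#' vectors of seconds k and k+1. Samples that touch an invalid position, a
#' zero displacement (undefined direction) or the end of the grid are
#' \code{NA}; \code{validMask} records position validity per second.
#'
#' @slot hand label.
#' @slot times numeric, seconds (0-based grid).
#' @slot speed numeric, pixels/s, \code{NA} where undefined.
#' @slot acceleration numeric, pixels/s per s, \code{NA} where undefined.
#' @slot directionChange numeric degrees in [0, 180], \code{NA} where undefined.
#' @slot validMask logical, position validity per second.
#' @seealso \code{\link{computeKinematics}}, \code{\link{kinematicSeries}}
#' @exportClass KinematicSeries
setClass("KinematicSeries",
  representation(hand = "character", times = "numeric", speed = "numeric",
                 acceleration = "numeric", directionChange = "numeric",
                 validMask = "logical"))

setValidity("KinematicSeries", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@speed) != n || length(object@acceleration) != n ||
      length(object@directionChange) != n || length(object@validMask) != n)
    msg <- c(msg, "all series must share the 1 Hz grid length")
  if (any(object@speed < 0, na.rm = TRUE)) msg <- c(msg, "speed must be >= 0")
  dc <- object@directionChange
  if (any(dc < 0 | dc > 180, na.rm = TRUE))
    msg <- c(msg, "directionChange must be in [0, 180] degrees")
  if (length(msg)) msg else TRUE
})

#' BinningSpec: discretisation of one kinematic feature
#'
#' Entropy is computed on a joint histogram; this class records how samples
#' map to bins. Edges are strictly increasing; samples outside the edge range
#' are clipped into the first/last bin so every finite sample maps to exactly
#' one bin. The logarithm base is fixed at 2 (entropies in bits).
#'
#' @slot feature one of \code{"speed"}, \code{"acceleration"},
#'   \code{"direction"}.
#' @slot nBins integer >= 2.
#' @slot edges numeric of length \code{nBins + 1}, strictly increasing.
#' @slot probs the percentile pair used to derive the edge range when the
#'   edges were data-driven (empty for fixed edges).
#' @seealso \code{\link{binningSpec}}, \code{\link{makeBinning}}
#' @exportClass BinningSpec
setClass("BinningSpec",
  representation(feature = "character", nBins = "integer", edges = "numeric",
                 probs = "numeric"))

setValidity("BinningSpec", function(object) {
  msg <- character()
  if (!object@feature %in% c("speed", "acceleration", "direction"))
    msg <- c(msg, "'feature' must be speed, acceleration or direction")
  if (object@nBins < 2L) msg <- c(msg, "'nBins' must be >= 2")
  if (length(object@edges) != object@nBins + 1L)
    msg <- c(msg, "'edges' must have nBins + 1 entries")
  else if (any(diff(object@edges) <= 0))
    msg <- c(msg, "'edges' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' JointEntropyTriplet: the three bimanual joint entropies of one operator
#'
#' One Shannon joint entropy (bits) per kinematic feature, computed from the
#' pairwise-valid samples of the dominant and non-dominant hand series. A
#' feature with no valid pairs is \code{NA} with the reason in \code{status}
#' (never reported as 0, which would mean perfectly regular motion).
#'
#' @slot speedH,accelerationH,directionH joint entropies in bits (\code{NA}
#'   if undefined).
#' @slot nSamples named integer, valid pair count per feature.
#' @slot binning named list of \code{\link{BinningSpec}} (or \code{NULL}
#'   where undefined) per feature.
#' @slot status named character, \code{"ok"} or the reason a feature is
#'   undefined.
#' @seealso \code{\link{operatorEntropy}}
#' @exportClass JointEntropyTriplet
setClass("JointEntropyTriplet",
  representation(speedH = "numeric", accelerationH = "numeric",
                 directionH = "numeric", nSamples = "integer",
                 binning = "list", status = "character"))

setValidity("JointEntropyTriplet", function(object) {
  msg <- character()
  hs <- c(speed = object@speedH, acceleration = object@accelerationH,
          direction = object@directionH)
  for (f in names(hs)) {
    b <- object@binning[[f]]
    if (!is.null(b) && !is.na(hs[[f]])) {
      if (hs[[f]] < -1e-12 || hs[[f]] > 2 * log2(b@nBins) + 1e-12)
        msg <- c(msg, sprintf("%s entropy outside [0, 2*log2(nBins)]", f))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ProcedureTimeline: timestamped events of one procedure
#'
#' Ordered event records with times in seconds from video start. Event kinds:
#' \code{milestone} (details \code{skin_incision},
#' \code{pectoralis_minor_divided}, \code{vessel_loop_passed}),
#' \code{contact_start}/\code{contact_end} (hand or instrument on the
#' specimen), \code{instrument_out}/\code{instrument_in} (instruments leaving
#' and re-entering the incision; their paired intervals are idle time),
#' \code{instrument_pickup} (detail = instrument identity) and
#' \code{dissection_start}/\code{dissection_end} (detail \code{blunt} or
#' \code{sharp}). All intervals are half-open [start, end). The constructor
#' sorts events by time; deeper semantic checks are in
#' \code{\link{validateTimeline}}.
#'
#' @slot events data.frame with columns \code{time_s}, \code{kind},
#'   \code{detail}.
#' @slot timeLimit procedure time cap in seconds (default 1200 s, i.e. the
#'   20-minute limit); totals are censored at this value.
#' @seealso \code{\link{procedureTimeline}}, \code{\link{computeMetrics}}
#' @exportClass ProcedureTimeline
setClass("ProcedureTimeline",
  representation(events = "data.frame", timeLimit = "numeric"))

.timelineKinds <- c("milestone", "contact_start", "contact_end",
                    "instrument_in", "instrument_out", "instrument_pickup",
                    "dissection_start", "dissection_end")

setValidity("ProcedureTimeline", function(object) {
  msg <- character()
  e <- object@events
  if (!all(c("time_s", "kind", "detail") %in% names(e)))
    return("events must have columns time_s, kind, detail")
  if (nrow(e)) {
    if (any(!is.finite(e$time_s)) || any(e$time_s < 0))
      msg <- c(msg, "event times must be finite and >= 0")
    if (is.unsorted(e$time_s)) msg <- c(msg, "event times must be non-decreasing")
    bad <- setdiff(unique(e$kind), .timelineKinds)
    if (length(bad))
      msg <- c(msg, paste("unknown event kind(s):", paste(bad, collapse = ", ")))
  }
  if (length(object@timeLimit) != 1L || object@timeLimit <= 0)
    msg <- c(msg, "'timeLimit' must be a single positive number of seconds")
  if (length(msg)) msg else TRUE
})

#' ProcedureMetrics: the eight observational timing metrics of one procedure
#'
#' Computed from a \code{\link{ProcedureTimeline}}. When the vessel-loop
#' milestone is absent the procedure is censored at the time limit:
#' \code{completed} is \code{FALSE} and \code{totalTime} holds the limit as a
#' "> limit" sentinel, which is never averaged silently (see
#' \code{\link{summarizeGroup}}). Ratios with a zero denominator are
#' \code{NA}. Idle and active time come from different event families
#' (instrument-out vs contact intervals) and need not add up to the total.
#'
#' @slot totalTime s, skin incision to vessel-loop passage (or the limit).
#' @slot idleTime s, union of instrument-out intervals.
#' @slot activeTime s, union of contact intervals.
#' @slot timeToPectoralisMinor s, incision to pectoralis-minor division
#'   (\code{NA} if the landmark was never reached).
#' @slot instrumentChanges count of transitions between distinct instruments
#'   in pickup order (re-picking the same instrument is not a change).
#' @slot bluntTime,sharpTime s of blunt and sharp dissection.
#' @slot instrumentDurations named numeric, seconds each instrument was in
#'   use (pickup to next pickup).
#' @slot activeIdleRatio,sharpBluntRatio,idlePctOfActive derived ratios;
#'   \code{idlePctOfActive} is a percentage.
#' @slot completed logical; \code{FALSE} means censored at \code{timeLimit}.
#' @slot timeLimit s.
#' @seealso \code{\link{computeMetrics}}, \code{\link{generateTimeline}}
#' @exportClass ProcedureMetrics
setClass("ProcedureMetrics",
  representation(totalTime = "numeric", idleTime = "numeric",
                 activeTime = "numeric", timeToPectoralisMinor = "numeric",
                 instrumentChanges = "integer", bluntTime = "numeric",
                 sharpTime = "numeric", instrumentDurations = "numeric",
                 activeIdleRatio = "numeric", sharpBluntRatio = "numeric",
                 idlePctOfActive = "numeric", completed = "logical",
                 timeLimit = "numeric"))

setValidity("ProcedureMetrics", function(object) {
  msg <- character()
  for (s in c("totalTime", "idleTime", "activeTime", "bluntTime", "sharpTime"))
    if (!is.na(slot(object, s)) && slot(object, s) < 0)
      msg <- c(msg, sprintf("'%s' must be >= 0", s))
  if (!is.na(object@instrumentChanges) && object@instrumentChanges < 0L)
    msg <- c(msg, "'instrumentChanges' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' OperatorReport: per-operator results with provenance
#'
#' Bundles the entropy triplet and/or procedure metrics of one operator with
#' machine-readable provenance: input file hashes, the configuration
#' snapshot, and the package version. Missing sections carry a reason (for
#' example, no glove data was recorded), mirroring how missing entropy is
#' reported as not-available rather than zero.
#'
#' @slot operatorId,group labels.
#' @slot entropy \code{\link{JointEntropyTriplet}} or \code{NULL}.
#' @slot metrics \code{\link{ProcedureMetrics}} or \code{NULL}.
#' @slot status named character reasons for absent sections.
#' @slot provenance list with elements \code{inputs} (named md5 hashes),
#'   \code{config} (snapshot) and \code{version}.
#' @seealso \code{\link{runPipeline}}
#' @exportClass OperatorReport
setClass("OperatorReport",
  representation(operatorId = "character", group = "character",
                 entropy = "ANY", metrics = "ANY", status = "character",
                 provenance = "list"))

setValidity("OperatorReport", function(object) {
  msg <- character()
  if (!all(c("inputs", "config", "version") %in% names(object@provenance)))
    msg <- c(msg, "provenance must contain inputs, config and version")
  if (!is.null(object@entropy) && !is(object@entropy, "JointEntropyTriplet"))
    msg <- c(msg, "'entropy' must be a JointEntropyTriplet or NULL")
  if (!is.null(object@metrics) && !is(object@metrics, "ProcedureMetrics"))
    msg <- c(msg, "'metrics' must be a ProcedureMetrics or NULL")
  if (length(msg)) msg else TRUE
})

## maximal runs of FALSE in a validity vector, as 0-based inclusive intervals
.invalidRuns <- function(valid) {
  if (!length(valid))
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  m <- cbind(start = starts[keep] - 1L, end = ends[keep] - 1L)
  storage.mode(m) <- "integer"
  m
}
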