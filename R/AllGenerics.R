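## Generics and accessors. Slot access from user code should go through
## these, never through @.

#' @export
setGeneric("hand", function(x) standardGeneric("hand"))
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))
#' @export
setGeneric("gaps", function(x) standardGeneric("gaps"))
#' @export
setGeneric("speed", function(x) standardGeneric("speed"))
#' @export
setGeneric("acceleration", function(x) standardGeneric("acceleration"))
#' @export
setGeneric("directionChange", function(x) standardGeneric("directionChange"))
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @export
setGeneric("speedH", function(x) standardGeneric("speedH"))
#' @export
setGeneric("accelerationH", function(x) standardGeneric("accelerationH"))
#' @export
setGeneric("directionH", function(x) standardGeneric("directionH"))
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("binning", function(x) standardGeneric("binning"))
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @export
setGeneric("timeLimit", function(x) standardGeneric("timeLimit"))
#' @export
setGeneric("totalTime", function(x) standardGeneric("totalTime"))
#' @export
setGeneric("idleTime", function(x) standardGeneric("idleTime"))
#' @export
setGeneric("activeTime", function(x) standardGeneric("activeTime"))
#' @export
setGeneric("instrumentChanges", function(x) standardGeneric("instrumentChanges"))
#' @export
setGeneric("isCompleted", function(x) standardGeneric("isCompleted"))

#' Accessors for handmotion classes
#'
#' Read-only accessors for the central classes: \code{hand}, \code{frameRate},
#' \code{detections} and \code{gaps} for \code{\linkS4class{HandTrack}};
#' \code{speed}, \code{acceleration}, \code{directionChange} and
#' \code{validMask} for \code{\linkS4class{KinematicSeries}}; \code{speedH},
#' \code{accelerationH}, \code{directionH}, \code{nSamples} and
#' \code{binning} for \code{\linkS4class{JointEntropyTriplet}};
#' \code{events} and \code{timeLimit} for
#' \code{\linkS4class{ProcedureTimeline}}; \code{totalTime}, \code{idleTime},
#' \code{activeTime}, \code{instrumentChanges} and \code{isCompleted} for
#' \code{\linkS4class{ProcedureMetrics}}.
#'
#' @param x an object of the matching class.
#' @return The slot value.
#' @name accessors
#' @aliases hand frameRate detections gaps speed acceleration directionChange
#'   validMask speedH accelerationH directionH nSamples binning events
#'   timeLimit totalTime idleTime activeTime instrumentChanges isCompleted
#' @examples
#' tl <- generateTimeline(totalTime = 100, idleTime = 15, activeTime = 85,
#'                        seed = 1)
#' m <- computeMetrics(tl)
#' totalTime(m); idleTime(m); activeTime(m)
NULL

setMethod("hand", "HandTrack", function(x) x@hand)
setMethod("frameRate", "HandTrack", function(x) x@frameRate)
setMethod("detections", "HandTrack", function(x) x@detections)
setMethod("gaps", "HandTrack", function(x) x@gaps)

setMethod("hand", "KinematicSeries", function(x) x@hand)
setMethod("speed", "KinematicSeries", function(x) x@speed)
setMethod("acceleration", "KinematicSeries", function(x) x@acceleration)
setMethod("directionChange", "KinematicSeries", function(x) x@directionChange)
setMethod("validMask", "KinematicSeries", function(x) x@validMask)

setMethod("speedH", "JointEntropyTriplet", function(x) x@speedH)
setMethod("accelerationH", "JointEntropyTriplet", function(x) x@accelerationH)
setMethod("directionH", "JointEntropyTriplet", function(x) x@directionH)
setMethod("nSamples", "JointEntropyTriplet", function(x) x@nSamples)
setMethod("binning", "JointEntropyTriplet", function(x) x@binning)

setMethod("events", "ProcedureTimeline", function(x) x@events)
setMethod("timeLimit", "ProcedureTimeline", function(x) x@timeLimit)

setMethod("totalTime", "ProcedureMetrics", function(x) x@totalTime)
setMethod("idleTime", "ProcedureMetrics", function(x) x@idleTime)
setMethod("activeTime", "ProcedureMetrics", function(x) x@activeTime)
setMethod("instrumentChanges", "ProcedureMetrics", function(x) x@instrumentChanges)
setMethod("isCompleted", "ProcedureMetrics", function(x) x@completed)
setMethod("timeLimit", "ProcedureMetrics", function(x) x@timeLimit)
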