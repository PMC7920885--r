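.fmtRange <- function(r) sprintf("[%.3g, %.3g]", r[1], r[2])

setMethod("show", "ColorSpec", function(object) {
  cat(sprintf("ColorSpec '%s': hue %s deg, sat %s, val %s\n", object@name,
              .fmtRange(object@hueRange), .fmtRange(object@satRange),
              .fmtRange(object@valRange)))
})

setMethod("show", "MotionProfile", function(object) {
  cat(sprintf(
    "MotionProfile (%s): %.0f px/s, jitter %.1f px, dir-change %.2f /s,\n  idle %.2f, %.0f s @ %.0f fps, seed %d\n",
    object@skillLevel, object@baseSpeed, object@jitterSd,
    object@directionChangeRate, object@idleFraction, object@duration,
    object@frameRate, object@seed))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene %dx%d px, blob radius %.0f px, %d distractor colour(s)\n",
              object@frameSize[1], object@frameSize[2], object@blobRadius,
              nrow(object@distractorColors)))
})

setMethod("show", "HandTrack", function(object) {
  d <- object@detections
  cat(sprintf("HandTrack '%s': %d frames @ %.0f fps, %d valid (%.1f%%), %d gap(s)\n",
              object@hand, nrow(d), object@frameRate, sum(d$valid),
              if (nrow(d)) 100 * mean(d$valid) else 0, nrow(object@gaps)))
})

setMethod("show", "KinematicSeries", function(object) {
  cat(sprintf("KinematicSeries '%s': %d s, %d valid positions, mean speed %.1f px/s\n",
              object@hand, length(object@times), sum(object@validMask),
              mean(object@speed, na.rm = TRUE)))
})

setMethod("show", "BinningSpec", function(object) {
  cat(sprintf("BinningSpec (%s): %d bins over [%.3g, %.3g]\n", object@feature,
              object@nBins, min(object@edges), max(object@edges)))
})

setMethod("show", "JointEntropyTriplet", function(object) {
  fmt <- function(h) if (is.na(h)) "NA" else sprintf("%.2f", h)
  cat(sprintf("Joint entropy (speed/acceleration/direction): %s/%s/%s bits\n",
              fmt(object@speedH), fmt(object@accelerationH),
              fmt(object@directionH)))
  bad <- object@status[object@status != "ok"]
  for (f in names(bad)) cat(sprintf("  %s: %s\n", f, bad[f]))
  cat(sprintf("  n = %s valid pairs\n",
              paste(object@nSamples, collapse = "/")))
})

setMethod("show", "ProcedureTimeline", function(object) {
  cat(sprintf("ProcedureTimeline: %d events over %.1f s (limit %.0f s)\n",
              nrow(object@events),
              if (nrow(object@events)) max(object@events$time_s) else 0,
              object@timeLimit))
})

setMethod("show", "ProcedureMetrics", function(object) {
  tot <- if (object@completed) sprintf("%.1f s", object@totalTime)
         else sprintf("> %.0f s (not completed)", object@timeLimit)
  cat("ProcedureMetrics\n")
  cat(sprintf("  total %s, idle %.1f s, active %.1f s\n", tot,
              object@idleTime, object@activeTime))
  cat(sprintf("  to pectoralis minor: %s s, instrument changes: %d\n",
              ifelse(is.na(object@timeToPectoralisMinor), "NA",
                     sprintf("%.1f", object@timeToPectoralisMinor)),
              object@instrumentChanges))
  cat(sprintf("  dissection blunt %.1f s / sharp %.1f s\n", object@bluntTime,
              object@sharpTime))
})

setMethod("show", "OperatorReport", function(object) {
  cat(sprintf("OperatorReport '%s' (group %s): entropy %s, metrics %s\n",
              object@operatorId, object@group,
              if (is.null(object@entropy)) "absent" else "present",
              if (is.null(object@metrics)) "absent" else "present"))
})
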