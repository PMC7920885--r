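## Synthetic hand-motion generator. The model is a constant-speed heading
## walk: the heading is piecewise constant, reset at Poisson-distributed
## change events; every frame step gets isotropic Gaussian jitter; the free
## trajectory is folded into the frame by reflection; idle bouts (hand out
## of frame, position frozen) are placed by exact random composition so the
## realised idle fraction matches the request up to frame quantisation.

## skill presets: the jitter ladder is the skill dial (expert smoothest);
## idle fractions mirror the few-percent idle-to-active proportions seen in
## observational review of this procedure. The ladder spans the responsive
## region of the entropy-vs-jitter curve at the default base speed, a design
## requirement of the generator (the jitter -> entropy map must be monotone).
.skillPresets <- list(
  expert   = list(jitterSd = 2,  idleFraction = 0.03),
  resident = list(jitterSd = 5,  idleFraction = 0.06),
  novice   = list(jitterSd = 20, idleFraction = 0.08))

#' Construct a synthetic motion profile
#'
#' Unspecified \code{jitterSd} / \code{idleFraction} default to the preset of
#' the requested skill level: jitter 2 / 5 / 20 pixels and idle fraction
#' 0.03 / 0.06 / 0.08 for expert / resident / novice. Base speed and
#' direction-change rate are skill-independent by default, so the jitter
#' scale alone orders the skill levels. The default base speed (400
#' pixels/s, unhurried gross hand motion under an overhead consumer camera
#' at UHD scale) and direction-change rate (one purposeful heading change
#' every 5 s) keep the preset jitter ladder inside the responsive part of
#' the entropy-vs-jitter curve.
#'
#' @param skillLevel \code{"expert"}, \code{"resident"} or \code{"novice"}.
#' @param baseSpeed nominal speed, pixels/s.
#' @param jitterSd per-frame Gaussian step perturbation, pixels.
#' @param directionChangeRate heading reset rate, events/s.
#' @param idleFraction fraction of time out of frame, in [0, 1].
#' @param duration s.
#' @param frameRate frames/s.
#' @param seed integer; all randomness of a generator call flows from it.
#' @return A \code{\linkS4class{MotionProfile}}.
#' @examples
#' motionProfile("expert", duration = 60, seed = 1)
#' @export
motionProfile <- function(skillLevel = c("resident", "expert", "novice"),
                          baseSpeed = 400, jitterSd = NULL,
                          directionChangeRate = 0.2, idleFraction = NULL,
                          duration = 600, frameRate = 50, seed = 1L) {
  skillLevel <- match.arg(skillLevel)
  preset <- .skillPresets[[skillLevel]]
  if (is.null(jitterSd)) jitterSd <- preset$jitterSd
  if (is.null(idleFraction)) idleFraction <- preset$idleFraction
  new("MotionProfile", skillLevel = skillLevel,
      baseSpeed = as.numeric(baseSpeed), jitterSd = as.numeric(jitterSd),
      directionChangeRate = as.numeric(directionChangeRate),
      idleFraction = as.numeric(idleFraction), duration = as.numeric(duration),
      frameRate = as.numeric(frameRate), seed = as.integer(seed))
}

## k positive integers summing to total (total >= k), drawn uniformly
.composition <- function(total, k) {
  total <- as.integer(total); k <- as.integer(k)
  if (k == 1L) return(total)
  cuts <- sort(sample.int(total - 1L, k - 1L))
  diff(c(0L, cuts, total))
}

## fold a free coordinate into [lo, hi] by reflection
.fold <- function(z, lo, hi) {
  p <- 2 * (hi - lo)
  w <- (z - lo) %% p
  lo + ifelse(w > hi - lo, p - w, w)
}

## idle mask of length n with exactly round(f*n) idle frames in random bouts
.idleMask <- function(n, f, frameRate) {
  idle <- rep(FALSE, n)
  idleN <- as.integer(round(f * n))
  if (idleN >= n) return(rep(TRUE, n))
  if (idleN == 0L) return(idle)
  k <- max(1L, min(as.integer(round(idleN / (4 * frameRate))), idleN))
  lens <- .composition(idleN, k)
  gapsFree <- as.vector(rmultinom(1L, n - idleN, rep(1, k + 1L)))
  pos <- 0L
  for (j in seq_len(k)) {
    pos <- pos + gapsFree[j]
    idle[(pos + 1L):(pos + lens[j])] <- TRUE
    pos <- pos + lens[j]
  }
  idle
}

.genOneHand <- function(profile, scene, handLabel, start, xBounds) {
  fr <- profile@frameRate
  n <- as.integer(round(profile@duration * fr))
  if (n < 1L) stop("profile duration too short for one frame")
  dt <- 1 / fr
  idle <- .idleMask(n, profile@idleFraction, fr)
  nChanges <- min(rpois(1L, profile@directionChangeRate * profile@duration), n)
  changeAt <- if (nChanges > 0L) sort(sample.int(n, nChanges)) else integer()
  headings <- runif(nChanges + 1L, 0, 2 * pi)
  phi <- headings[findInterval(seq_len(n), changeAt) + 1L]
  step <- cbind(cos(phi), sin(phi)) * (profile@baseSpeed * dt) +
    matrix(rnorm(2L * n, 0, profile@jitterSd), ncol = 2L)
  step[idle, ] <- 0
  h <- scene@frameSize[2]; m <- scene@blobRadius
  x <- .fold(start[1] + c(0, cumsum(step[, 1]))[seq_len(n)], xBounds[1], xBounds[2])
  y <- .fold(start[2] + c(0, cumsum(step[, 2]))[seq_len(n)], m, h - 1 - m)
  x[idle] <- NA_real_; y[idle] <- NA_real_
  handTrack(handLabel, fr,
            data.frame(frame_index = 0:(n - 1L), hand = handLabel,
                       valid = !idle, x = x, y = y))
}

#' Generate ground-truth trajectories for two hands
#'
#' Draws one trajectory per hand from the motion model of \code{profile}
#' (see \code{\linkS4class{MotionProfile}}). The dominant hand works the
#' left half of the frame and the non-dominant hand the right half (as the
#' two hands flank the incision under an overhead camera); with the blob
#' radius as margin the two rendered blobs can touch but never occlude one
#' another. Positions stay at least one blob radius from the frame edge;
#' idle bouts appear as invalid frames (hand out of view, position frozen
#' until it re-enters). A fixed seed reproduces the trajectories bit for
#' bit.
#'
#' @param profile a \code{\linkS4class{MotionProfile}}.
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @return Named list of two ground-truth \code{\linkS4class{HandTrack}}
#'   objects (\code{dominant}, \code{nondominant}).
#' @examples
#' sc <- syntheticScene(frameSize = c(320, 240))
#' tr <- generateTrajectory(motionProfile("expert", duration = 5, seed = 3), sc)
#' head(detections(tr$dominant))
#' @export
generateTrajectory <- function(profile, scene) {
  stopifnot(is(profile, "MotionProfile"), is(scene, "SyntheticScene"))
  validObject(profile); validObject(scene)
  w <- scene@frameSize[1]; h <- scene@frameSize[2]; m <- scene@blobRadius
  if (w / 2 <= 2 * m) stop("frame too narrow for two non-overlapping hands")
  withr::with_seed(profile@seed, {
    dom <- .genOneHand(profile, scene, "dominant", c(0.25 * w, 0.5 * h),
                       xBounds = c(m, w / 2 - m))
    nond <- .genOneHand(profile, scene, "nondominant", c(0.75 * w, 0.5 * h),
                        xBounds = c(w / 2 + m, w - 1 - m))
    list(dominant = dom, nondominant = nond)
  })
}
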