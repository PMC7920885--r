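#' Resample a hand track to 1 Hz positions
#'
#' The position at second k is the mean of the valid per-frame centroids
#' with timestamps in [k, k+1). A second is marked invalid when fewer than
#' half of its frames carry a valid detection; averaging within the second
#' suppresses detector pixel noise that frame-rate differencing would
#' amplify. No interpolation is performed across invalid seconds: time the
#' hands spend out of view is meaningful signal in this domain, not noise
#' to impute.
#'
#' @param track a \code{\linkS4class{HandTrack}}.
#' @param minValidFraction minimum fraction of valid frames for a second to
#'   be valid (default 0.5).
#' @return data.frame with columns \code{t} (s, 0-based), \code{x}, \code{y}
#'   (pixels, \code{NA} when invalid), \code{valid}, \code{n_valid_frames}.
#' @export
resampleTrack <- function(track, minValidFraction = 0.5) {
  stopifnot(is(track, "HandTrack"))
  d <- detections(track)
  if (!nrow(d)) stop("zero-length track")
  fr <- frameRate(track)
  sec <- floor(d$frame_index / fr)
  nSec <- floor(nrow(d) / fr)
  if (nSec < 1L) stop("track shorter than one second")
  out <- data.frame(t = 0:(nSec - 1L), x = NA_real_, y = NA_real_,
                    valid = FALSE, n_valid_frames = 0L)
  for (k in 0:(nSec - 1L)) {
    inSec <- sec == k
    ok <- inSec & d$valid
    nOk <- sum(ok)
    out$n_valid_frames[k + 1L] <- nOk
    if (nOk >= minValidFraction * sum(inSec) && nOk > 0L) {
      out$x[k + 1L] <- mean(d$x[ok])
      out$y[k + 1L] <- mean(d$y[ok])
      out$valid[k + 1L] <- TRUE
    }
  }
  out
}

#' Compute 1 Hz kinematics from per-second positions
#'
#' Given positions p(k) on the 1 Hz grid, the series are
#' \code{speed[k] = |p(k+1) - p(k)|} in pixels/s,
#' \code{acceleration[k] = speed[k+1] - speed[k]}, and
#' \code{directionChange[k]}, the unsigned angle in degrees between the
#' displacement vectors p(k) to p(k+1) and p(k+1) to p(k+2). A sample is
#' \code{NA} whenever any position it touches is invalid; the direction
#' change is also \code{NA} when either displacement is exactly zero (a
#' still hand has no direction, and reporting 0 degrees would fabricate
#' directional stability from stillness).
#'
#' Speed and acceleration are invariant to rotating or translating the
#' coordinate frame and scale linearly with a rescaling of pixel units;
#' the direction change is invariant to all three.
#'
#' @param positions data.frame as returned by \code{\link{resampleTrack}}
#'   (columns \code{t}, \code{x}, \code{y}, \code{valid}).
#' @param hand hand label recorded in the result.
#' @return A \code{\linkS4class{KinematicSeries}}.
#' @examples
#' p <- data.frame(t = 0:2, x = c(0, 100, 100), y = c(0, 0, 100),
#'                 valid = TRUE)
#' ks <- computeKinematics(p, "dominant")
#' speed(ks); directionChange(ks)  # 100, 100, NA and NA, 90, NA
#' @export
computeKinematics <- function(positions, hand = "hand") {
  stopifnot(all(c("t", "x", "y", "valid") %in% names(positions)))
  n <- nrow(positions)
  x <- positions$x; y <- positions$y
  v <- positions$valid & !is.na(x) & !is.na(y)
  sp <- acc <- th <- rep(NA_real_, n)
  if (n >= 2L) {
    dx <- x[-1L] - x[-n]; dy <- y[-1L] - y[-n]
    pairOk <- v[-n] & v[-1L]
    sp[seq_len(n - 1L)][pairOk] <- sqrt(dx^2 + dy^2)[pairOk]
  }
  if (n >= 3L) {
    acc[seq_len(n - 2L)] <- sp[2:(n - 1L)] - sp[seq_len(n - 2L)]
    for (k in seq_len(n - 2L)) {
      if (is.na(sp[k]) || is.na(sp[k + 1L])) next
      v1 <- c(x[k + 1L] - x[k], y[k + 1L] - y[k])
      v2 <- c(x[k + 2L] - x[k + 1L], y[k + 2L] - y[k + 1L])
      n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
      if (n1 == 0 || n2 == 0) next  # undefined for zero displacement
      th[k] <- acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
    }
  }
  new("KinematicSeries", hand = as.character(hand),
      times = as.numeric(positions$t), speed = sp, acceleration = acc,
      directionChange = th, validMask = v)
}

#' Kinematic series of a hand track
#'
#' Convenience composition of \code{\link{resampleTrack}} and
#' \code{\link{computeKinematics}}.
#'
#' @param track a \code{\linkS4class{HandTrack}}.
#' @param minValidFraction passed to \code{\link{resampleTrack}}.
#' @return A \code{\linkS4class{KinematicSeries}}.
#' @export
kinematicSeries <- function(track, minValidFraction = 0.5) {
  computeKinematics(resampleTrack(track, minValidFraction), hand = hand(track))
}

#' Write kinematic series as CSV
#'
#' One row per second per hand: \code{t}, \code{hand}, \code{speed},
#' \code{acceleration}, \code{direction_change}, \code{valid}.
#'
#' @param series a \code{\linkS4class{KinematicSeries}} or list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeKinematics <- function(series, path) {
  if (is(series, "KinematicSeries")) series <- list(series)
  d <- do.call(rbind, lapply(series, function(s)
    data.frame(t = s@times, hand = s@hand, speed = s@speed,
               acceleration = s@acceleration,
               direction_change = s@directionChange, valid = s@validMask)))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
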