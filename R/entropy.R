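#' Construct a binning specification
#'
#' @param feature \code{"speed"}, \code{"acceleration"} or
#'   \code{"direction"}.
#' @param edges strictly increasing bin edges (length = number of bins + 1).
#' @param probs percentile pair recorded when the edges were derived from
#'   data (empty for fixed edges).
#' @return A \code{\linkS4class{BinningSpec}}.
#' @export
binningSpec <- function(feature, edges, probs = numeric()) {
  new("BinningSpec", feature = feature,
      nBins = as.integer(length(edges) - 1L), edges = as.numeric(edges),
      probs = as.numeric(probs))
}

#' Derive the default binning for a kinematic feature
#'
#' Directional change uses fixed equal-width bins over [0, 180] degrees
#' (default 8 bins of 22.5 degrees). Speed and acceleration use equal-width
#' bins (default 32) spanning the 1st to 99th percentile of the supplied
#' values, which should be pooled over both hands of the procedure; samples
#' outside the range are clipped into the end bins. With these defaults the
#' joint support is at most 10 bits for speed/acceleration and 6 bits for
#' direction. The percentile range is computed per procedure, so entropies
#' are comparable across operators only under an identical binning policy;
#' the realised edges are recorded in every result for auditability.
#'
#' @param feature \code{"speed"}, \code{"acceleration"} or
#'   \code{"direction"}.
#' @param values finite samples used to derive a data-driven range (ignored
#'   for \code{"direction"}).
#' @param nBins number of bins per hand.
#' @param probs percentile pair for the data-driven range.
#' @return A \code{\linkS4class{BinningSpec}}.
#' @export
makeBinning <- function(feature = c("speed", "acceleration", "direction"),
                        values = NULL, nBins = NULL,
                        probs = c(0.01, 0.99)) {
  feature <- match.arg(feature)
  if (feature == "direction") {
    if (is.null(nBins)) nBins <- 8L
    return(binningSpec(feature, seq(0, 180, length.out = nBins + 1L)))
  }
  if (is.null(nBins)) nBins <- 32L
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to derive a binning range from")
  r <- unname(quantile(values, probs, names = FALSE, type = 7))
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)  # constant signal: one central bin
  binningSpec(feature, seq(r[1], r[2], length.out = nBins + 1L), probs = probs)
}

## map samples to 1..nBins, clipping outliers into the end bins
.binIndex <- function(x, spec) {
  findInterval(x, spec@edges, rightmost.closed = TRUE, all.inside = TRUE)
}

## entropy in bits of a count vector
.countEntropy <- function(counts) {
  p <- counts[counts > 0L] / sum(counts)
  -sum(p * log2(p))
}

#' Shannon entropy of one discretised sample
#'
#' Plug-in (maximum-likelihood) estimate in bits on the binning of
#' \code{spec}; the marginal counterpart of \code{\link{jointEntropy}}.
#'
#' @param x numeric samples; \code{NA}s are dropped.
#' @param spec a \code{\linkS4class{BinningSpec}}.
#' @return Entropy in bits, with attribute \code{n} (samples used).
#' @export
shannonEntropy <- function(x, spec) {
  stopifnot(is(spec, "BinningSpec"))
  x <- x[is.finite(x)]
  if (!length(x)) stop("no valid samples")
  h <- .countEntropy(tabulate(.binIndex(x, spec), spec@nBins))
  structure(h, n = length(x))
}

#' Shannon joint entropy of two discretised samples
#'
#' Computes the plug-in estimate H(X,Y) = -sum over occupied cells of
#' p(x,y) log2 p(x,y) in bits, where p is the joint histogram of the paired
#' samples on the bins of \code{spec} (the same edges for both signals;
#' empty cells contribute nothing). Pairs where either sample is \code{NA}
#' are dropped before binning. No bias correction is applied: this is the
#' bare maximum-likelihood estimator, whose upward bias for an
#' under-sampled histogram is of order (occupied cells)/(2 n ln 2).
#'
#' In the bimanual setting X and Y are the same kinematic feature of the
#' dominant and non-dominant hand; lower joint entropy means more regular,
#' predictable coordination. The estimate always satisfies
#' 0 <= H(X,Y) <= 2 log2(nBins) and H(X,Y) <= H(X) + H(Y).
#'
#' @param x,y equal-length numeric samples.
#' @param spec a \code{\linkS4class{BinningSpec}} shared by both signals.
#' @return Joint entropy in bits, with attribute \code{n} (pairs used).
#' @examples
#' b <- binningSpec("speed", seq(0, 1, length.out = 5))
#' jointEntropy(c(0.1, 0.4, 0.6, 0.9), c(0.1, 0.4, 0.6, 0.9), b)  # 2 bits
#' @export
jointEntropy <- function(x, y, spec) {
  stopifnot(is(spec, "BinningSpec"))
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) stop("no valid (x, y) pairs")
  ix <- .binIndex(x[ok], spec)
  iy <- .binIndex(y[ok], spec)
  nb <- spec@nBins
  h <- .countEntropy(tabulate((ix - 1L) * nb + iy, nb * nb))
  structure(h, n = sum(ok))
}

#' Bimanual joint entropy triplet of one operator
#'
#' For each kinematic feature (speed, acceleration, directional change),
#' pairs the dominant and non-dominant hand samples at each second, keeps
#' the pairs where both are valid (each feature uses its own maximal valid
#' pair set), derives the feature's binning from the pooled values of both
#' hands unless explicit binnings are supplied, and computes the Shannon
#' joint entropy. A feature with no valid pairs is reported as \code{NA}
#' with the reason in the \code{status} slot, never as 0.
#'
#' @param dominant,nondominant \code{\linkS4class{KinematicSeries}} on the
#'   same 1 Hz grid.
#' @param nBinsSpeed,nBinsAcceleration,nBinsDirection bin counts for the
#'   default binning policy.
#' @param probs percentile pair for the speed/acceleration range.
#' @param bins optional named list of explicit
#'   \code{\linkS4class{BinningSpec}} objects (\code{speed},
#'   \code{acceleration}, \code{direction}) overriding the policy.
#' @return A \code{\linkS4class{JointEntropyTriplet}}.
#' @export
operatorEntropy <- function(dominant, nondominant, nBinsSpeed = 32L,
                            nBinsAcceleration = 32L, nBinsDirection = 8L,
                            probs = c(0.01, 0.99), bins = NULL) {
  stopifnot(is(dominant, "KinematicSeries"), is(nondominant, "KinematicSeries"))
  if (length(dominant@times) != length(nondominant@times) ||
      any(dominant@times != nondominant@times))
    stop("the two series must share the same 1 Hz grid")
  feats <- list(
    speed = list(x = dominant@speed, y = nondominant@speed,
                 nBins = nBinsSpeed),
    acceleration = list(x = dominant@acceleration, y = nondominant@acceleration,
                        nBins = nBinsAcceleration),
    direction = list(x = dominant@directionChange, y = nondominant@directionChange,
                     nBins = nBinsDirection))
  H <- setNames(rep(NA_real_, 3L), names(feats))
  n <- setNames(rep(0L, 3L), names(feats))
  bspecs <- setNames(vector("list", 3L), names(feats))
  status <- setNames(rep("ok", 3L), names(feats))
  for (f in names(feats)) {
    x <- feats[[f]]$x; y <- feats[[f]]$y
    ok <- is.finite(x) & is.finite(y)
    if (!any(ok)) {
      status[f] <- "undefined: no pairwise-valid samples"
      next
    }
    spec <- if (!is.null(bins) && !is.null(bins[[f]])) bins[[f]]
            else makeBinning(f, values = c(x[ok], y[ok]),
                             nBins = feats[[f]]$nBins, probs = probs)
    h <- jointEntropy(x[ok], y[ok], spec)
    H[f] <- as.numeric(h)
    n[f] <- attr(h, "n")
    bspecs[[f]] <- spec
  }
  new("JointEntropyTriplet", speedH = unname(H["speed"]),
      accelerationH = unname(H["acceleration"]),
      directionH = unname(H["direction"]), nSamples = n, binning = bspecs,
      status = status)
}
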