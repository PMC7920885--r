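#' Construct an HSV colour specification for one glove
#'
#' @param name label for the hand the colour marks, e.g. \code{"dominant"}.
#' @param hueRange numeric(2), hue window in degrees; \code{hueRange[1] >
#'   hueRange[2]} denotes a window wrapping through 0/360 (e.g.
#'   \code{c(340, 20)} for red).
#' @param satRange,valRange numeric(2) saturation / value windows in [0, 1].
#' @return A \code{\linkS4class{ColorSpec}}.
#' @examples
#' green <- colorSpec("dominant", c(90, 150))
#' orange <- colorSpec("nondominant", c(20, 50))
#' specsOverlap(green, orange)  # FALSE: safe to track together
#' @export
colorSpec <- function(name, hueRange, satRange = c(0.35, 1),
                      valRange = c(0.2, 1)) {
  new("ColorSpec", name = as.character(name), hueRange = as.numeric(hueRange),
      satRange = as.numeric(satRange), valRange = as.numeric(valRange))
}

#' Derive a colour specification from an RGB colour
#'
#' Builds an HSV window centred on the hue of \code{rgb} with generous
#' saturation and value slack, suitable for segmenting a solid glove colour.
#'
#' @param rgb length-3 RGB in [0, 1].
#' @param name hand label.
#' @param hueHalfWidth half-width of the hue window, degrees.
#' @return A \code{\linkS4class{ColorSpec}}.
#' @export
specForColor <- function(rgb, name = "hand", hueHalfWidth = 25) {
  stopifnot(length(rgb) == 3L, all(rgb >= 0), all(rgb <= 1))
  hsv <- grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 1)
  h <- 360 * hsv[1, 1]
  lo <- (h - hueHalfWidth) %% 360
  hi <- (h + hueHalfWidth) %% 360
  colorSpec(name, c(lo, hi),
            satRange = c(max(0, hsv[2, 1] - 0.35), 1),
            valRange = c(max(0.1, hsv[3, 1] - 0.4), 1))
}

## membership of hue values (degrees) in a possibly wrapping window
.hueIn <- function(h, range) {
  if (range[1] <= range[2]) h >= range[1] & h <= range[2]
  else h >= range[1] | h <= range[2]
}

## do two possibly wrapping hue windows intersect?
.hueWindowsIntersect <- function(a, b) {
  any(.hueIn(c(b[1], b[2]), a)) || any(.hueIn(c(a[1], a[2]), b))
}

#' Test whether two colour specifications overlap
#'
#' Two specifications overlap when their HSV boxes intersect in all three
#' dimensions, in which case a pixel could match both and per-hand tracking
#' is ambiguous. \code{\link{trackVideo}} refuses overlapping glove specs.
#'
#' @param a,b \code{\linkS4class{ColorSpec}} objects.
#' @return logical.
#' @export
specsOverlap <- function(a, b) {
  stopifnot(is(a, "ColorSpec"), is(b, "ColorSpec"))
  iv <- function(p, q) p[1] <= q[2] && q[1] <= p[2]
  .hueWindowsIntersect(a@hueRange, b@hueRange) &&
    iv(a@satRange, b@satRange) && iv(a@valRange, b@valRange)
}

## logical (H x W) mask of in-range pixels for a frame array (H, W, 3)
.colorMask <- function(frame, spec) {
  d <- dim(frame)
  hsv <- grDevices::rgb2hsv(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
                            as.vector(frame[, , 3]), maxColorValue = 1)
  m <- .hueIn(360 * hsv[1, ], spec@hueRange) &
    hsv[2, ] >= spec@satRange[1] & hsv[2, ] <= spec@satRange[2] &
    hsv[3, ] >= spec@valRange[1] & hsv[3, ] <= spec@valRange[2]
  matrix(m, d[1], d[2])
}
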