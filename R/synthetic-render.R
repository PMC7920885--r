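#' Construct a synthetic scene
#'
#' Describes the frame geometry and colours used by \code{\link{renderVideo}}.
#' Validity requires every pair of glove/distractor colours to be
#' hue-separable under the scene's hue window half-width, so the tracker's
#' colour model can never confuse two blobs.
#'
#' @param frameSize integer(2), width and height in pixels.
#' @param gloveColors 2 x 3 RGB matrix in [0, 1]; default green dominant,
#'   orange non-dominant, mirroring the colour-coded glove convention.
#' @param distractorColors n x 3 RGB matrix of extra blob colours, or
#'   \code{NULL}; see \code{\link{defaultDistractors}}.
#' @param blobRadius glove blob radius, pixels.
#' @param background length-3 RGB background.
#' @param hueHalfWidth hue window half-width, degrees.
#' @return A \code{\linkS4class{SyntheticScene}}.
#' @examples
#' syntheticScene(frameSize = c(320, 240),
#'                distractorColors = defaultDistractors())
#' @export
syntheticScene <- function(frameSize = c(320L, 240L),
                           gloveColors = NULL, distractorColors = NULL,
                           blobRadius = 10, background = rep(0.08, 3),
                           hueHalfWidth = 25) {
  if (is.null(gloveColors)) {
    gloveColors <- rbind(dominant = c(0, 0.78, 0.05),
                         nondominant = c(1, 0.55, 0))
  }
  colnames(gloveColors) <- c("r", "g", "b")
  if (is.null(distractorColors))
    distractorColors <- matrix(numeric(), ncol = 3L,
                               dimnames = list(NULL, c("r", "g", "b")))
  new("SyntheticScene", frameSize = as.integer(frameSize),
      gloveColors = gloveColors, distractorColors = as.matrix(distractorColors),
      blobRadius = as.numeric(blobRadius), background = as.numeric(background),
      hueHalfWidth = as.numeric(hueHalfWidth))
}

#' Default distractor colours
#'
#' A small palette (blue, magenta) hue-separable from the default green and
#' orange glove colours, for exercising the tracker's resistance to other
#' coloured gloves in the field.
#'
#' @return 2 x 3 RGB matrix.
#' @export
defaultDistractors <- function() {
  rbind(blue = c(0.15, 0.25, 1), magenta = c(0.85, 0, 0.85))
}

#' Colour specifications matching a scene's glove colours
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @return Named list of two \code{\linkS4class{ColorSpec}} objects suitable
#'   for \code{\link{trackVideo}} on videos rendered from \code{scene}.
#' @export
gloveSpecs <- function(scene) {
  stopifnot(is(scene, "SyntheticScene"))
  list(dominant = specForColor(scene@gloveColors["dominant", ], "dominant",
                               scene@hueHalfWidth),
       nondominant = specForColor(scene@gloveColors["nondominant", ],
                                  "nondominant", scene@hueHalfWidth))
}

## paint a filled circle of colour col at (cx, cy) into frame (H, W, 3)
.paintBlob <- function(frame, cx, cy, r, col) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  mask <- outer((0:(h - 1) - cy)^2, (0:(w - 1) - cx)^2, "+") <= r^2
  for (ch in 1:3) {
    plane <- frame[, , ch]
    plane[mask] <- col[ch]
    frame[, , ch] <- plane
  }
  frame
}

.renderFrame <- function(scene, positions) {
  w <- scene@frameSize[1]; h <- scene@frameSize[2]
  frame <- array(rep(scene@background, each = h * w), dim = c(h, w, 3L))
  for (p in positions)
    if (!is.na(p$x) && !is.na(p$y))
      frame <- .paintBlob(frame, p$x, p$y, p$r, p$col)
  frame
}

## extract per-frame (x, y, valid) from a HandTrack or data.frame
.positionTable <- function(obj) {
  d <- if (is(obj, "HandTrack")) detections(obj) else as.data.frame(obj)
  data.frame(x = d$x, y = d$y,
             valid = if ("valid" %in% names(d)) d$valid else !is.na(d$x))
}

#' Render a synthetic glove video with ground-truth sidecar
#'
#' Draws one solid filled circle per in-frame hand at the ground-truth
#' position, in the scene's glove colour, plus any distractor blobs, and
#' writes the frames to disk together with a per-frame ground-truth CSV
#' (columns \code{frame_index}, \code{hand}, \code{x}, \code{y},
#' \code{in_frame}). Frames with a hand out of frame contain no pixels of
#' that glove's colour.
#'
#' Two containers are supported, chosen by \code{path}: a multi-page TIFF
#' (\code{.tif}/\code{.tiff}; all frames are held in memory, best for short
#' clips) or a directory of numbered PNG frames (constant memory, any
#' length). Both are read back by \code{\link{readVideo}} and by standard
#' image tools.
#'
#' @param tracks named list of two \code{\linkS4class{HandTrack}} objects as
#'   returned by \code{\link{generateTrajectory}}.
#' @param scene the \code{\linkS4class{SyntheticScene}} to render.
#' @param path output \code{.tif}/\code{.tiff} file or directory.
#' @param distractors optional list of \code{\linkS4class{HandTrack}} (or
#'   data.frames with \code{x}, \code{y}) giving distractor blob motion;
#'   distractor i uses row i (recycled) of the scene's
#'   \code{distractorColors} and must have as many frames as the tracks.
#' @param sidecar ground-truth CSV path; defaults next to \code{path}.
#' @return Invisibly, list with \code{video}, \code{sidecar} and
#'   \code{nFrames}.
#' @export
renderVideo <- function(tracks, scene, path, distractors = NULL,
                        sidecar = NULL) {
  stopifnot(is(scene, "SyntheticScene"))
  validObject(scene)
  doms <- .positionTable(tracks$dominant)
  nond <- .positionTable(tracks$nondominant)
  n <- nrow(doms)
  if (nrow(nond) != n) stop("the two hand tracks must have equal length")
  dcols <- scene@distractorColors
  dpos <- lapply(distractors, .positionTable)
  if (length(dpos) && nrow(dcols) == 0L)
    stop("scene has no distractorColors for the given distractor tracks")
  for (dp in dpos) if (nrow(dp) != n)
    stop("distractor tracks must have as many frames as the hand tracks")

  ext <- tolower(tools::file_ext(path))
  asTiff <- ext %in% c("tif", "tiff")
  if (!asTiff) dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sidecar))
    sidecar <- if (asTiff) paste0(tools::file_path_sans_ext(path), "_truth.csv")
               else file.path(path, "truth.csv")

  w <- scene@frameSize[1]; h <- scene@frameSize[2]; r <- scene@blobRadius
  if (asTiff) arr <- array(0, dim = c(w, h, 3L, n))
  for (i in seq_len(n)) {
    ps <- list()
    for (j in seq_along(dpos)) {
      col <- dcols[(j - 1L) %% nrow(dcols) + 1L, ]
      ps[[length(ps) + 1L]] <- list(x = dpos[[j]]$x[i], y = dpos[[j]]$y[i],
                                    r = r, col = col)
    }
    ps[[length(ps) + 1L]] <- list(x = doms$x[i], y = doms$y[i], r = r,
                                  col = scene@gloveColors["dominant", ])
    ps[[length(ps) + 1L]] <- list(x = nond$x[i], y = nond$y[i], r = r,
                                  col = scene@gloveColors["nondominant", ])
    frame <- .renderFrame(scene, ps)
    if (asTiff) {
      for (ch in 1:3) arr[, , ch, i] <- t(frame[, , ch])
    } else {
      png::writePNG(frame, file.path(path, sprintf("frame_%06d.png", i - 1L)))
    }
  }
  if (asTiff)
    EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path,
                        type = "tiff", compression = "deflate")
  truth <- rbind(
    data.frame(frame_index = 0:(n - 1L), hand = "dominant", x = doms$x,
               y = doms$y, in_frame = doms$valid),
    data.frame(frame_index = 0:(n - 1L), hand = "nondominant", x = nond$x,
               y = nond$y, in_frame = nond$valid))
  write.csv(truth, sidecar, row.names = FALSE)
  invisible(list(video = path, sidecar = sidecar, nFrames = n))
}
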