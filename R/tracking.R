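#' Build a HandTrack from per-frame detections
#'
#' Normalises a detection table into a \code{\linkS4class{HandTrack}},
#' deriving the gap list (maximal runs of invalid frames) from the validity
#' column. Mostly used internally by \code{\link{trackVideo}} and
#' \code{\link{generateTrajectory}}, but exposed for assembling tracks from
#' external sources.
#'
#' @param hand hand label.
#' @param frameRate frames/s.
#' @param detections data.frame with at least \code{frame_index},
#'   \code{valid}, \code{x}, \code{y}; missing bounding-box / pixel-count
#'   columns are filled with \code{NA}.
#' @return A \code{\linkS4class{HandTrack}}.
#' @export
handTrack <- function(hand, frameRate, detections) {
  need <- c("frame_index", "hand", "valid", "x", "y", "bbox_x0", "bbox_y0",
            "bbox_x1", "bbox_y1", "pixel_count")
  for (col in setdiff(need, names(detections)))
    detections[[col]] <- if (col == "hand") hand else NA
  detections <- detections[need]
  detections$frame_index <- as.integer(detections$frame_index)
  detections$valid <- as.logical(detections$valid)
  detections <- detections[order(detections$frame_index), , drop = FALSE]
  rownames(detections) <- NULL
  new("HandTrack", hand = as.character(hand), frameRate = as.numeric(frameRate),
      detections = detections, gaps = .invalidRuns(detections$valid))
}

#' Default minimum component size for a frame
#'
#' The detection threshold is 30 pixels for a 1920 x 1080 frame and scales
#' with frame area, with a floor of 1 pixel.
#'
#' @param frameSize integer(2), width and height in pixels.
#' @return integer pixel count.
#' @export
defaultMinPixels <- function(frameSize) {
  max(1L, as.integer(round(30 * prod(as.numeric(frameSize)) / (1920 * 1080))))
}

#' Detect one glove in a single frame
#'
#' Segments the frame with the HSV window of \code{spec}, labels connected
#' components of the in-range mask, keeps the largest component, and reports
#' the minimal axis-aligned bounding box of that component. The hand position
#' is the centre of that box. If the largest component has fewer than
#' \code{minPixels} pixels the detection is invalid (no centroid). The
#' computation is purely per-frame and deterministic, which is what lets the
#' tracker re-acquire a glove immediately after it re-enters the field.
#'
#' @param frame numeric array (height, width, 3), RGB in [0, 1]. Pixel
#'   (row r, column c) has coordinates x = c - 1, y = r - 1 (origin top-left,
#'   x rightwards, y downwards).
#' @param spec a \code{\linkS4class{ColorSpec}}.
#' @param minPixels minimum component size in pixels; default scales with
#'   frame area (see \code{\link{defaultMinPixels}}).
#' @param frameIndex 0-based frame index recorded in the result.
#' @return One-row data.frame with columns \code{frame_index}, \code{hand},
#'   \code{valid}, \code{x}, \code{y}, \code{bbox_x0}, \code{bbox_y0},
#'   \code{bbox_x1}, \code{bbox_y1}, \code{pixel_count}.
#' @examples
#' f <- array(0, dim = c(100, 100, 3))
#' f[46:55, 46:55, 2] <- 0.8  # 10x10 green square, corners (45,45)-(54,54)
#' detectHand(f, colorSpec("dominant", c(90, 150)))[, c("x", "y")]
#' @export
detectHand <- function(frame, spec, minPixels = NULL, frameIndex = 0L) {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("'frame' must be an (height, width, 3) RGB array")
  if (any(!is.finite(frame)))
    stop("corrupt frame: non-finite pixel values")
  if (is.null(minPixels)) minPixels <- defaultMinPixels(dim(frame)[2:1])
  if (minPixels < 1L) stop("'minPixels' must be >= 1")
  miss <- data.frame(frame_index = as.integer(frameIndex), hand = spec@name,
                     valid = FALSE, x = NA_real_, y = NA_real_,
                     bbox_x0 = NA_real_, bbox_y0 = NA_real_,
                     bbox_x1 = NA_real_, bbox_y1 = NA_real_,
                     pixel_count = 0L)
  mask <- .colorMask(frame, spec)
  if (sum(mask) < minPixels) return(miss)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  if (sizes[best] < minPixels) return(miss)
  idx <- which(lab == best, arr.ind = TRUE)
  x0 <- min(idx[, 2]) - 1; x1 <- max(idx[, 2]) - 1
  y0 <- min(idx[, 1]) - 1; y1 <- max(idx[, 1]) - 1
  data.frame(frame_index = as.integer(frameIndex), hand = spec@name,
             valid = TRUE, x = (x0 + x1) / 2, y = (y0 + y1) / 2,
             bbox_x0 = x0, bbox_y0 = y0, bbox_x1 = x1, bbox_y1 = y1,
             pixel_count = sizes[best])
}

#' Open a video for frame-by-frame reading
#'
#' Supported containers are a multi-page TIFF file and a directory of
#' numbered PNG frames (both written by \code{\link{renderVideo}}). A list
#' of in-memory frame arrays is passed through. Frames are decoded lazily so
#' long recordings never need to fit in memory at once.
#'
#' @param video path to a \code{.tif}/\code{.tiff} file, path to a directory
#'   of \code{.png} frames, or a list of (height, width, 3) arrays.
#' @return A \code{videoSource}: list with \code{nFrames} and
#'   \code{getFrame(i)} (1-based) returning an (height, width, 3) array.
#' @export
readVideo <- function(video) {
  if (is.list(video) && !is.null(video$getFrame)) return(video)
  if (is.list(video)) {
    frames <- video
    return(structure(list(nFrames = length(frames),
                          getFrame = function(i) frames[[i]]),
                     class = "videoSource"))
  }
  if (!is.character(video) || length(video) != 1L)
    stop("'video' must be a path or a list of frames")
  if (dir.exists(video)) {
    files <- sort(list.files(video, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no .png frames found in ", video)
    return(structure(list(nFrames = length(files),
                          getFrame = function(i) png::readPNG(files[i])),
                     class = "videoSource"))
  }
  if (!file.exists(video)) stop("video not found: ", video)
  ext <- tolower(tools::file_ext(video))
  if (!ext %in% c("tif", "tiff"))
    stop("unsupported video container: ", video)
  img <- EBImage::readImage(video)
  a <- as.array(img)                      # (x, y, channel[, frame])
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  n <- dim(a)[4]
  structure(list(nFrames = n,
                 getFrame = function(i) aperm(a[, , , i], c(2, 1, 3))),
            class = "videoSource")
}

#' Track both gloves through a video
#'
#' Runs \code{\link{detectHand}} independently on every frame for each of
#' the two glove colour specifications and assembles one
#' \code{\linkS4class{HandTrack}} per hand. Detection is stateless across
#' frames, so the tracker re-attaches to a glove on the first frame it
#' re-enters the field, and is byte-deterministic: the same video always
#' yields the same tracks.
#'
#' @param video anything accepted by \code{\link{readVideo}}.
#' @param dominant,nondominant \code{\linkS4class{ColorSpec}} for the two
#'   gloves; they must not overlap (see \code{\link{specsOverlap}}).
#' @param frameRate frames/s of the recording (default 50).
#' @param minPixels minimum component size; default scales with frame area.
#' @return Named list of two \code{\linkS4class{HandTrack}} objects
#'   (\code{dominant}, \code{nondominant}).
#' @export
trackVideo <- function(video, dominant, nondominant, frameRate = 50,
                       minPixels = NULL) {
  stopifnot(is(dominant, "ColorSpec"), is(nondominant, "ColorSpec"))
  if (specsOverlap(dominant, nondominant))
    stop("configuration error: the two colour specifications overlap; ",
         "per-hand tracking would be ambiguous")
  src <- readVideo(video)
  n <- src$nFrames
  res <- lapply(list(dominant, nondominant), function(spec) {
    rows <- vector("list", n)
    for (i in seq_len(n))
      rows[[i]] <- detectHand(src$getFrame(i), spec, minPixels = minPixels,
                              frameIndex = i - 1L)
    handTrack(spec@name, frameRate, do.call(rbind, rows))
  })
  names(res) <- c("dominant", "nondominant")
  res
}

#' Write / read hand tracks as CSV
#'
#' The track CSV schema is one row per frame per hand:
#' \code{frame_index, hand, valid, x, y, bbox_x0, bbox_y0, bbox_x1, bbox_y1,
#' pixel_count}.
#'
#' @param tracks a \code{\linkS4class{HandTrack}} or a list of them.
#' @param path output CSV path.
#' @return \code{writeTrack}: \code{path}, invisibly. \code{readTrack}: a
#'   named list of \code{\linkS4class{HandTrack}} objects, one per hand
#'   label present.
#' @export
writeTrack <- function(tracks, path) {
  if (is(tracks, "HandTrack")) tracks <- list(tracks)
  d <- do.call(rbind, lapply(tracks, detections))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrack
#' @param frameRate frames/s to attach to the tracks read back.
#' @export
readTrack <- function(path, frameRate = 50) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  res <- lapply(split(d, d$hand), function(dd)
    handTrack(dd$hand[1], frameRate, dd))
  res[order(match(names(res), c("dominant", "nondominant")))]
}
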