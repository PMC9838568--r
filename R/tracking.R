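# Probe-tip tracking: HSV color gating of the dental-ligature marker,
# largest-in-range blob centroid, temporal interpolation and median
# smoothing, and evaluation against a reference track.

#' HSV color gate for the probe-tip ligature marker
#'
#' Colored dental ligatures at the distal tip of the fiber holder give the
#' probe a saturated, tissue-atypical color; this gate selects it in HSV
#' space. The hue interval is wrap-aware (e.g. 350..10 selects reds across
#' the 0/360 seam). The default gate is teal, a hue absent from oral mucosa
#' imagery.
#'
#' @slot hueLo,hueHi hue interval bounds in degrees (0..360), wrap-aware
#' @slot satMin,valMin minimum saturation / value in 0..1
#' @slot minAreaPx,maxAreaPx accepted blob area range in px^2
#' @export
setClass("ColorGate", representation(
  hueLo = "numeric", hueHi = "numeric", satMin = "numeric", valMin = "numeric",
  minAreaPx = "numeric", maxAreaPx = "numeric"))

setValidity("ColorGate", function(object) {
  if (object@hueLo < 0 || object@hueLo > 360 || object@hueHi < 0 || object@hueHi > 360)
    return("hue bounds must lie in [0, 360]")
  if (object@satMin < 0 || object@satMin > 1 || object@valMin < 0 || object@valMin > 1)
    return("satMin and valMin must lie in [0, 1]")
  if (object@minAreaPx >= object@maxAreaPx) return("minAreaPx must be < maxAreaPx")
  TRUE
})

#' @describeIn ColorGate-class constructor; defaults select a teal marker
#' @param hueLo,hueHi,satMin,valMin,minAreaPx,maxAreaPx see slots
#' @export
colorGate <- function(hueLo = 160, hueHi = 200, satMin = 0.35, valMin = 0.2,
                      minAreaPx = 20, maxAreaPx = 5000) {
  new("ColorGate", hueLo = hueLo, hueHi = hueHi, satMin = satMin,
      valMin = valMin, minAreaPx = minAreaPx, maxAreaPx = maxAreaPx)
}

#' Segment the probe marker by color thresholding
#'
#' Converts the RGB frame to HSV, keeps pixels inside the gate's (wrap-aware)
#' hue interval with saturation and value above the gate minima, then applies
#' a single 3x3 morphological opening to drop speckle.
#'
#' @param frame width x height x 3 RGB array (0..255 scale)
#' @param gate a [ColorGate-class]
#' @return logical matrix, the marker mask (possibly empty)
#' @export
segmentMarker <- function(frame, gate) {
  .assert(is.array(frame) && length(dim(frame)) == 3 && dim(frame)[3] == 3,
          "frame must be a width x height x 3 RGB array")
  .assert(is(gate, "ColorGate"), "gate must be a ColorGate")
  d <- dim(frame)[1:2]
  hsv <- grDevices::rgb2hsv(r = as.vector(frame[, , 1]),
                            g = as.vector(frame[, , 2]),
                            b = as.vector(frame[, , 3]), maxColorValue = 255)
  hue <- hsv[1, ] * 360
  inHue <- if (gate@hueLo <= gate@hueHi) hue >= gate@hueLo & hue <= gate@hueHi
           else hue >= gate@hueLo | hue <= gate@hueHi
  m <- matrix(inHue & hsv[2, ] >= gate@satMin & hsv[3, ] >= gate@valMin, d[1], d[2])
  opened <- EBImage::opening(m * 1, EBImage::makeBrush(3, "box"))
  EBImage::imageData(opened) > 0.5
}

#' Locate the probe tip in a marker mask
#'
#' Labels connected components (8-connectivity), keeps those with area in
#' the gate's accepted range, and returns the centroid of the largest. Area
#' ties are broken toward the smaller centroid y, then smaller x. With no
#' qualifying component the result is flagged invalid.
#'
#' @param markerMask logical matrix from [segmentMarker]
#' @param gate a [ColorGate-class] (area range)
#' @return list(x, y, blobArea, valid); x, y are the 0-based centroid in px
#' @export
locateTip <- function(markerMask, gate) {
  .assert(is.matrix(markerMask), "markerMask must be a matrix")
  .assert(is(gate, "ColorGate"), "gate must be a ColorGate")
  none <- list(x = NA_real_, y = NA_real_, blobArea = 0, valid = FALSE)
  if (!any(markerMask)) return(none)
  st <- .labelStats(.label8(markerMask))
  st <- st[st$area >= gate@minAreaPx & st$area <= gate@maxAreaPx, , drop = FALSE]
  if (!nrow(st)) return(none)
  st <- st[order(-st$area, st$y, st$x), , drop = FALSE]
  list(x = st$x[1], y = st$y[1], blobArea = st$area[1], valid = TRUE)
}

#' Track the probe tip through a widefield video
#'
#' Runs [segmentMarker] + [locateTip] on every frame, fills invalid runs of
#' length at most \code{maxGap} (with valid entries on both flanks) by
#' linear interpolation, and smooths valid positions with a centered running
#' median of \code{smoothWindow} frames (shrunken windows at the edges and
#' around invalid entries). The output for frame t depends only on frames up
#' to t + (smoothWindow - 1) / 2, so the procedure is streaming-capable.
#'
#' @param frames list of RGB arrays, or a function(i) returning frame i
#'   (in which case \code{nFrames} must be given)
#' @param gate a [ColorGate-class]
#' @param timestamps numeric vector of per-frame times in seconds; defaults
#'   to the frame index
#' @param smoothWindow odd window length for the running median, default 5
#' @param maxGap longest invalid run to fill by interpolation, default 5
#' @param nFrames number of frames when \code{frames} is a function
#' @return a [ProbeTrack-class]; interpolated entries are valid with
#'   \code{interpolated = TRUE}
#' @export
trackVideo <- function(frames, gate, timestamps = NULL, smoothWindow = 5L,
                       maxGap = 5L, nFrames = NULL) {
  if (is.function(frames)) {
    .assert(!is.null(nFrames), "nFrames is required when frames is a function")
    getFrame <- frames; n <- as.integer(nFrames)
  } else {
    .assert(is.list(frames), "frames must be a list or a function")
    getFrame <- function(i) frames[[i]]; n <- length(frames)
  }
  .assert(n >= 1L, "at least one frame is required")
  .assert(smoothWindow %% 2 == 1, "smoothWindow must be odd")
  if (is.null(timestamps)) timestamps <- seq_len(n) - 1
  .assert(length(timestamps) == n, "timestamps length must match frame count")

  x <- y <- rep(NA_real_, n); area <- numeric(n); valid <- logical(n)
  for (i in seq_len(n)) {
    tip <- locateTip(segmentMarker(getFrame(i), gate), gate)
    x[i] <- tip$x; y[i] <- tip$y; area[i] <- tip$blobArea; valid[i] <- tip$valid
  }

  interp <- logical(n)
  r <- rle(valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] || r$lengths[k] > maxGap) next
    if (k == 1L || k == length(r$values)) next  # no flank on one side
    a <- starts[k] - 1L; b <- ends[k] + 1L
    idx <- starts[k]:ends[k]
    t <- (idx - a) / (b - a)
    x[idx] <- x[a] + t * (x[b] - x[a])
    y[idx] <- y[a] + t * (y[b] - y[a])
    valid[idx] <- TRUE; interp[idx] <- TRUE
  }

  half <- (smoothWindow - 1L) / 2L
  sx <- x; sy <- y
  vi <- which(valid)
  for (i in vi) {
    w <- max(1L, i - half):min(n, i + half)
    w <- w[valid[w]]
    sx[i] <- median(x[w]); sy[i] <- median(y[w])
  }
  probeTrack(data.frame(
    frame_index = seq_len(n) - 1L, timestamp_s = as.numeric(timestamps),
    x_px = sx, y_px = sy, blob_area_px2 = area, valid = valid,
    interpolated = interp))
}

#' Evaluate a probe track against a reference
#'
#' Positional errors are computed over frames valid in both tracks and
#' converted to millimeters through the calibration.
#'
#' @param track,truth [ProbeTrack-class] objects sharing frame indices
#' @param cal a [CalibrationModel-class]
#' @return list(meanErrorMm, p95ErrorMm, validFraction); validFraction is
#'   the fraction of truth-valid frames the track marks valid
#' @export
evaluateTracking <- function(track, truth, cal) {
  .assert(is(track, "ProbeTrack") && is(truth, "ProbeTrack"),
          "track and truth must be ProbeTrack objects")
  a <- track@entries; b <- truth@entries
  common <- intersect(a$frame_index, b$frame_index)
  .assert(length(common) > 0, "tracks share no frames")
  ia <- match(common, a$frame_index); ib <- match(common, b$frame_index)
  both <- a$valid[ia] & b$valid[ib]
  .assert(any(both), "no frames are valid in both tracks")
  err <- pixelsToMm(cal, a$x_px[ia][both] - b$x_px[ib][both],
                    a$y_px[ia][both] - b$y_px[ib][both])
  list(meanErrorMm = mean(err),
       p95ErrorMm = as.numeric(quantile(err, 0.95, names = FALSE)),
       validFraction = sum(both) / sum(b$valid[ib]))
}

#' Read/write a probe track as CSV
#'
#' Columns: frame_index, timestamp_s, x_px, y_px, blob_area_px2, valid,
#' interpolated.
#'
#' @param track a [ProbeTrack-class]
#' @param path file path
#' @return \code{readTrack} returns a [ProbeTrack-class]
#' @export
writeTrack <- function(track, path) {
  .assert(is(track, "ProbeTrack"), "track must be a ProbeTrack")
  utils::write.csv(track@entries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrack
#' @export
readTrack <- function(path) {
  e <- utils::read.csv(path)
  e$valid <- as.logical(e$valid); e$interpolated <- as.logical(e$interpolated)
  probeTrack(e)
}
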