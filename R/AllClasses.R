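#' Physical calibration of the widefield camera frame
#'
#' Maps pixel displacements in the widefield frame to millimeters on tissue.
#' The default corresponds to an 80 x 50 mm field of view imaged at
#' 960 x 600 px, i.e. 0.0833 mm/px in both axes.
#'
#' @slot frameWidth integer, frame width in px
#' @slot frameHeight integer, frame height in px
#' @slot mmPerPxX,mmPerPxY millimeters spanned by one pixel
#' @export
setClass("CalibrationModel", representation(
  frameWidth = "integer", frameHeight = "integer",
  mmPerPxX = "numeric", mmPerPxY = "numeric"))

setValidity("CalibrationModel", function(object) {
  v <- c(object@frameWidth, object@frameHeight, object@mmPerPxX, object@mmPerPxY)
  if (any(!is.finite(v)) || any(v <= 0)) return("all calibration fields must be strictly positive")
  TRUE
})

#' Construct a camera calibration model
#'
#' @param frameWidth,frameHeight frame dimensions in px
#' @param mmPerPxX,mmPerPxY physical pixel pitch on tissue, mm/px
#' @return a [CalibrationModel-class] object
#' @examples
#' cal <- calibrationModel()
#' pixelsToMm(cal, 12, 0)
#' @export
calibrationModel <- function(frameWidth = 960L, frameHeight = 600L,
                             mmPerPxX = 80 / 960, mmPerPxY = 50 / 600) {
  new("CalibrationModel", frameWidth = as.integer(frameWidth),
      frameHeight = as.integer(frameHeight),
      mmPerPxX = mmPerPxX, mmPerPxY = mmPerPxY)
}

#' Planar homography between camera and projector image planes
#'
#' A 3x3 projective transform, normalized so the bottom-right entry is 1,
#' standing in for the physical camera-projector coregistration of the
#' projection light path.
#'
#' @slot matrix 3x3 numeric matrix, camera plane -> projector plane
#' @export
setClass("PlanarHomography", representation(matrix = "matrix"))

setValidity("PlanarHomography", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || any(dim(m) != c(3L, 3L)) || any(!is.finite(m)))
    return("matrix must be a finite 3x3 numeric matrix")
  if (abs(m[3, 3] - 1) > 1e-12) return("matrix must be normalized with bottom-right entry 1")
  if (abs(det(m)) < 1e-12) return("matrix is numerically singular")
  TRUE
})

#' @describeIn PlanarHomography-class construct from a 3x3 matrix
#'   (renormalized so that h33 = 1)
#' @param m 3x3 numeric matrix
#' @export
planarHomography <- function(m) {
  .assert(is.matrix(m) && all(dim(m) == c(3, 3)), "m must be a 3x3 matrix")
  .assert(abs(m[3, 3]) > 1e-12, "bottom-right entry must be nonzero for normalization")
  new("PlanarHomography", matrix = m / m[3, 3])
}

#' Normalized red-to-green autofluorescence risk map
#'
#' Per-pixel normalized red/green fluorescence intensity ratio over a
#' clinician-outlined mucosa mask. Elevated values indicate loss of green
#' (collagen) autofluorescence and/or gain of red (porphyrin) emission,
#' the widefield signature of oral neoplasia. Values are NA outside the
#' mucosa mask; inside, they are normalized so that the chosen statistic
#' (mean or median) over the mask equals 1.
#'
#' @slot rg numeric matrix (width x height) of normalized ratios, NA outside mask
#' @slot mask logical matrix, the mucosa mask
#' @slot normalizationConstant the raw-ratio statistic divided out
#' @slot epsilon green-channel guard added to the denominator, intensity units
#' @slot normStat "mean" or "median"
#' @export
setClass("RiskMap", representation(
  rg = "matrix", mask = "matrix", normalizationConstant = "numeric",
  epsilon = "numeric", normStat = "character"))

setValidity("RiskMap", function(object) {
  if (!all(dim(object@rg) == dim(object@mask))) return("rg and mask dims differ")
  inside <- object@rg[object@mask]
  if (any(!is.finite(inside))) return("rg must be finite inside the mask")
  if (any(inside < 0)) return("rg must be nonnegative inside the mask")
  if (!all(is.na(object@rg[!object@mask]))) return("rg must be NA outside the mask")
  if (object@normalizationConstant <= 0) return("normalizationConstant must be positive")
  if (object@epsilon <= 0) return("epsilon must be positive")
  TRUE
})

#' Probe-tip track through widefield video
#'
#' Time series of tracked probe-tip pixel positions, one entry per widefield
#' frame, with validity and interpolation flags.
#'
#' @slot entries data.frame with columns frame_index, timestamp_s, x_px,
#'   y_px, blob_area_px2, valid, interpolated
#' @export
setClass("ProbeTrack", representation(entries = "data.frame"))

setValidity("ProbeTrack", function(object) {
  e <- object@entries
  need <- c("frame_index", "timestamp_s", "x_px", "y_px", "blob_area_px2",
            "valid", "interpolated")
  if (!all(need %in% names(e))) return("missing track columns")
  if (nrow(e) > 1) {
    if (any(diff(e$frame_index) <= 0)) return("frame_index must be strictly increasing")
    if (any(diff(e$timestamp_s) < 0)) return("timestamps must be nondecreasing")
  }
  if (any(e$valid & (!is.finite(e$x_px) | !is.finite(e$y_px))))
    return("valid entries must have finite positions")
  TRUE
})

#' @describeIn ProbeTrack-class construct from an entries data.frame
#' @param entries see the entries slot
#' @export
probeTrack <- function(entries) new("ProbeTrack", entries = entries)

#' Per-pixel running score field
#'
#' Accumulates microendoscopy frame scores onto widefield anatomy: at each
#' pixel a running sum and count of deposited scores; the mean is computed
#' on demand. Because the microscope runs at a much higher frame rate than
#' the widefield camera, many scores can land on one pixel; the per-pixel
#' average is the quantity thresholded by the guidance rule.
#'
#' @slot sum numeric matrix of score sums
#' @slot count integer matrix of deposit counts
#' @export
setClass("ScoreField", representation(sum = "matrix", count = "matrix"))

setValidity("ScoreField", function(object) {
  if (!all(dim(object@sum) == dim(object@count))) return("sum and count dims differ")
  if (any(object@count < 0)) return("count must be nonnegative")
  if (any(object@sum[object@count == 0] != 0)) return("sum must be 0 where count is 0")
  m <- object@sum[object@count > 0] / object@count[object@count > 0]
  if (length(m) && (any(m < -1e-9) || any(m > 1 + 1e-9))) return("mean score outside [0,1]")
  TRUE
})

#' Dual-threshold biopsy guidance map
#'
#' Binary mask of pixels recommended for biopsy: inside the mucosa mask,
#' visited by the probe (score count > 0), with normalized RG ratio at or
#' above \code{tauRG} and mean frame score at or above \code{tauMTN}.
#'
#' @slot mask logical matrix
#' @slot tauRG,tauMTN the thresholds used
#' @slot provenance character identifiers of the inputs used
#' @export
setClass("GuidanceMap", representation(
  mask = "matrix", tauRG = "numeric", tauMTN = "numeric", provenance = "character"))

setValidity("GuidanceMap", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@tauRG < 0) return("tauRG must be >= 0")
  if (object@tauMTN < 0 || object@tauMTN > 1) return("tauMTN must be in [0,1]")
  TRUE
})

#' Single microendoscopy frame
#'
#' One grayscale fiber-bundle microendoscopy frame (default 720 x 540 px with
#' a 790-um circular field of view), in arbitrary intensity units on a
#' nominal 0..255 scale.
#'
#' @slot pixels numeric matrix (width x height)
#' @slot timestamp seconds from session start
#' @slot frameIndex integer frame number
#' @slot fovCenter numeric length-2, (x, y) px of the fov-circle center
#' @slot fovRadius fov-circle radius in px
#' @export
setClass("MicroFrame", representation(
  pixels = "matrix", timestamp = "numeric", frameIndex = "integer",
  fovCenter = "numeric", fovRadius = "numeric"))

setValidity("MicroFrame", function(object) {
  w <- nrow(object@pixels); h <- ncol(object@pixels)
  c <- object@fovCenter; r <- object@fovRadius
  if (any(!is.finite(object@pixels))) return("pixel intensities must be finite")
  if (length(c) != 2) return("fovCenter must be length 2")
  if (c[1] - r < -0.5 || c[1] + r > w - 0.5 || c[2] - r < -0.5 || c[2] + r > h - 0.5)
    return("fov circle must lie within the frame")
  TRUE
})

#' @describeIn MicroFrame-class constructor; fov defaults to the largest
#'   centered circle
#' @param pixels,timestamp,frameIndex,fovCenter,fovRadius see slots
#' @export
microFrame <- function(pixels, timestamp = 0, frameIndex = 0L,
                       fovCenter = (dim(pixels) - 1) / 2,
                       fovRadius = min(dim(pixels)) / 2 - 1) {
  new("MicroFrame", pixels = pixels, timestamp = timestamp,
      frameIndex = as.integer(frameIndex), fovCenter = as.numeric(fovCenter),
      fovRadius = fovRadius)
}

#' Mosaic of registered microendoscopy frames
#'
#' @slot image composite intensity matrix (canvas)
#' @slot weight per-pixel accumulated blend weight; image defined where > 0
#' @slot placements data.frame: frame_index, dx_px, dy_px, correlation_peak,
#'   chained_valid
#' @slot umPerPx microns per pixel in the microscope plane
#' @export
setClass("MosaicCanvas", representation(
  image = "matrix", weight = "matrix", placements = "data.frame",
  umPerPx = "numeric"))

setValidity("MosaicCanvas", function(object) {
  if (!all(dim(object@image) == dim(object@weight))) return("image and weight dims differ")
  if (object@umPerPx <= 0) return("umPerPx must be positive")
  TRUE
})

# ---- accessors ----------------------------------------------------------

#' Accessors for pipeline containers
#'
#' Small accessor functions for the package's S4 containers, preferred over
#' direct slot access.
#'
#' @param x the object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
riskValues <- function(x) { .assert(is(x, "RiskMap"), "x must be a RiskMap"); x@rg }

#' @rdname accessors
#' @export
riskMask <- function(x) { .assert(is(x, "RiskMap"), "x must be a RiskMap"); x@mask }

#' @rdname accessors
#' @export
normalizationConstant <- function(x) { .assert(is(x, "RiskMap"), "x must be a RiskMap"); x@normalizationConstant }

#' @rdname accessors
#' @export
trackEntries <- function(x) { .assert(is(x, "ProbeTrack"), "x must be a ProbeTrack"); x@entries }

#' @rdname accessors
#' @export
fieldCount <- function(x) { .assert(is(x, "ScoreField"), "x must be a ScoreField"); x@count }

#' @rdname accessors
#' @export
fieldSum <- function(x) { .assert(is(x, "ScoreField"), "x must be a ScoreField"); x@sum }

#' Per-pixel mean score of a ScoreField
#'
#' @param x a [ScoreField-class]
#' @return numeric matrix: sum/count where count > 0, NA elsewhere
#' @export
fieldMean <- function(x) {
  .assert(is(x, "ScoreField"), "x must be a ScoreField")
  m <- matrix(NA_real_, nrow(x@sum), ncol(x@sum))
  vis <- x@count > 0
  m[vis] <- x@sum[vis] / x@count[vis]
  m
}

#' @rdname accessors
#' @export
guidanceMask <- function(x) { .assert(is(x, "GuidanceMap"), "x must be a GuidanceMap"); x@mask }

#' @rdname accessors
#' @export
homographyMatrix <- function(x) { .assert(is(x, "PlanarHomography"), "x must be a PlanarHomography"); x@matrix }

#' @rdname accessors
#' @export
mosaicImage <- function(x) { .assert(is(x, "MosaicCanvas"), "x must be a MosaicCanvas"); x@image }

#' @rdname accessors
#' @export
mosaicPlacements <- function(x) { .assert(is(x, "MosaicCanvas"), "x must be a MosaicCanvas"); x@placements }

#' Physical width of a mosaic
#'
#' @param x a [MosaicCanvas-class]
#' @return x-extent of the canvas in millimeters
#' @export
mosaicWidthMm <- function(x) {
  .assert(is(x, "MosaicCanvas"), "x must be a MosaicCanvas")
  nrow(x@image) * x@umPerPx / 1000
}

# ---- show methods -------------------------------------------------------

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: %d x %d px, %.4f x %.4f mm/px (%.1f x %.1f mm field)\n",
              object@frameWidth, object@frameHeight, object@mmPerPxX, object@mmPerPxY,
              object@frameWidth * object@mmPerPxX, object@frameHeight * object@mmPerPxY))
})

setMethod("show", "PlanarHomography", function(object) {
  cat("PlanarHomography (camera -> projector):\n")
  print(round(object@matrix, 6))
})

setMethod("show", "RiskMap", function(object) {
  inside <- object@rg[object@mask]
  cat(sprintf("RiskMap: %d x %d px, %d mucosa px (%.1f%%)\n",
              nrow(object@rg), ncol(object@rg), sum(object@mask),
              100 * mean(object@mask)))
  cat(sprintf("  normalized RG (%s = 1): range %.3f .. %.3f, normalization constant %.4g\n",
              object@normStat, min(inside), max(inside), object@normalizationConstant))
})

setMethod("show", "ProbeTrack", function(object) {
  e <- object@entries
  cat(sprintf("ProbeTrack: %d frames, %.1f%% valid (%d interpolated), t = %.2f .. %.2f s\n",
              nrow(e), 100 * mean(e$valid), sum(e$interpolated),
              min(e$timestamp_s), max(e$timestamp_s)))
})

setMethod("show", "ScoreField", function(object) {
  vis <- object@count > 0
  cat(sprintf("ScoreField: %d x %d px, %d visited px, %d deposits",
              nrow(object@sum), ncol(object@sum), sum(vis), sum(object@count)))
  if (any(vis)) cat(sprintf(", mean score range %.3f .. %.3f",
                            min(object@sum[vis] / object@count[vis]),
                            max(object@sum[vis] / object@count[vis])))
  cat("\n")
})

setMethod("show", "GuidanceMap", function(object) {
  cat(sprintf("GuidanceMap: %d x %d px, %d recommended px (tauRG = %.3g, tauMTN = %.3g)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              object@tauRG, object@tauMTN))
})

setMethod("show", "MicroFrame", function(object) {
  cat(sprintf("MicroFrame #%d @ %.3f s: %d x %d px, fov r = %.1f px at (%.1f, %.1f)\n",
              object@frameIndex, object@timestamp, nrow(object@pixels),
              ncol(object@pixels), object@fovRadius, object@fovCenter[1],
              object@fovCenter[2]))
})

setMethod("show", "MosaicCanvas", function(object) {
  cat(sprintf("MosaicCanvas: %d x %d px canvas from %d frames (%d chained valid), width %.2f mm\n",
              nrow(object@image), ncol(object@image), nrow(object@placements),
              sum(object@placements$chained_valid), mosaicWidthMm(object)))
})
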