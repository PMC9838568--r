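# Microendoscopy frame quality control and diagnostic scoring.
#
# Frames are quality-controlled (probe contact + sharpness) and each passing
# frame receives a diagnostic probability in [0, 1] from a pluggable scorer.
# The shipped baseline is transparent nuclear morphometry: proflavine-stained
# epithelium shows sparse, regular nuclei when normal and crowded, enlarged
# nuclei when dysplastic, so density, mean nuclear area and crowding carry
# the diagnostic signal.

#' Default microscope pixel pitch
#'
#' 790 um field of view across 720 px, i.e. about 1.097 um/px.
#' @return microns per pixel in the microscope plane
#' @export
microUmPerPx <- function() 790 / 720

#' Quality-control a microendoscopy frame
#'
#' Two checks gate scoring: probe contact (fraction of fov-circle pixels at
#' or above \code{contactFloor} must reach \code{minCoverage} -- a probe off
#' tissue returns almost no signal) and image content (mean squared gradient
#' magnitude inside the fov must reach \code{minSharpness} -- motion blur and
#' defocus suppress gradients).
#'
#' @param frame a [MicroFrame-class]
#' @param contactFloor intensity floor counting as signal (0..255 scale)
#' @param minCoverage minimum signal coverage fraction in 0..1
#' @param minSharpness minimum mean squared gradient magnitude
#' @return list(passContact, passContent, coverageFraction, sharpness)
#' @export
qcFrame <- function(frame, contactFloor = 20, minCoverage = 0.3,
                    minSharpness = 2) {
  .assert(is(frame, "MicroFrame"), "frame must be a MicroFrame")
  px <- frame@pixels
  fov <- .fovMask(nrow(px), ncol(px), frame@fovCenter[1], frame@fovCenter[2],
                  frame@fovRadius)
  coverage <- mean(px[fov] >= contactFloor)
  # central-difference gradient, fov eroded by 1 px to stay off the vignette
  w <- nrow(px); h <- ncol(px)
  gx <- matrix(0, w, h); gy <- matrix(0, w, h)
  gx[2:(w - 1), ] <- (px[3:w, ] - px[1:(w - 2), ]) / 2
  gy[, 2:(h - 1)] <- (px[, 3:h] - px[, 1:(h - 2)]) / 2
  fovIn <- .fovMask(w, h, frame@fovCenter[1], frame@fovCenter[2],
                    frame@fovRadius - 2)
  sharp <- mean((gx^2 + gy^2)[fovIn])
  list(passContact = coverage >= minCoverage,
       passContent = sharp >= minSharpness,
       coverageFraction = coverage, sharpness = sharp)
}

#' Segment nuclei in a microendoscopy frame
#'
#' Background is removed with a white top-hat (structuring disc about twice
#' the expected nucleus radius), a global Otsu threshold is computed from
#' fov-circle pixels, touching nuclei are split by a watershed on the
#' distance transform, and components are filtered to the accepted area
#' range. Centroid, area and eccentricity are reported per nucleus.
#'
#' @param frame a [MicroFrame-class] that passed QC
#' @param minNucleusArea,maxNucleusArea accepted component areas, px^2
#' @param expectedRadiusPx expected nucleus radius in px; sets the top-hat
#'   disc radius (about 2x this). Default ~3.2 px (3.5 um at the default
#'   pixel pitch)
#' @return data.frame with columns x, y (0-based px), area (px^2),
#'   eccentricity; zero rows is a valid result
#' @export
segmentNuclei <- function(frame, minNucleusArea = 8, maxNucleusArea = 500,
                          expectedRadiusPx = 3.5 / microUmPerPx()) {
  .assert(is(frame, "MicroFrame"), "frame must be a MicroFrame")
  px <- frame@pixels / 255
  w <- nrow(px); h <- ncol(px)
  fov <- .fovMask(w, h, frame@fovCenter[1], frame@fovCenter[2], frame@fovRadius)
  discR <- max(2L, round(2 * expectedRadiusPx))
  th <- EBImage::whiteTopHat(px, EBImage::makeBrush(2L * discR + 1L, "disc"))
  th <- EBImage::imageData(EBImage::gblur(th, sigma = 0.8))
  vals <- th[fov]
  if (!any(vals > 0)) return(.emptyNuclei())
  thr <- EBImage::otsu(EBImage::Image(matrix(vals, nrow = 1L)), range = c(0, 1))
  # noise floor: on a signal-free frame Otsu merely bisects the noise, so
  # require the threshold to clear the background spread as well
  floorThr <- median(vals) + 4 * mad(vals)
  bw <- th >= max(thr, floorThr) & fov
  if (!any(bw)) return(.emptyNuclei())
  lab <- EBImage::imageData(EBImage::watershed(EBImage::distmap(bw), tolerance = 1))
  st <- .labelStats(lab)
  st <- st[st$area >= minNucleusArea & st$area <= maxNucleusArea, , drop = FALSE]
  inFov <- (st$x - frame@fovCenter[1])^2 + (st$y - frame@fovCenter[2])^2 <=
    frame@fovRadius^2
  st <- st[inFov, c("x", "y", "area", "eccentricity"), drop = FALSE]
  rownames(st) <- NULL
  st
}

.emptyNuclei <- function() data.frame(x = numeric(0), y = numeric(0),
                                      area = numeric(0), eccentricity = numeric(0))

#' Standardization reference for the morphometry scorer
#'
#' Midpoints and scales used to standardize the three morphometric features
#' before the logistic combination. The defaults bracket a sparse/regular
#' (normal) and a crowded/enlarged (dysplastic) nuclear phenotype: density
#' 300 vs 900 nuclei/mm^2, mean nuclear radius 3.5 vs 5.25 um, and the
#' nearest-neighbor crowding those densities imply.
#'
#' @return list of (mid, scale) pairs for density (nuclei/mm^2),
#'   meanArea (um^2) and crowding (1/um)
#' @export
morphometryReference <- function() {
  list(density = list(mid = 600, scale = 300),
       meanArea = list(mid = 62, scale = 24),
       crowding = list(mid = 0.047, scale = 0.013))
}

#' Score a frame from nuclear morphometry
#'
#' Three features are computed from the segmented nuclei: density (nuclei
#' per mm^2 of fov), mean nuclear area (um^2) and crowding (reciprocal mean
#' nearest-neighbor distance, 1/um; 0 when fewer than 2 nuclei). Features
#' are standardized by the reference ranges, combined linearly with the
#' given weights and mapped through a logistic to a probability in [0, 1].
#' All features are geometric, so the score is invariant to global intensity
#' scaling of the frame.
#'
#' @param nuclei data.frame from [segmentNuclei]
#' @param frame the scored [MicroFrame-class] (fov geometry)
#' @param umPerPx microscope pixel pitch, um/px
#' @param weights numeric length 4: intercept, density, mean-area and
#'   crowding weights
#' @param reference standardization reference, see [morphometryReference]
#' @return list(score, features); score in [0, 1]
#' @export
scoreFrameMorphometry <- function(nuclei, frame, umPerPx = microUmPerPx(),
                                  weights = c(0, 1, 1, 1),
                                  reference = morphometryReference()) {
  .assert(is(frame, "MicroFrame"), "frame must be a MicroFrame")
  .assert(length(weights) == 4, "weights must have length 4")
  fovAreaMm2 <- pi * (frame@fovRadius * umPerPx / 1000)^2
  n <- nrow(nuclei)
  density <- n / fovAreaMm2
  meanArea <- if (n > 0) mean(nuclei$area) * umPerPx^2 else 0
  crowding <- 0
  if (n >= 2) {
    d <- as.matrix(dist(cbind(nuclei$x, nuclei$y))) * umPerPx
    diag(d) <- Inf
    crowding <- 1 / mean(apply(d, 1, min))
  }
  z <- weights[1] +
    weights[2] * (density - reference$density$mid) / reference$density$scale +
    weights[3] * (meanArea - reference$meanArea$mid) / reference$meanArea$scale +
    weights[4] * (crowding - reference$crowding$mid) / reference$crowding$scale
  list(score = plogis(z),
       features = c(density = density, meanArea = meanArea, crowding = crowding))
}

#' Baseline morphometry scorer (scorer contract)
#'
#' Returns a deterministic function(frame) -> score in [0, 1] satisfying the
#' scorer contract used by [scoreStream]: segment nuclei, compute
#' morphometric features, logistic combination. Any user scorer with the
#' same signature and codomain can replace it (the clinical system used a
#' trained multitask network here; the pipeline only requires a per-frame
#' probability).
#'
#' @param umPerPx,weights,reference passed to [scoreFrameMorphometry]
#' @param minNucleusArea,maxNucleusArea passed to [segmentNuclei]
#' @return function(frame) returning a scalar in [0, 1]
#' @export
morphometryScorer <- function(umPerPx = microUmPerPx(), weights = c(0, 1, 1, 1),
                              reference = morphometryReference(),
                              minNucleusArea = 8, maxNucleusArea = 500) {
  function(frame) {
    nuc <- segmentNuclei(frame, minNucleusArea, maxNucleusArea)
    scoreFrameMorphometry(nuc, frame, umPerPx, weights, reference)$score
  }
}

#' QC and score a stream of microendoscopy frames
#'
#' Applies [qcFrame] to every frame and the scorer only to frames passing
#' both checks. The result for frame t depends only on frame t (streaming
#' contract), mirroring the background real-time scoring of the clinical
#' workflow.
#'
#' @param frames list of [MicroFrame-class] objects, or a function(i)
#'   returning frame i (give \code{nFrames})
#' @param scorer function(frame) -> probability in [0, 1]
#' @param qcParams list of [qcFrame] parameters (contactFloor, minCoverage,
#'   minSharpness)
#' @param nFrames number of frames when \code{frames} is a function
#' @param scorerId identifier recorded in the scorer_id column
#' @return data.frame: frame_index, timestamp_s, coverage_fraction,
#'   sharpness, qc_pass, score (NA when QC fails), scorer_id
#' @export
scoreStream <- function(frames, scorer, qcParams = list(), nFrames = NULL,
                        scorerId = "morphometry") {
  if (is.function(frames)) {
    .assert(!is.null(nFrames), "nFrames is required when frames is a function")
    getFrame <- frames; n <- as.integer(nFrames)
  } else {
    getFrame <- function(i) frames[[i]]; n <- length(frames)
  }
  .assert(is.function(scorer), "scorer must be a function")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- getFrame(i)
    qc <- do.call(qcFrame, c(list(frame = fr), qcParams))
    score <- NA_real_
    if (qc$passContact && qc$passContent) {
      score <- scorer(fr)
      .assert(is.numeric(score) && length(score) == 1 && is.finite(score) &&
                score >= 0 && score <= 1,
              "scorer contract violation: score must be a scalar in [0, 1]")
    }
    out[[i]] <- data.frame(
      frame_index = fr@frameIndex, timestamp_s = fr@timestamp,
      coverage_fraction = qc$coverageFraction, sharpness = qc$sharpness,
      qc_pass = qc$passContact && qc$passContent, score = score,
      scorer_id = scorerId)
  }
  do.call(rbind, out)
}

#' Read/write a frame-score table as CSV
#'
#' @param scores data.frame from [scoreStream]
#' @param path file path
#' @return \code{readScores} returns the data.frame
#' @export
writeScores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  s <- utils::read.csv(path)
  s$qc_pass <- as.logical(s$qc_pass)
  s
}
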