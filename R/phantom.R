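# Synthetic phantom sessions: seeded, ground-truthed emulation of a full
# multimodal imaging session -- WL/AF image pair with an elliptical lesion,
# dual-frame-rate widefield video of a colored probe marker moving along a
# trajectory, and regime-dependent nuclei-bearing microscopy frames.
#
# The AF contrast model follows the neoplasia signature: loss of green
# (collagen) autofluorescence and gain of red (porphyrin) emission inside
# the lesion. Microscopy regimes follow the nuclear phenotypes: sparse,
# regular nuclei when normal; crowded, enlarged nuclei when dysplastic.

#' Parameterization of a synthetic imaging session
#'
#' All generator parameters plus the session seed; see [phantomSpec] for
#' defaults and units. Every derived frame is a deterministic function of
#' (spec, frame index).
#'
#' @slot seed integer session seed
#' @slot widefieldDims c(width, height) px of the widefield frame
#' @slot lesionCenter,lesionSemiAxes,lesionRotationDeg lesion ellipse, px/deg
#' @slot afModel list: greenBg, redBg (background intensities, 0..255),
#'   lesionRedGain (>= 1), lesionGreenLoss (<= 1), noiseSd
#' @slot marker list: hueDeg, radiusPx
#' @slot trajectory n x 2 px waypoint polyline of the probe path
#' @slot speedMmPerS probe speed along the path
#' @slot widefieldFps,microFps frame rates, Hz
#' @slot microDims c(width, height) px of microscopy frames
#' @slot fovRadiusPx microscopy fov-circle radius, px
#' @slot microModel list: normalDensity (nuclei/mm^2),
#'   dysplasticDensityMult, nucleusRadiusUm (list normal/dysplastic of
#'   c(mean, sd)), amplitude, background, noiseSd
#' @slot durationS session duration, s
#' @slot transitionWidthPx width of the optional linear density ramp at the
#'   lesion boundary (0 = instantaneous regime switch)
#' @export
setClass("PhantomSpec", representation(
  seed = "numeric", widefieldDims = "integer", lesionCenter = "numeric",
  lesionSemiAxes = "numeric", lesionRotationDeg = "numeric", afModel = "list",
  marker = "list", trajectory = "matrix", speedMmPerS = "numeric",
  widefieldFps = "numeric", microFps = "numeric", microDims = "integer",
  fovRadiusPx = "numeric", microModel = "list", durationS = "numeric",
  transitionWidthPx = "numeric"))

setValidity("PhantomSpec", function(object) {
  d <- object@widefieldDims
  c0 <- object@lesionCenter; ax <- object@lesionSemiAxes
  if (any(ax <= 0)) return("lesion semi-axes must be positive")
  r <- max(ax)
  if (c0[1] - r < 0 || c0[1] + r > d[1] - 1 || c0[2] - r < 0 || c0[2] + r > d[2] - 1)
    return("lesion must lie inside the frame")
  tr <- object@trajectory
  if (any(tr[, 1] < 0 | tr[, 1] > d[1] - 1 | tr[, 2] < 0 | tr[, 2] > d[2] - 1))
    return("trajectory exits the frame")
  if (object@microModel$normalDensity <= 0) return("densities must be positive")
  if (object@microModel$dysplasticDensityMult < 1) return("dysplasticDensityMult must be >= 1")
  if (object@microFps < object@widefieldFps) return("microFps must be >= widefieldFps")
  if (object@durationS <= 0 || object@speedMmPerS <= 0) return("duration and speed must be positive")
  TRUE
})

#' Construct a phantom session specification
#'
#' Defaults emulate the target acquisition geometry: a 960 x 600 widefield
#' frame spanning 80 x 50 mm, 20 fps widefield video, 90 fps microscopy at
#' 720 x 540 px, a teal ligature marker, an elliptical lesion with 2x red
#' gain and 0.6x green loss, additive Gaussian noise at 2% of the dynamic
#' range, and a two-regime nuclear model (normal: 300 nuclei/mm^2, 3.5 um
#' mean radius; dysplastic: 3x density, 1.5x radius).
#'
#' @param seed session seed (integer)
#' @param widefieldDims,lesionCenter,lesionSemiAxes,lesionRotationDeg,afModel
#'   see [PhantomSpec-class]
#' @param marker,trajectory,speedMmPerS,widefieldFps,microFps,microDims see
#'   [PhantomSpec-class]
#' @param fovRadiusPx,microModel,durationS,transitionWidthPx see
#'   [PhantomSpec-class]
#' @return a [PhantomSpec-class]
#' @examples
#' spec <- phantomSpec(seed = 7)
#' pair <- generateAFPair(spec)
#' dim(pair$af)
#' @export
phantomSpec <- function(
    seed = 1L,
    widefieldDims = c(960L, 600L),
    lesionCenter = c(600, 300),
    lesionSemiAxes = c(130, 85),
    lesionRotationDeg = 20,
    afModel = list(greenBg = 120, redBg = 40, lesionRedGain = 2.0,
                   lesionGreenLoss = 0.6, noiseSd = 0.02 * 255),
    marker = list(hueDeg = 180, radiusPx = 6),
    trajectory = cbind(c(330, 860), c(270, 330)),
    speedMmPerS = 15,
    widefieldFps = 20,
    microFps = 90,
    microDims = c(720L, 540L),
    fovRadiusPx = 260,
    microModel = list(normalDensity = 300, dysplasticDensityMult = 3,
                      nucleusRadiusUm = list(normal = c(3.5, 0.4),
                                             dysplastic = c(5.25, 0.6)),
                      amplitude = 140, background = 30, noiseSd = 0.02 * 255),
    durationS = 3,
    transitionWidthPx = 0) {
  new("PhantomSpec", seed = as.numeric(seed),
      widefieldDims = as.integer(widefieldDims),
      lesionCenter = lesionCenter, lesionSemiAxes = lesionSemiAxes,
      lesionRotationDeg = lesionRotationDeg, afModel = afModel,
      marker = marker, trajectory = as.matrix(trajectory),
      speedMmPerS = speedMmPerS, widefieldFps = widefieldFps,
      microFps = microFps, microDims = as.integer(microDims),
      fovRadiusPx = fovRadiusPx, microModel = microModel,
      durationS = durationS, transitionWidthPx = transitionWidthPx)
}

# signed ellipse membership weight in [0,1]: 1 inside, 0 outside, used both
# binary (lesion mask) and as a feathered mixing weight
.lesionMask <- function(spec) {
  d <- spec@widefieldDims
  th <- spec@lesionRotationDeg * pi / 180
  x <- .gridX(d[1], d[2]) - spec@lesionCenter[1]
  y <- .gridY(d[1], d[2]) - spec@lesionCenter[2]
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / spec@lesionSemiAxes[1])^2 + (v / spec@lesionSemiAxes[2])^2 <= 1
}

#' Generate the white-light / autofluorescence phantom image pair
#'
#' The AF image applies the lesion contrast model (red gain, green loss)
#' with a ~2 px feathered boundary and additive Gaussian noise clipped at
#' zero. The WL image is a textured pink mucosa rendering used only for
#' overlays and marker video. Deterministic under the spec seed.
#'
#' @param spec a [PhantomSpec-class]
#' @return list(wl, af, lesionMask): two width x height x 3 arrays
#'   (0..255) and the binary ground-truth lesion mask
#' @export
generateAFPair <- function(spec) {
  .assert(is(spec, "PhantomSpec"), "spec must be a PhantomSpec")
  validObject(spec)
  d <- spec@widefieldDims
  lesion <- .lesionMask(spec)
  wgt <- EBImage::imageData(EBImage::gblur(lesion * 1, sigma = 1))
  am <- spec@afModel

  set.seed(.frameSeed(spec@seed, 1, 0))
  af <- array(0, c(d[1], d[2], 3))
  af[, , 1] <- am$redBg * (1 + wgt * (am$lesionRedGain - 1))
  af[, , 2] <- am$greenBg * (1 - wgt * (1 - am$lesionGreenLoss))
  af[, , 3] <- 15
  af <- af + array(rnorm(length(af), 0, am$noiseSd), dim(af))
  af <- .clamp(af, 0, 255)

  tex <- EBImage::imageData(EBImage::gblur(matrix(rnorm(d[1] * d[2]), d[1], d[2]),
                                           sigma = 12))
  tex <- 40 * tex / max(abs(tex), 1e-9)
  wl <- array(0, c(d[1], d[2], 3))
  wl[, , 1] <- 205 + tex
  wl[, , 2] <- 140 + tex
  wl[, , 3] <- 150 + tex
  wl <- .clamp(wl + array(rnorm(length(wl), 0, am$noiseSd), dim(wl)), 0, 255)
  list(wl = wl, af = af, lesionMask = lesion)
}

#' Generate one microscopy frame with ground-truth nuclei
#'
#' Nucleus centers are drawn from a hard-core point process inside the fov
#' circle (minimum separation one nucleus diameter for the normal regime,
#' half a diameter for the dysplastic regime) at the regime's density;
#' counts are Poisson around density x fov area. Each nucleus is rendered
#' as an isotropic Gaussian blob with the regime's radius distribution over
#' a dark background with additive noise; pixels outside the fov circle are
#' vignetted to near zero. Deterministic under (spec seed, seedOffset).
#'
#' @param spec a [PhantomSpec-class]
#' @param regime "normal" or "dysplastic"
#' @param seedOffset integer distinguishing frames of one session
#' @param densityFactor optional override of the density multiplier
#'   (used by the optional boundary transition ramp); default by regime
#' @return list(frame = [MicroFrame-class], nuclei = data.frame(x, y,
#'   radius_px))
#' @export
generateMicroFrame <- function(spec, regime = c("normal", "dysplastic"),
                               seedOffset = 0L, densityFactor = NULL) {
  .assert(is(spec, "PhantomSpec"), "spec must be a PhantomSpec")
  regime <- match.arg(regime)
  mm <- spec@microModel
  d <- spec@microDims
  umPerPx <- microUmPerPx()
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  R <- spec@fovRadiusPx
  if (is.null(densityFactor))
    densityFactor <- if (regime == "dysplastic") mm$dysplasticDensityMult else 1
  density <- mm$normalDensity * densityFactor
  fovAreaMm2 <- pi * (R * umPerPx / 1000)^2

  set.seed(.frameSeed(spec@seed, 2, seedOffset))
  n <- rpois(1, density * fovAreaMm2)
  rpar <- mm$nucleusRadiusUm[[regime]]
  radii <- pmax(rnorm(n, rpar[1], rpar[2]), rpar[1] / 2) / umPerPx
  minSep <- (if (regime == "normal") 2 else 1) * mean(radii)

  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L; maxTries <- 200L * max(n, 1L)
  while (length(xs) < n && tries < maxTries) {
    tries <- tries + 1L
    a <- runif(1, 0, 2 * pi); r <- R * sqrt(runif(1))
    px <- cx + r * cos(a); py <- cy + r * sin(a)
    if (!length(xs) || min((xs - px)^2 + (ys - py)^2) >= minSep^2) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  .assert(length(xs) == n, sprintf(
    "hard-core placement failed: placed %d of %d nuclei (density %.0f/mm^2, min sep %.1f px)",
    length(xs), n, density, minSep))
  radii <- radii[seq_len(n)]

  img <- matrix(mm$background, d[1], d[2])
  for (k in seq_len(n)) {
    sg <- radii[k] / 1.5
    ext <- ceiling(3 * sg)
    x0 <- max(0, round(xs[k]) - ext); x1 <- min(d[1] - 1, round(xs[k]) + ext)
    y0 <- max(0, round(ys[k]) - ext); y1 <- min(d[2] - 1, round(ys[k]) + ext)
    gx <- x0:x1; gy <- y0:y1
    blob <- mm$amplitude *
      outer(exp(-(gx - xs[k])^2 / (2 * sg^2)), exp(-(gy - ys[k])^2 / (2 * sg^2)))
    img[gx + 1, gy + 1] <- img[gx + 1, gy + 1] + blob
  }
  img <- img + matrix(rnorm(d[1] * d[2], 0, mm$noiseSd), d[1], d[2])
  fov <- .fovMask(d[1], d[2], cx, cy, R)
  img[!fov] <- abs(rnorm(sum(!fov), 0, 1))
  img <- .clamp(img, 0, 255)
  list(frame = microFrame(img, frameIndex = seedOffset,
                          fovCenter = c(cx, cy), fovRadius = R),
       nuclei = data.frame(x = xs, y = ys, radius_px = radii))
}

# tip position (px) at time t along the waypoint polyline at constant speed
.tipAt <- function(spec, t, cal) {
  tr <- spec@trajectory
  seg <- sqrt(diff(tr[, 1])^2 + diff(tr[, 2])^2)
  segMm <- pixelsToMm(cal, diff(tr[, 1]), diff(tr[, 2]))
  cumMm <- c(0, cumsum(segMm))
  total <- cumMm[length(cumMm)]
  s <- .clamp(spec@speedMmPerS * t, 0, total)
  i <- pmin(findInterval(s, cumMm, rightmost.closed = TRUE), length(seg))
  frac <- ifelse(segMm[i] > 0, (s - cumMm[i]) / segMm[i], 0)
  cbind(x = tr[i, 1] + frac * (tr[i + 1, 1] - tr[i, 1]),
        y = tr[i, 2] + frac * (tr[i + 1, 2] - tr[i, 2]))
}

#' Generate a complete synthetic imaging session
#'
#' The probe tip moves along the spec's trajectory at constant speed; the
#' widefield stream renders the teal marker disc over the WL phantom at
#' \code{widefieldFps}, and the microscopy stream generates nuclei frames at
#' \code{microFps} whose regime is dysplastic exactly when the true tip
#' position lies inside the ground-truth lesion (with an optional linear
#' density ramp of \code{transitionWidthPx} at the boundary). Both streams
#' share one clock. Frames are returned as lazy per-index closures, each a
#' deterministic function of (seed, stream, index), so a session is
#' reproducible bit-for-bit without holding all frames in memory.
#'
#' @param spec a [PhantomSpec-class]
#' @return list with elements: \code{spec}; \code{cal}
#'   ([CalibrationModel-class]); \code{wl}, \code{af}, \code{lesionMask};
#'   \code{nWidefield}, \code{nMicro}; \code{widefieldTimestamps},
#'   \code{microTimestamps}; \code{widefieldFrame(i)} RGB array;
#'   \code{microFrame(i)} [MicroFrame-class]; \code{truth} = list(track
#'   [ProbeTrack-class], regimes character vector, tipAtMicro n x 2,
#'   nuclei(i) data.frame)
#' @export
generateSession <- function(spec) {
  .assert(is(spec, "PhantomSpec"), "spec must be a PhantomSpec")
  validObject(spec)
  d <- spec@widefieldDims
  cal <- calibrationModel(d[1], d[2], 80 / 960, 50 / 600)
  pair <- generateAFPair(spec)

  nW <- max(1L, round(spec@durationS * spec@widefieldFps))
  nM <- max(1L, round(spec@durationS * spec@microFps))
  tW <- (seq_len(nW) - 1) / spec@widefieldFps
  tM <- (seq_len(nM) - 1) / spec@microFps

  tipW <- .tipAt(spec, tW, cal)
  tipM <- .tipAt(spec, tM, cal)
  lesion <- pair$lesionMask
  inLesion <- lesion[cbind(round(tipM[, 1]) + 1L, round(tipM[, 2]) + 1L)]
  regimes <- ifelse(inLesion, "dysplastic", "normal")

  markerHex <- grDevices::hsv(spec@marker$hueDeg / 360, 0.85, 0.8)
  markerRGB <- as.numeric(grDevices::col2rgb(markerHex))
  rad <- spec@marker$radiusPx
  noiseSd <- spec@afModel$noiseSd
  wl <- pair$wl

  widefieldFrame <- function(i) {
    .assert(i >= 1 && i <= nW, "widefield frame index out of range")
    set.seed(.frameSeed(spec@seed, 3, i))
    fr <- wl
    tx <- tipW[i, 1]; ty <- tipW[i, 2]
    ext <- ceiling(rad + 1)
    gx <- max(0, floor(tx) - ext):min(d[1] - 1, ceiling(tx) + ext)
    gy <- max(0, floor(ty) - ext):min(d[2] - 1, ceiling(ty) + ext)
    dist <- sqrt(outer((gx - tx)^2, (gy - ty)^2, "+"))
    cov <- .clamp(rad + 0.5 - dist, 0, 1)
    for (ch in 1:3) {
      patch <- fr[gx + 1, gy + 1, ch]
      fr[gx + 1, gy + 1, ch] <- (1 - cov) * patch + cov * markerRGB[ch]
    }
    .clamp(fr + array(rnorm(length(fr), 0, noiseSd), dim(fr)), 0, 255)
  }

  densityFactorAt <- function(i) {
    if (spec@transitionWidthPx <= 0) return(NULL)
    # linear ramp of the density multiplier across the lesion boundary
    th <- spec@lesionRotationDeg * pi / 180
    x <- tipM[i, 1] - spec@lesionCenter[1]; y <- tipM[i, 2] - spec@lesionCenter[2]
    u <- x * cos(th) + y * sin(th); v <- -x * sin(th) + y * cos(th)
    q <- sqrt((u / spec@lesionSemiAxes[1])^2 + (v / spec@lesionSemiAxes[2])^2)
    dpx <- (q - 1) * min(spec@lesionSemiAxes)  # approx signed boundary distance
    t <- .clamp(0.5 - dpx / spec@transitionWidthPx, 0, 1)
    1 + t * (spec@microModel$dysplasticDensityMult - 1)
  }

  microGen <- function(i) {
    .assert(i >= 1 && i <= nM, "micro frame index out of range")
    i <- as.integer(i)
    out <- generateMicroFrame(spec, regimes[i], seedOffset = i,
                              densityFactor = densityFactorAt(i))
    out$frame@timestamp <- tM[i]
    out$frame@frameIndex <- i - 1L
    out
  }

  truthTrack <- probeTrack(data.frame(
    frame_index = seq_len(nW) - 1L, timestamp_s = tW,
    x_px = tipW[, 1], y_px = tipW[, 2],
    blob_area_px2 = pi * rad^2, valid = TRUE, interpolated = FALSE))

  list(spec = spec, cal = cal, wl = pair$wl, af = pair$af,
       lesionMask = lesion, nWidefield = nW, nMicro = nM,
       widefieldTimestamps = tW, microTimestamps = tM,
       widefieldFrame = widefieldFrame,
       microFrame = function(i) microGen(i)$frame,
       truth = list(track = truthTrack, regimes = regimes, tipAtMicro = tipM,
                    nuclei = function(i) microGen(i)$nuclei))
}
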