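# Mosaicking of high-frame-rate microendoscopy video: translation-only
# registration by phase correlation, feathered compositing, and the
# average-score-versus-distance profile along the imaging path.
#
# At 90 fps consecutive frames overlap almost entirely, so translation is
# the dominant inter-frame motion; rotation and deformation are not modeled.

#' Register two microendoscopy frames by phase correlation
#'
#' Phase correlation restricted to the fov circle (pixels outside it are
#' replaced by the in-fov mean intensity), with the integer peak refined to
#' subpixel precision by a parabolic fit. The returned shift (dx, dy) is the
#' displacement of frame b's content relative to frame a: shifting a by
#' (dx, dy) aligns it with b. \code{correlationPeak} is the normalized peak
#' height, ~1 for identical frames and near 0 for unrelated ones; a low
#' peak is reported, never raised as an error.
#'
#' @param a,b [MicroFrame-class] objects with equal dims
#' @return list(dx, dy, correlationPeak)
#' @export
registerPair <- function(a, b) {
  .assert(is(a, "MicroFrame") && is(b, "MicroFrame"),
          "a and b must be MicroFrame objects")
  .assert(all(dim(a@pixels) == dim(b@pixels)), "frames must share dims")
  pa <- .fovPrep(a); pb <- .fovPrep(b)
  n <- length(pa)
  Fa <- fft(pa); Fb <- fft(pb)
  Q <- Fb * Conj(Fa)
  R <- Q / pmax(Mod(Q), 1e-12)
  r <- Re(fft(R, inverse = TRUE)) / n
  w <- nrow(r); h <- ncol(r)
  p <- which.max(r)
  pxi <- (p - 1L) %% w; pyi <- (p - 1L) %/% w
  wrap <- function(i, m) ifelse(i > m / 2, i - m, i)
  # parabolic subpixel refinement along each axis (wrap-aware neighbors)
  sub <- function(rm1, r0, rp1) {
    den <- rm1 - 2 * r0 + rp1
    if (abs(den) < 1e-12) 0 else .clamp(0.5 * (rm1 - rp1) / den, -0.5, 0.5)
  }
  xm <- r[(pxi - 1L) %% w + 1L, pyi + 1L]; xp <- r[(pxi + 1L) %% w + 1L, pyi + 1L]
  ym <- r[pxi + 1L, (pyi - 1L) %% h + 1L]; yp <- r[pxi + 1L, (pyi + 1L) %% h + 1L]
  dx <- wrap(pxi, w) + sub(xm, r[p], xp)
  dy <- wrap(pyi, h) + sub(ym, r[p], yp)
  list(dx = dx, dy = dy, correlationPeak = max(r))
}

.fovPrep <- function(fr) {
  px <- fr@pixels
  fov <- .fovMask(nrow(px), ncol(px), fr@fovCenter[1], fr@fovCenter[2],
                  fr@fovRadius)
  m <- mean(px[fov])
  px[!fov] <- m
  px - m
}

#' Build a mosaic from a microendoscopy frame sequence
#'
#' Global frame offsets are obtained by chaining pairwise registrations.
#' When a pair's correlation peak falls below \code{minPeak} the chain
#' breaks: the new frame keeps the last valid offset and is flagged
#' \code{chained_valid = FALSE} (data preserved, geometry flagged), and
#' chaining restarts from there. Frames are composited by feathered
#' averaging, weighting each pixel by its distance to the fov-circle edge so
#' seams blend smoothly.
#'
#' @param frames list of QC-passing [MicroFrame-class] objects
#' @param scores optional numeric vector of per-frame scores recorded in the
#'   placements table
#' @param minPeak correlation-peak floor for a trusted registration
#' @param umPerPx microscope pixel pitch, um/px
#' @return a [MosaicCanvas-class]
#' @export
buildMosaic <- function(frames, scores = NULL, minPeak = 0.2,
                        umPerPx = microUmPerPx()) {
  .assert(length(frames) >= 1, "at least one frame is required")
  n <- length(frames)
  off <- matrix(0, n, 2)
  peak <- numeric(n); peak[1] <- 1
  chained <- logical(n); chained[1] <- TRUE
  for (i in seq_len(n)[-1]) {
    reg <- registerPair(frames[[i - 1]], frames[[i]])
    peak[i] <- reg$correlationPeak
    if (reg$correlationPeak >= minPeak) {
      off[i, ] <- off[i - 1, ] + c(reg$dx, reg$dy)
      chained[i] <- TRUE
    } else {
      off[i, ] <- off[i - 1, ]
      chained[i] <- FALSE
    }
  }

  d <- dim(frames[[1]]@pixels)
  fr1 <- frames[[1]]
  fov <- .fovMask(d[1], d[2], fr1@fovCenter[1], fr1@fovCenter[2], fr1@fovRadius)
  feather <- EBImage::imageData(EBImage::distmap(fov))
  feather <- feather / max(feather)

  oi <- round(off)
  x0 <- min(oi[, 1]); y0 <- min(oi[, 2])
  W <- max(oi[, 1]) - x0 + d[1]; H <- max(oi[, 2]) - y0 + d[2]
  acc <- matrix(0, W, H); wacc <- matrix(0, W, H)
  for (i in seq_len(n)) {
    xs <- (oi[i, 1] - x0 + 1):(oi[i, 1] - x0 + d[1])
    ys <- (oi[i, 2] - y0 + 1):(oi[i, 2] - y0 + d[2])
    acc[xs, ys] <- acc[xs, ys] + frames[[i]]@pixels * feather
    wacc[xs, ys] <- wacc[xs, ys] + feather
  }
  img <- matrix(0, W, H)
  vis <- wacc > 0
  img[vis] <- acc[vis] / wacc[vis]

  pl <- data.frame(
    frame_index = vapply(frames, function(f) f@frameIndex, integer(1)),
    dx_px = off[, 1], dy_px = off[, 2], correlation_peak = peak,
    chained_valid = chained)
  if (!is.null(scores)) pl$score <- scores
  new("MosaicCanvas", image = img, weight = wacc, placements = pl,
      umPerPx = umPerPx)
}

#' Average score versus distance along the imaging path
#'
#' Cumulative arc length is computed along the smoothed probe track; each
#' scored microscope frame inherits the arc length of its associated
#' widefield frame, and scores are averaged in consecutive bins of
#' \code{binWidthMm}. This is the profile that exposes low-risk, transition
#' and high-risk zones as the probe crosses a lesion boundary.
#'
#' @param track a [ProbeTrack-class] with at least 2 valid entries
#' @param scores data.frame from [scoreStream]
#' @param assoc data.frame from [associateFrames]
#' @param cal a [CalibrationModel-class]
#' @param binWidthMm bin width along the path, default 0.5 mm
#' @return data.frame: arc_length_mm (bin left edge, nondecreasing),
#'   mean_score, n_frames
#' @export
scoreProfile <- function(track, scores, assoc, cal, binWidthMm = 0.5) {
  .assert(is(track, "ProbeTrack"), "track must be a ProbeTrack")
  e <- track@entries[track@entries$valid, , drop = FALSE]
  .assert(nrow(e) >= 2, "track needs at least 2 valid entries")
  step <- pixelsToMm(cal, diff(e$x_px), diff(e$y_px))
  arc <- c(0, cumsum(step))
  scored <- scores[!is.na(scores$score), , drop = FALSE]
  ai <- match(scored$frame_index, assoc$micro_index)
  wf <- assoc$widefield_index[ai]
  ti <- match(wf, e$frame_index)
  ok <- !is.na(ai) & !is.na(ti)
  .assert(any(ok), "no scored frames could be assigned an arc length")
  s <- scored$score[ok]; a <- arc[ti[ok]]
  bin <- floor(a / binWidthMm)
  agg <- rowsum(cbind(s, 1), bin)
  data.frame(arc_length_mm = as.numeric(rownames(agg)) * binWidthMm,
             mean_score = agg[, 1] / agg[, 2], n_frames = as.integer(agg[, 2]),
             row.names = NULL)
}

#' Write a mosaic to disk
#'
#' 16-bit TIFF (intensities scaled from the nominal 0..255 range) plus a
#' placements CSV.
#'
#' @param mosaic a [MosaicCanvas-class]
#' @param imagePath,placementsPath output paths
#' @return invisibly, the image path
#' @export
writeMosaic <- function(mosaic, imagePath, placementsPath) {
  .assert(is(mosaic, "MosaicCanvas"), "mosaic must be a MosaicCanvas")
  img <- .clamp(t(mosaic@image) / 255, 0, 1)
  tiff::writeTIFF(img, imagePath, bits.per.sample = 16L)
  utils::write.csv(mosaic@placements, placementsPath, row.names = FALSE)
  invisible(imagePath)
}
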