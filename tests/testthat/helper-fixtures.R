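# In-code fixtures shared across tests. All synthetic, built at test time.

# RGB frame (w x h x 3, 0..255) of a pinkish background with an optional
# hard-thresholded colored disc at (x, y). Disc centered on integer pixels
# is symmetric, so its centroid is exactly (x, y).
makeMarkerFrame <- function(w = 200, h = 100, x = NA, y = NA, radius = 4,
                            hue = 180, sat = 0.9, val = 0.8) {
  fr <- array(0, c(w, h, 3))
  fr[, , 1] <- 205; fr[, , 2] <- 140; fr[, , 3] <- 150
  if (!is.na(x)) {
    rgb <- as.numeric(grDevices::col2rgb(grDevices::hsv(hue / 360, sat, val)))
    gx <- matrix(rep(0:(w - 1), h), w, h)
    gy <- matrix(rep(0:(h - 1), each = w), w, h)
    disc <- (gx - x)^2 + (gy - y)^2 <= radius^2
    for (ch in 1:3) {
      plane <- fr[, , ch]; plane[disc] <- rgb[ch]; fr[, , ch] <- plane
    }
  }
  fr
}

# grayscale micro-style frame with Gaussian-blob nuclei at given centers
makeBlobFrame <- function(centers, radiiPx = 3.2, w = 240, h = 240,
                          background = 30, amplitude = 140, noiseSd = 0,
                          fovRadius = min(w, h) / 2 - 4) {
  img <- matrix(background, w, h)
  radiiPx <- rep(radiiPx, length.out = nrow(centers))
  for (k in seq_len(nrow(centers))) {
    sg <- radiiPx[k] / 1.5
    ext <- ceiling(3 * sg)
    gx <- max(0, round(centers[k, 1]) - ext):min(w - 1, round(centers[k, 1]) + ext)
    gy <- max(0, round(centers[k, 2]) - ext):min(h - 1, round(centers[k, 2]) + ext)
    img[gx + 1, gy + 1] <- img[gx + 1, gy + 1] + amplitude *
      outer(exp(-(gx - centers[k, 1])^2 / (2 * sg^2)),
            exp(-(gy - centers[k, 2])^2 / (2 * sg^2)))
  }
  if (noiseSd > 0) img <- img + matrix(rnorm(w * h, 0, noiseSd), w, h)
  microFrame(pmin(pmax(img, 0), 255), fovRadius = fovRadius)
}

# independent even-odd point-in-polygon oracle (per-pixel loop)
pointInPolygonOracle <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xi <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      if (px < xi) inside <- !inside
    }
    j <- i
  }
  inside
}

# independent rank-based AUROC (Wilcoxon statistic), oracle for pROC-based code
aurocOracle <- function(scoresPos, scoresNeg) {
  r <- rank(c(scoresPos, scoresNeg))
  n1 <- length(scoresPos); n2 <- length(scoresNeg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# master texture cropped into overlapping windows: real (non-circular)
# shifts with known ground truth
makeWindows <- function(n, stepX = 20, w = 360, h = 280, seed = 42) {
  set.seed(seed)
  W <- w + stepX * (n - 1)
  master <- matrix(30 + rnorm(W * h, 0, 5), W, h)
  cx <- runif(400, 10, W - 10); cy <- runif(400, 10, h - 10)
  for (k in seq_along(cx)) {
    sg <- 2.2; ext <- 7
    gx <- max(1, round(cx[k]) - ext):min(W, round(cx[k]) + ext)
    gy <- max(1, round(cy[k]) - ext):min(h, round(cy[k]) + ext)
    master[gx, gy] <- master[gx, gy] + 140 *
      outer(exp(-(gx - cx[k])^2 / (2 * sg^2)), exp(-(gy - cy[k])^2 / (2 * sg^2)))
  }
  lapply(seq_len(n), function(i) {
    microFrame(master[(1 + stepX * (i - 1)):(w + stepX * (i - 1)), ],
               frameIndex = i - 1L, fovRadius = min(w, h) / 2 - 4)
  })
}

# quick probe track straight along x at constant speed (valid everywhere)
makeLineTrack <- function(n, x0 = 0, y0 = 50, stepPx = 12) {
  probeTrack(data.frame(
    frame_index = seq_len(n) - 1L, timestamp_s = (seq_len(n) - 1) / 20,
    x_px = x0 + stepPx * (seq_len(n) - 1), y_px = y0,
    blob_area_px2 = 100, valid = TRUE, interpolated = FALSE))
}
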