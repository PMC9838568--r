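# Internal helpers shared across modules.
#
# Image convention (package-wide): grayscale images are numeric matrices of
# dim c(width, height); RGB images are arrays of dim c(width, height, 3).
# Pixel (x, y) is 0-based with origin at the top-left pixel center and lives
# at m[x + 1, y + 1]. This matches EBImage's storage order, so matrices pass
# to EBImage functions without transposition.

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

.isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

# deterministic per-frame seed stream, kept < 2^31
.frameSeed <- function(seed, stream, i) {
  (as.numeric(seed) * 10007 + stream * 1000003 + i * 97) %% 2147483629
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# pixel-center coordinate grids for a W x H image (0-based)
.gridX <- function(w, h) matrix(rep(0:(w - 1L), times = h), w, h)
.gridY <- function(w, h) matrix(rep(0:(h - 1L), each = w), w, h)

# integer offsets of a filled disc of given radius (centred at 0,0)
.discOffsets <- function(radius) {
  r <- max(0, radius)
  k <- floor(r)
  dx <- rep(-k:k, times = 2L * k + 1L)
  dy <- rep(-k:k, each = 2L * k + 1L)
  keep <- dx * dx + dy * dy <= r * r
  cbind(dx = dx[keep], dy = dy[keep])
}

# boolean fov-circle mask for a W x H frame
.fovMask <- function(w, h, cx, cy, radius) {
  (.gridX(w, h) - cx)^2 + (.gridY(w, h) - cy)^2 <= radius^2
}

# 8-connectivity labeling: EBImage::bwlabel (4-connectivity) followed by a
# vectorized merge of labels touching diagonally, via union-find on labels.
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  w <- nrow(lab); h <- ncol(lab)
  a1 <- lab[-w, -h]; b1 <- lab[-1, -1]   # down-right diagonal pairs
  a2 <- lab[-w, -1]; b2 <- lab[-1, -h]   # up-right diagonal pairs
  pa <- c(a1[a1 > 0 & b1 > 0 & a1 != b1], a2[a2 > 0 & b2 > 0 & a2 != b2])
  pb <- c(b1[a1 > 0 & b1 > 0 & a1 != b1], b2[a2 > 0 & b2 > 0 & a2 != b2])
  if (length(pa)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_along(pa)) {
      ra <- find(pa[k]); rb <- find(pb[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1))
    dense <- match(root, sort(unique(root)))
    lab[lab > 0] <- dense[lab[lab > 0]]
  }
  lab
}

# per-label centroid (0-based px), area (px^2) and eccentricity from second
# central moments; vectorized over labels with rowsum
.labelStats <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), eccentricity = numeric(0)))
  }
  l <- lab[idx]
  w <- nrow(lab)
  x <- (idx - 1L) %% w
  y <- (idx - 1L) %/% w
  area <- as.vector(rowsum(rep(1, length(l)), l))
  labels <- as.integer(rownames(rowsum(rep(1, length(l)), l)))
  cx <- as.vector(rowsum(x, l)) / area
  cy <- as.vector(rowsum(y, l)) / area
  ord <- match(l, labels)
  dx <- x - cx[ord]; dy <- y - cy[ord]
  mxx <- as.vector(rowsum(dx * dx, l)) / area
  myy <- as.vector(rowsum(dy * dy, l)) / area
  mxy <- as.vector(rowsum(dx * dy, l)) / area
  tr <- mxx + myy
  dt <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + dt) / 2
  l2 <- (tr - dt) / 2
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  data.frame(label = labels, x = cx, y = cy, area = area, eccentricity = ecc)
}
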