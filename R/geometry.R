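# Planar geometry: homography estimation and application, binary mask
# warping into projector coordinates, and pixel-to-millimeter conversion.

#' Estimate a planar homography from point correspondences
#'
#' Direct linear transform with Hartley coordinate pre-normalization
#' (centroid to origin, mean distance sqrt(2)). With exactly 4 points and
#' \code{method = "exact4"} the correspondences are interpolated exactly; with
#' \code{method = "leastSquares"} the algebraic error over all
#' correspondences is minimized via SVD.
#'
#' This is the software analogue of coregistering the widefield camera with
#' the guidance-map projector: fiducials seen by both define the planar map
#' between the two image planes.
#'
#' @param src,dst n x 2 matrices of (x, y) pixel coordinates, n >= 4
#' @param method "leastSquares" (default) or "exact4"
#' @return a [PlanarHomography-class] mapping src-plane to dst-plane
#' @examples
#' src <- cbind(c(0, 959, 959, 0), c(0, 0, 599, 599))
#' h <- estimateHomography(src, src + 5)  # pure translation
#' applyHomography(h, cbind(10, 10))
#' @export
estimateHomography <- function(src, dst, method = c("leastSquares", "exact4")) {
  method <- match.arg(method)
  src <- .asPointSet(src); dst <- .asPointSet(dst)
  .assert(nrow(src) == nrow(dst), "src and dst must have the same number of points")
  .assert(nrow(src) >= 4L, "at least 4 correspondences are required")
  if (method == "exact4") {
    .assert(nrow(src) == 4L, "exact4 requires exactly 4 correspondences")
    .assert(!.anyCollinear(src), "exact4 requires no 3 source points collinear")
  }
  .assert(!.degenerate(src) && !.degenerate(dst),
          "degenerate point configuration (duplicate or collinear points)")

  ns <- .normalizePoints(src); nd <- .normalizePoints(dst)
  x <- ns$pts[, 1]; y <- ns$pts[, 2]
  u <- nd$pts[, 1]; v <- nd$pts[, 2]
  n <- length(x)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  .assert(abs(det(H)) > 1e-12 && abs(H[3, 3]) > 1e-12,
          "homography estimation failed (degenerate configuration)")
  planarHomography(H)
}

.asPointSet <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  .assert(is.numeric(p) && ncol(p) == 2 && all(is.finite(p)),
          "points must be a finite n x 2 numeric matrix")
  unname(p)
}

.degenerate <- function(p) {
  if (anyDuplicated(p)) return(TRUE)
  # all points collinear
  if (nrow(p) >= 3) {
    d <- sweep(p, 2, p[1, ])
    s <- svd(d)$d
    if (s[2] < 1e-9 * max(s[1], 1)) return(TRUE)
  }
  FALSE
}

.anyCollinear <- function(p) {
  cmb <- utils::combn(nrow(p), 3)
  for (k in seq_len(ncol(cmb))) {
    a <- p[cmb[1, k], ]; b <- p[cmb[2, k], ]; c <- p[cmb[3, k], ]
    area2 <- abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2]))
    if (area2 < 1e-9) return(TRUE)
  }
  FALSE
}

.normalizePoints <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3, byrow = TRUE)
  list(pts = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])), T = T)
}

#' Apply a homography to points
#'
#' Projective transform applied pointwise; order is preserved. Points whose
#' homogeneous scale vanishes (mapping to infinity) are returned as NA.
#'
#' @param h a [PlanarHomography-class]
#' @param pts n x 2 matrix of (x, y) coordinates
#' @return n x 2 matrix of transformed coordinates
#' @export
applyHomography <- function(h, pts) {
  .assert(is(h, "PlanarHomography"), "h must be a PlanarHomography")
  pts <- .asPointSet(pts)
  ph <- h@matrix %*% rbind(t(pts), 1)
  w <- ph[3, ]
  bad <- abs(w) < 1e-12
  w[bad] <- NA_real_
  out <- cbind(ph[1, ] / w, ph[2, ] / w)
  colnames(out) <- c("x", "y")
  out
}

#' Invert a homography
#'
#' @param h a [PlanarHomography-class]
#' @return the inverse [PlanarHomography-class]
#' @export
invertHomography <- function(h) {
  .assert(is(h, "PlanarHomography"), "h must be a PlanarHomography")
  planarHomography(solve(h@matrix))
}

#' Warp a binary mask into another image plane
#'
#' Inverse-mapped nearest-neighbor warp: each output pixel center is mapped
#' through the inverse homography and takes the value of the nearest source
#' pixel; pixels mapping outside the source are 0. Nearest neighbor keeps
#' the output strictly binary (no gray halos in a projected guidance map).
#'
#' @param h [PlanarHomography-class], source plane -> output plane
#' @param mask logical or 0/1 matrix (width x height)
#' @param outWidth,outHeight output dimensions in px
#' @return logical matrix of dim c(outWidth, outHeight)
#' @export
warpBinaryMask <- function(h, mask, outWidth = nrow(mask), outHeight = ncol(mask)) {
  .assert(is(h, "PlanarHomography"), "h must be a PlanarHomography")
  .assert(is.matrix(mask), "mask must be a matrix")
  hin <- solve(h@matrix)
  w <- as.integer(outWidth); ht <- as.integer(outHeight)
  gx <- as.vector(.gridX(w, ht)); gy <- as.vector(.gridY(w, ht))
  ph <- hin %*% rbind(gx, gy, 1)
  s <- ph[3, ]
  sx <- round(ph[1, ] / s); sy <- round(ph[2, ] / s)
  ok <- is.finite(sx) & is.finite(sy) & sx >= 0 & sx < nrow(mask) &
    sy >= 0 & sy < ncol(mask)
  out <- matrix(FALSE, w, ht)
  out[cbind(gx[ok] + 1L, gy[ok] + 1L)] <- mask[cbind(sx[ok] + 1L, sy[ok] + 1L)] > 0
  out
}

#' Convert a pixel displacement to millimeters
#'
#' Euclidean length of the displacement under the calibration's per-axis
#' pixel pitch.
#'
#' @param cal a [CalibrationModel-class]
#' @param dxPx,dyPx displacement components in px (vectorized)
#' @return displacement length(s) in mm
#' @export
pixelsToMm <- function(cal, dxPx, dyPx) {
  .assert(is(cal, "CalibrationModel"), "cal must be a CalibrationModel")
  sqrt((dxPx * cal@mmPerPxX)^2 + (dyPx * cal@mmPerPxY)^2)
}

#' Read/write a homography as JSON
#'
#' Stored as 9 numbers, row-major, with h33 = 1.
#'
#' @param h a [PlanarHomography-class]
#' @param path file path
#' @return \code{readHomography} returns a [PlanarHomography-class]
#' @export
writeHomography <- function(h, path) {
  .assert(is(h, "PlanarHomography"), "h must be a PlanarHomography")
  jsonlite::write_json(list(matrix = as.vector(t(h@matrix))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHomography
#' @export
readHomography <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)$matrix
  .assert(length(v) == 9, "homography JSON must contain 9 numbers")
  planarHomography(matrix(v, 3, 3, byrow = TRUE))
}
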