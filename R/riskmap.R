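# Widefield autofluorescence risk mapping: mucosa outline rasterization,
# normalized red-to-green ratio computation, thresholding, heatmap overlay.

#' Rasterize a mucosa outline polygon to a mask
#'
#' Even-odd-rule rasterization of the closed polygon over pixel centers;
#' pixels whose center lies on a polygon edge are included. This is how the
#' clinician's freehand mucosa outline (drawn to exclude teeth, gloves and
#' retractors) becomes the analysis mask for the risk map.
#'
#' @param vertices n x 2 matrix of polygon vertices in px, n >= 3; the
#'   polygon is closed implicitly
#' @param width,height mask dimensions in px
#' @return logical matrix of dim c(width, height)
#' @examples
#' m <- polygonToMask(cbind(c(0, 19, 19, 0), c(0, 0, 19, 19)), 20, 20)
#' sum(m)  # full-frame rectangle -> all 400 px
#' @export
polygonToMask <- function(vertices, width, height) {
  v <- .asPointSet(vertices)
  .assert(nrow(v) >= 3L, "a polygon needs at least 3 vertices")
  v[, 1] <- .clamp(v[, 1], 0, width - 1)
  v[, 2] <- .clamp(v[, 2], 0, height - 1)
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[c(2:n, 1), 1]; y2 <- v[c(2:n, 1), 2]
  area2 <- abs(sum(x1 * y2 - x2 * y1))
  .assert(area2 > 0, "zero-area polygon")

  px <- as.vector(.gridX(width, height))
  py <- as.vector(.gridY(width, height))
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  eps <- 1e-9
  for (i in seq_len(n)) {
    ax <- x1[i]; ay <- y1[i]; bx <- x2[i]; by <- y2[i]
    # even-odd crossing count (half-open edge rule)
    cross <- ((ay > py) != (by > py))
    if (any(cross)) {
      xi <- ax + (py[cross] - ay) * (bx - ax) / (by - ay)
      hit <- px[cross] < xi
      idx <- which(cross)[hit]
      inside[idx] <- !inside[idx]
    }
    # boundary inclusion: pixel center on the segment
    d2 <- (bx - ax)^2 + (by - ay)^2
    if (d2 > 0) {
      t <- .clamp(((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / d2, 0, 1)
      onEdge <- onEdge | ((px - (ax + t * (bx - ax)))^2 +
                            (py - (ay + t * (by - ay)))^2 < eps)
    }
  }
  matrix(inside | onEdge, width, height)
}

#' Compute the normalized red-to-green risk map
#'
#' Per-pixel raw ratio r = R / (G + epsilon), self-normalized by the chosen
#' statistic of r over the mucosa mask so that the map is invariant to
#' global illumination and exposure: \code{rg = r / stat(r[mask])}. Oral
#' neoplasia loses green (collagen) autofluorescence and gains red
#' (porphyrin) emission, so elevated normalized RG marks at-risk tissue.
#'
#' @param af width x height x 3 RGB array, the autofluorescence image
#'   (channel order R, G, B; arbitrary intensity units)
#' @param mask logical matrix, mucosa mask with at least one TRUE pixel
#' @param normStat "mean" (default) or "median"
#' @param epsilon green-channel guard added to the denominator; default 1
#'   intensity unit on the nominal 0..255 scale
#' @return a [RiskMap-class]
#' @export
computeRGRatio <- function(af, mask, normStat = c("mean", "median"), epsilon = 1) {
  normStat <- match.arg(normStat)
  .assert(is.array(af) && length(dim(af)) == 3 && dim(af)[3] >= 2,
          "af must be a width x height x 3 RGB array")
  .assert(is.matrix(mask) && all(dim(mask) == dim(af)[1:2]),
          "mask dims must match the frame")
  mask <- mask > 0
  .assert(any(mask), "mucosa mask is empty")
  .assert(epsilon > 0, "epsilon must be positive")
  G <- af[, , 2]
  .assert(any(G[mask] > 0), "green channel is all zero inside the mask (uninterpretable AF image)")
  r <- af[, , 1] / (G + epsilon)
  k <- switch(normStat, mean = mean(r[mask]), median = median(r[mask]))
  .assert(is.finite(k) && k > 0, "degenerate normalization constant")
  rg <- r / k
  rg[!mask] <- NA_real_
  new("RiskMap", rg = rg, mask = mask, normalizationConstant = k,
      epsilon = epsilon, normStat = normStat)
}

#' Threshold a risk map
#'
#' @param risk a [RiskMap-class]
#' @param tauRG threshold on the normalized RG ratio, >= 0
#' @return logical matrix: TRUE where inside the mask and rg >= tauRG
#' @export
thresholdRisk <- function(risk, tauRG) {
  .assert(is(risk, "RiskMap"), "risk must be a RiskMap")
  .assert(is.numeric(tauRG) && length(tauRG) == 1 && tauRG >= 0,
          "tauRG must be a nonnegative scalar")
  out <- risk@mask & !is.na(risk@rg) & risk@rg >= tauRG
  out[is.na(out)] <- FALSE
  out
}

#' Render a risk heatmap overlay
#'
#' Maps normalized RG linearly to [0, 1] over \code{displayRange}, clips,
#' passes through a cold-to-warm colormap and alpha-blends over the base
#' image inside the mask; pixels outside the mask show the base unmodified.
#' Higher risk renders in warmer colors.
#'
#' @param risk a [RiskMap-class]
#' @param base width x height x 3 RGB array (0..255 scale) to overlay onto
#' @param colormap a palette name accepted by [grDevices::hcl.colors]
#'   (default "Inferno")
#' @param alpha overlay opacity in 0..1
#' @param displayRange length-2 (lo, hi); default the 2nd-98th percentile of
#'   rg inside the mask, a robust contrast choice
#' @return width x height x 3 RGB array on the base image's scale
#' @export
renderRiskHeatmap <- function(risk, base, colormap = "Inferno", alpha = 0.5,
                              displayRange = NULL) {
  .assert(is(risk, "RiskMap"), "risk must be a RiskMap")
  .assert(is.array(base) && all(dim(base)[1:2] == dim(risk@rg)),
          "base dims must match the risk map")
  inside <- risk@rg[risk@mask]
  if (is.null(displayRange))
    displayRange <- as.numeric(quantile(inside, c(0.02, 0.98), names = FALSE))
  .assert(displayRange[1] < displayRange[2], "displayRange lo must be < hi")

  ncol <- 256L
  pal <- grDevices::hcl.colors(ncol, colormap)
  palRGB <- grDevices::col2rgb(pal)  # 3 x ncol, 0..255
  t <- .clamp((risk@rg - displayRange[1]) / diff(displayRange), 0, 1)
  idx <- pmin(ncol, floor(t * (ncol - 1L)) + 1L)
  out <- base
  sel <- which(risk@mask & !is.na(idx))
  npix <- prod(dim(base)[1:2])
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[sel] <- (1 - alpha) * plane[sel] + alpha * palRGB[ch, idx[sel]]
    out[, , ch] <- plane
  }
  out
}
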