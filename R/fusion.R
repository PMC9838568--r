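# Multimodal fusion: timestamp association of the two video streams,
# accumulation of frame scores onto anatomy, dual-threshold guidance maps
# with fast interactive updates, and projection into projector coordinates.

#' Associate microscope frames with widefield frames by timestamp
#'
#' Each microscope timestamp is paired with the widefield frame nearest in
#' time (ties toward the earlier widefield frame); pairs farther apart than
#' \code{tolerance} are dropped. Because the microscope runs at ~90 fps and
#' the widefield camera at ~20 fps, the association is many-to-one.
#'
#' @param microTimestamps,widefieldTimestamps nondecreasing times in seconds
#' @param tolerance maximum |dt| in seconds for a pair to be kept; default
#'   0.1 s (about two widefield frame periods)
#' @return data.frame: micro_index, widefield_index (both 0-based),
#'   dt_s = micro time minus widefield time
#' @export
associateFrames <- function(microTimestamps, widefieldTimestamps, tolerance = 0.1) {
  mt <- as.numeric(microTimestamps); wt <- as.numeric(widefieldTimestamps)
  .assert(length(mt) > 0 && length(wt) > 0, "timestamp lists must be nonempty")
  .assert(!is.unsorted(mt) && !is.unsorted(wt), "timestamps must be nondecreasing")
  lo <- findInterval(mt, wt)            # last wt <= mt (0 if none)
  hi <- pmin(lo + 1L, length(wt))
  lo <- pmax(lo, 1L)
  dlo <- abs(mt - wt[lo]); dhi <- abs(mt - wt[hi])
  pick <- ifelse(dhi < dlo, hi, lo)     # tie -> earlier frame (lo)
  dt <- mt - wt[pick]
  keep <- abs(dt) <= tolerance
  data.frame(micro_index = which(keep) - 1L, widefield_index = pick[keep] - 1L,
             dt_s = dt[keep])
}

#' Accumulate frame scores onto anatomy
#'
#' For each scored microscope frame with a timestamp association whose
#' widefield frame has a valid track entry, the score is deposited (sum +=
#' score, count += 1) at every pixel within \code{footprintRadiusPx} of the
#' tracked tip position. Frames failing any of the three conditions are
#' skipped. The default footprint is the probe's physical field of view
#' (790 um diameter, about 4.7 px radius at the default calibration);
#' radius 0 deposits at the single tip pixel.
#'
#' @param track a [ProbeTrack-class] (widefield frames)
#' @param scores data.frame from [scoreStream] (micro frames)
#' @param assoc data.frame from [associateFrames]
#' @param footprintRadiusPx deposit disc radius in px
#' @param dims c(width, height) of the widefield frame
#' @return a [ScoreField-class]
#' @export
accumulateScores <- function(track, scores, assoc,
                             footprintRadiusPx = (790 / 2 / 1000) / (80 / 960),
                             dims = c(960L, 600L)) {
  .assert(is(track, "ProbeTrack"), "track must be a ProbeTrack")
  e <- track@entries
  s <- matrix(0, dims[1], dims[2]); cnt <- matrix(0L, dims[1], dims[2])
  disc <- .discOffsets(footprintRadiusPx)
  scored <- scores[!is.na(scores$score), , drop = FALSE]
  for (k in seq_len(nrow(scored))) {
    ai <- match(scored$frame_index[k], assoc$micro_index)
    if (is.na(ai)) next
    ti <- match(assoc$widefield_index[ai], e$frame_index)
    if (is.na(ti) || !e$valid[ti]) next
    px <- round(e$x_px[ti]) + disc[, 1]
    py <- round(e$y_px[ti]) + disc[, 2]
    ok <- px >= 0 & px < dims[1] & py >= 0 & py < dims[2]
    idx <- cbind(px[ok] + 1L, py[ok] + 1L)
    s[idx] <- s[idx] + scored$score[k]
    cnt[idx] <- cnt[idx] + 1L
  }
  new("ScoreField", sum = s, count = cnt)
}

#' Compute the dual-threshold biopsy guidance map
#'
#' A pixel is recommended for biopsy iff it lies inside the mucosa mask, was
#' visited by the probe (score count > 0), its normalized RG ratio is at
#' least \code{tauRG} and its mean frame score is at least \code{tauMTN}.
#' Thresholds are clinician-set and have no universal defaults.
#'
#' @param risk a [RiskMap-class]
#' @param field a [ScoreField-class] on the same pixel grid
#' @param tauRG threshold on the normalized RG ratio, >= 0
#' @param tauMTN threshold on the mean frame score, in 0..1
#' @param provenance optional character identifiers recorded in the map
#' @return a [GuidanceMap-class]
#' @export
computeGuidanceMap <- function(risk, field, tauRG, tauMTN,
                               provenance = character(0)) {
  .assert(is(risk, "RiskMap"), "risk must be a RiskMap")
  .assert(is(field, "ScoreField"), "field must be a ScoreField")
  .assert(all(dim(risk@rg) == dim(field@sum)), "risk and field dims differ")
  visited <- field@count > 0
  meanScore <- matrix(0, nrow(field@sum), ncol(field@sum))
  meanScore[visited] <- field@sum[visited] / field@count[visited]
  m <- risk@mask & visited & !is.na(risk@rg) & risk@rg >= tauRG &
    meanScore >= tauMTN
  m[is.na(m)] <- FALSE
  new("GuidanceMap", mask = m, tauRG = tauRG, tauMTN = tauMTN,
      provenance = provenance)
}

#' Recompute the guidance map for new thresholds
#'
#' Operates only on the cached risk map and score field -- no raw video or
#' per-frame data is touched -- so interactive threshold sliders update the
#' map in well under a second. Output is identical to [computeGuidanceMap]
#' at the same thresholds.
#'
#' @inheritParams computeGuidanceMap
#' @return a [GuidanceMap-class]
#' @export
updateThresholds <- function(risk, field, tauRG, tauMTN,
                             provenance = character(0)) {
  computeGuidanceMap(risk, field, tauRG, tauMTN, provenance)
}

#' Project a guidance map into projector coordinates
#'
#' Warps the binary guidance mask through the camera-to-projector homography
#' so it can be displayed by the projection path onto the tissue itself.
#'
#' @param map a [GuidanceMap-class]
#' @param h a [PlanarHomography-class], camera -> projector
#' @param projectorDims c(width, height) of the projector plane
#' @return logical matrix of the projector-plane mask
#' @export
projectGuidance <- function(map, h, projectorDims = dim(map@mask)) {
  .assert(is(map, "GuidanceMap"), "map must be a GuidanceMap")
  warpBinaryMask(h, map@mask, projectorDims[1], projectorDims[2])
}

#' Threshold sweep table for interactive exploration
#'
#' Tabulates the guidance-map area over a grid of threshold pairs, the
#' non-interactive stand-in for the clinician's two sliders.
#'
#' @param risk a [RiskMap-class]
#' @param field a [ScoreField-class]
#' @param tauRGGrid,tauMTNGrid numeric vectors of thresholds
#' @return data.frame: tau_rg, tau_mtn, mask_area_px
#' @export
thresholdSweep <- function(risk, field,
                           tauRGGrid = seq(0.5, 3, by = 0.25),
                           tauMTNGrid = seq(0.1, 0.9, by = 0.1)) {
  grid <- expand.grid(tau_rg = tauRGGrid, tau_mtn = tauMTNGrid)
  grid$mask_area_px <- vapply(seq_len(nrow(grid)), function(i) {
    sum(computeGuidanceMap(risk, field, grid$tau_rg[i], grid$tau_mtn[i])@mask)
  }, numeric(1))
  grid
}
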