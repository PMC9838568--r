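# Session I/O and the end-to-end pipeline driver: image readers/writers,
# configuration handling, session serialization with a manifest, staged
# pipeline execution with hash-based resume, and session evaluation.

#' Read/write RGB and grayscale images
#'
#' Thin wrappers over the png package converting between PNG row-major
#' storage and the package's (width x height) 0..255 convention.
#'
#' @param path file path
#' @param img image to write: width x height x 3 array or width x height
#'   matrix, 0..255
#' @return readers return arrays/matrices in package convention
#' @export
readImageRGB <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
}

#' @rdname readImageRGB
#' @export
writeImageRGB <- function(img, path) {
  png::writePNG(aperm(.clamp(img, 0, 255), c(2, 1, 3)) / 255, path)
  invisible(path)
}

#' @rdname readImageRGB
#' @export
readImageGray <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  t(a) * 255
}

#' @rdname readImageRGB
#' @export
writeImageGray <- function(img, path) {
  png::writePNG(t(.clamp(img, 0, 255)) / 255, path)
  invisible(path)
}

#' Write/read a binary mask as PNG (0/255)
#'
#' @param mask logical matrix
#' @param path file path
#' @return \code{readMask} returns a logical matrix
#' @export
writeMask <- function(mask, path) {
  png::writePNG(t(mask * 1), path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  t(a) > 0.5
}

#' Store/load a risk map (32-bit float TIFF + JSON sidecar + mask PNG)
#'
#' TIFF float storage is defined on [0, 1], so rg is divided by a scale
#' factor recorded in the sidecar and restored on read.
#'
#' @param risk a [RiskMap-class]
#' @param dir output directory (files rg.tif, rg.json, mucosa_mask.png)
#' @return \code{readRiskMap} returns a [RiskMap-class]
#' @export
writeRiskMap <- function(risk, dir) {
  .assert(is(risk, "RiskMap"), "risk must be a RiskMap")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(risk@rg, na.rm = TRUE)
  rg <- risk@rg / scale
  rg[is.na(rg)] <- 0
  tiff::writeTIFF(t(rg), file.path(dir, "rg.tif"), bits.per.sample = 32L)
  writeMask(risk@mask, file.path(dir, "mucosa_mask.png"))
  jsonlite::write_json(list(
    scale = scale, normalization_constant = risk@normalizationConstant,
    epsilon = risk@epsilon, norm_stat = risk@normStat),
    file.path(dir, "rg.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeRiskMap
#' @export
readRiskMap <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "rg.json"), simplifyVector = TRUE)
  rg <- t(tiff::readTIFF(file.path(dir, "rg.tif"))) * meta$scale
  mask <- readMask(file.path(dir, "mucosa_mask.png"))
  rg[!mask] <- NA_real_
  new("RiskMap", rg = rg, mask = mask,
      normalizationConstant = meta$normalization_constant,
      epsilon = meta$epsilon, normStat = meta$norm_stat)
}

#' Block-mean downsampling of a widefield frame
#'
#' Averages factor x factor pixel blocks per channel (anti-aliased); this is
#' the resolution reduction applied to the full-sensor 1920 x 1200 stream to
#' produce the 960 x 600 multimodal-imaging frames.
#'
#' @param frame width x height x 3 array or width x height matrix
#' @param factor integer >= 1; both dims must be divisible by it
#' @return downsampled frame, dims divided by factor
#' @export
downsampleWidefield <- function(frame, factor) {
  .assert(.isCount(factor) && factor >= 1, "factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(frame)
  d <- dim(frame)
  .assert(d[1] %% factor == 0 && d[2] %% factor == 0,
          "frame dims must be divisible by factor")
  blockMean <- function(m) {
    w <- nrow(m); h <- ncol(m)
    a <- m; dim(a) <- c(factor, w %/% factor * h)
    s1 <- colSums(a); dim(s1) <- c(w %/% factor, h)
    b <- t(s1); dim(b) <- c(factor, h %/% factor * (w %/% factor))
    s2 <- colSums(b); dim(s2) <- c(h %/% factor, w %/% factor)
    t(s2) / factor^2
  }
  if (length(d) == 2) return(blockMean(frame))
  out <- array(0, c(d[1] %/% factor, d[2] %/% factor, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- blockMean(frame[, , ch])
  out
}

#' Default pipeline configuration
#'
#' All tunable analysis parameters in one nested list; see the package
#' vignette for units and rationale. \code{readConfig}/\code{writeConfig}
#' round-trip it as YAML, rejecting unknown keys.
#'
#' @return nested configuration list
#' @export
defaultConfig <- function() {
  list(
    calibration = list(frameWidth = 960L, frameHeight = 600L,
                       mmPerPxX = 80 / 960, mmPerPxY = 50 / 600),
    gate = list(hueLo = 160, hueHi = 200, satMin = 0.35, valMin = 0.2,
                minAreaPx = 20, maxAreaPx = 5000),
    tracking = list(smoothWindow = 5L, maxGap = 5L),
    qc = list(contactFloor = 20, minCoverage = 0.3, minSharpness = 2),
    scorer = list(id = "morphometry", weights = c(0, 1, 1, 1)),
    risk = list(normStat = "mean", epsilon = 1),
    fusion = list(assocToleranceS = 0.1, footprintRadiusPx = 4.7),
    guidance = list(tauRG = 1.9, tauMTN = 0.5),
    mosaic = list(enabled = FALSE, minPeak = 0.2, umPerPx = 790 / 720),
    profile = list(binWidthMm = 0.5),
    downsampleFactor = 1L)
}

#' @rdname defaultConfig
#' @param config configuration list
#' @param path YAML file path
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname defaultConfig
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- defaultConfig()
  unknown <- setdiff(names(cfg), names(ref))
  .assert(length(unknown) == 0,
          paste("unknown config keys:", paste(unknown, collapse = ", ")))
  for (k in names(cfg)) {
    if (is.list(ref[[k]])) {
      u2 <- setdiff(names(cfg[[k]]), names(ref[[k]]))
      .assert(length(u2) == 0,
              paste0("unknown config keys under ", k, ": ", paste(u2, collapse = ", ")))
      ref[[k]][names(cfg[[k]])] <- cfg[[k]]
    } else ref[[k]] <- cfg[[k]]
  }
  ref
}

#' Write a synthetic session to disk
#'
#' Lays out a session directory the pipeline driver can consume: wl.png,
#' af.png, lesion_mask.png (truth), outline.json (mucosa polygon),
#' widefield/ and micro/ frame PNGs with per-stream timestamps.csv,
#' truth_track.csv, truth_labels.csv and manifest.json (seed, parameters
#' echo, file inventory).
#'
#' @param session list from [generateSession]
#' @param dir output directory
#' @return invisibly, the manifest path
#' @export
writeSession <- function(session, dir) {
  dir.create(file.path(dir, "widefield"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "micro"), showWarnings = FALSE, recursive = TRUE)
  d <- session$spec@widefieldDims
  writeImageRGB(session$wl, file.path(dir, "wl.png"))
  writeImageRGB(session$af, file.path(dir, "af.png"))
  writeMask(session$lesionMask, file.path(dir, "lesion_mask.png"))
  margin <- 5
  outline <- list(vertices = list(
    c(margin, margin), c(d[1] - 1 - margin, margin),
    c(d[1] - 1 - margin, d[2] - 1 - margin), c(margin, d[2] - 1 - margin)))
  jsonlite::write_json(outline, file.path(dir, "outline.json"), digits = NA)

  for (i in seq_len(session$nWidefield))
    writeImageRGB(session$widefieldFrame(i),
                  file.path(dir, "widefield", sprintf("frame_%04d.png", i - 1)))
  utils::write.csv(data.frame(frame_index = seq_len(session$nWidefield) - 1L,
                              timestamp_s = session$widefieldTimestamps),
                   file.path(dir, "widefield", "timestamps.csv"), row.names = FALSE)
  for (i in seq_len(session$nMicro))
    writeImageGray(session$microFrame(i)@pixels,
                   file.path(dir, "micro", sprintf("frame_%04d.png", i - 1)))
  utils::write.csv(data.frame(frame_index = seq_len(session$nMicro) - 1L,
                              timestamp_s = session$microTimestamps),
                   file.path(dir, "micro", "timestamps.csv"), row.names = FALSE)

  writeTrack(session$truth$track, file.path(dir, "truth_track.csv"))
  utils::write.csv(data.frame(frame_index = seq_len(session$nMicro) - 1L,
                              regime = session$truth$regimes),
                   file.path(dir, "truth_labels.csv"), row.names = FALSE)

  spec <- session$spec
  manifest <- list(
    seed = spec@seed,
    widefield_dims = spec@widefieldDims, micro_dims = spec@microDims,
    fov_radius_px = spec@fovRadiusPx,
    widefield_fps = spec@widefieldFps, micro_fps = spec@microFps,
    duration_s = spec@durationS,
    n_widefield = session$nWidefield, n_micro = session$nMicro,
    files = list(wl = "wl.png", af = "af.png", outline = "outline.json",
                 lesion_mask = "lesion_mask.png",
                 widefield_dir = "widefield", micro_dir = "micro",
                 truth_track = "truth_track.csv",
                 truth_labels = "truth_labels.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

.readManifest <- function(sessionDir) {
  p <- file.path(sessionDir, "manifest.json")
  .assert(file.exists(p), paste("manifest not found:", p))
  m <- jsonlite::read_json(p, simplifyVector = TRUE)
  for (f in c("af", "outline")) {
    fp <- file.path(sessionDir, m$files[[f]])
    .assert(file.exists(fp), paste("manifest references missing file:", fp))
  }
  m
}

# stage-resume bookkeeping: a stage is current if all recorded input hashes
# match and all outputs still exist with matching hashes
.stageState <- function(outDir) {
  p <- file.path(outDir, "stage_state.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = FALSE) else list()
}

.stageCurrent <- function(state, stage, inputs) {
  rec <- state[[stage]]
  if (is.null(rec)) return(FALSE)
  h <- unname(tools::md5sum(inputs))
  if (!identical(as.character(h), as.character(unlist(rec$inputs)))) return(FALSE)
  outs <- as.character(unlist(rec$outputFiles))
  all(file.exists(outs)) &&
    identical(as.character(unname(tools::md5sum(outs))),
              as.character(unlist(rec$outputs)))
}

.stageRecord <- function(state, stage, inputs, outputs, outDir) {
  state[[stage]] <- list(inputs = as.list(unname(tools::md5sum(inputs))),
                         outputFiles = as.list(outputs),
                         outputs = as.list(unname(tools::md5sum(outputs))))
  jsonlite::write_json(state, file.path(outDir, "stage_state.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state
}

#' Run the end-to-end analysis pipeline on a session directory
#'
#' Executes the stages risk map -> probe track -> frame scoring -> fusion
#' (plus optional mosaic and score profile) in order, writing each stage's
#' outputs and a run log under \code{outDir}. Stages whose inputs and
#' outputs are unchanged (content hashes) are skipped on rerun, so the
#' pipeline is idempotent and resumable.
#'
#' @param sessionDir session directory with a manifest.json (see
#'   [writeSession])
#' @param outDir output directory
#' @param config configuration list, see [defaultConfig]
#' @return invisibly, a list of stage output paths
#' @export
runPipeline <- function(sessionDir, outDir, config = defaultConfig()) {
  m <- .readManifest(sessionDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  state <- .stageState(outDir)
  logPath <- file.path(outDir, "run_log.txt")
  logLine <- function(...) cat(sprintf(...), "\n", file = logPath, append = TRUE)

  cal <- calibrationModel(config$calibration$frameWidth,
                          config$calibration$frameHeight,
                          config$calibration$mmPerPxX, config$calibration$mmPerPxY)

  # --- stage: risk map ---------------------------------------------------
  afPath <- file.path(sessionDir, m$files$af)
  outlinePath <- file.path(sessionDir, m$files$outline)
  riskDir <- file.path(outDir, "risk")
  riskOuts <- file.path(riskDir, c("rg.tif", "rg.json", "mucosa_mask.png"))
  if (!.stageCurrent(state, "riskmap", c(afPath, outlinePath))) {
    af <- readImageRGB(afPath)
    poly <- jsonlite::read_json(outlinePath, simplifyVector = TRUE)$vertices
    mask <- polygonToMask(poly, dim(af)[1], dim(af)[2])
    risk <- computeRGRatio(af, mask, config$risk$normStat, config$risk$epsilon)
    writeRiskMap(risk, riskDir)
    state <- .stageRecord(state, "riskmap", c(afPath, outlinePath), riskOuts, outDir)
    logLine("riskmap: %d mucosa px, normalization %.4g", sum(mask),
            normalizationConstant(risk))
  } else logLine("riskmap: up to date, skipped")

  # --- stage: probe track ------------------------------------------------
  wfDir <- file.path(sessionDir, m$files$widefield_dir)
  wfTs <- utils::read.csv(file.path(wfDir, "timestamps.csv"))
  wfFiles <- file.path(wfDir, sprintf("frame_%04d.png", wfTs$frame_index))
  trackPath <- file.path(outDir, "track.csv")
  trackInputs <- c(wfFiles, file.path(wfDir, "timestamps.csv"))
  if (!.stageCurrent(state, "track", trackInputs)) {
    gate <- do.call(colorGate, config$gate)
    track <- trackVideo(function(i) readImageRGB(wfFiles[i]), gate,
                        timestamps = wfTs$timestamp_s,
                        smoothWindow = config$tracking$smoothWindow,
                        maxGap = config$tracking$maxGap, nFrames = length(wfFiles))
    writeTrack(track, trackPath)
    state <- .stageRecord(state, "track", trackInputs, trackPath, outDir)
    logLine("track: %d frames, %.1f%% valid", length(wfFiles),
            100 * mean(trackEntries(track)$valid))
  } else logLine("track: up to date, skipped")

  # --- stage: frame scoring ----------------------------------------------
  micDir <- file.path(sessionDir, m$files$micro_dir)
  micTs <- utils::read.csv(file.path(micDir, "timestamps.csv"))
  micFiles <- file.path(micDir, sprintf("frame_%04d.png", micTs$frame_index))
  scoresPath <- file.path(outDir, "scores.csv")
  scoreInputs <- c(micFiles, file.path(micDir, "timestamps.csv"))
  if (!.stageCurrent(state, "score", scoreInputs)) {
    scorer <- morphometryScorer(weights = config$scorer$weights)
    fovR <- if (!is.null(m$fov_radius_px)) m$fov_radius_px else NULL
    loadMicro <- function(i) {
      px <- readImageGray(micFiles[i])
      if (is.null(fovR)) microFrame(px, micTs$timestamp_s[i], micTs$frame_index[i])
      else microFrame(px, micTs$timestamp_s[i], micTs$frame_index[i],
                      fovRadius = fovR)
    }
    scores <- scoreStream(loadMicro, scorer, qcParams = config$qc,
                          nFrames = length(micFiles),
                          scorerId = config$scorer$id)
    writeScores(scores, scoresPath)
    state <- .stageRecord(state, "score", scoreInputs, scoresPath, outDir)
    logLine("score: %d frames acquired, %d passed QC, %d scored",
            nrow(scores), sum(scores$qc_pass), sum(!is.na(scores$score)))
  } else logLine("score: up to date, skipped")

  # --- stage: fusion -----------------------------------------------------
  fuseInputs <- c(riskOuts, trackPath, scoresPath)
  fieldSumPath <- file.path(outDir, "scorefield_sum.tif")
  fieldCountPath <- file.path(outDir, "scorefield_count.tif")
  guidancePath <- file.path(outDir, "guidance.png")
  guidanceMeta <- file.path(outDir, "guidance.json")
  fuseOuts <- c(fieldSumPath, fieldCountPath, guidancePath, guidanceMeta)
  if (!.stageCurrent(state, "fuse", fuseInputs)) {
    risk <- readRiskMap(riskDir)
    track <- readTrack(trackPath)
    scores <- readScores(scoresPath)
    assoc <- associateFrames(micTs$timestamp_s, wfTs$timestamp_s,
                             config$fusion$assocToleranceS)
    field <- accumulateScores(track, scores, assoc,
                              config$fusion$footprintRadiusPx,
                              dims = dim(riskValues(risk)))
    cmax <- max(fieldCount(field), 1)
    tiff::writeTIFF(t(fieldSum(field)) / max(fieldSum(field), 1),
                    fieldSumPath, bits.per.sample = 32L)
    tiff::writeTIFF(t(fieldCount(field)) / cmax, fieldCountPath,
                    bits.per.sample = 16L)
    gm <- computeGuidanceMap(risk, field, config$guidance$tauRG,
                             config$guidance$tauMTN,
                             provenance = c(riskDir, trackPath, scoresPath))
    writeMask(guidanceMask(gm), guidancePath)
    jsonlite::write_json(list(
      tau_rg = config$guidance$tauRG, tau_mtn = config$guidance$tauMTN,
      count_scale = cmax, sum_scale = max(fieldSum(field), 1),
      mask_area_px = sum(guidanceMask(gm)),
      provenance = c(riskDir, trackPath, scoresPath)),
      guidanceMeta, auto_unbox = TRUE, digits = NA)
    state <- .stageRecord(state, "fuse", fuseInputs, fuseOuts, outDir)
    logLine("fuse: %d deposits on %d px, guidance area %d px",
            sum(fieldCount(field)), sum(fieldCount(field) > 0),
            sum(guidanceMask(gm)))
  } else logLine("fuse: up to date, skipped")

  # --- optional: mosaic + profile ---------------------------------------
  outs <- list(risk = riskDir, track = trackPath, scores = scoresPath,
               guidance = guidancePath)
  if (isTRUE(config$mosaic$enabled)) {
    scores <- readScores(scoresPath)
    track <- readTrack(trackPath)
    assoc <- associateFrames(micTs$timestamp_s, wfTs$timestamp_s,
                             config$fusion$assocToleranceS)
    pass <- which(scores$qc_pass)
    frames <- lapply(pass, function(i) {
      px <- readImageGray(micFiles[i])
      microFrame(px, micTs$timestamp_s[i], micTs$frame_index[i],
                 fovRadius = m$fov_radius_px)
    })
    mos <- buildMosaic(frames, scores$score[pass], config$mosaic$minPeak,
                       config$mosaic$umPerPx)
    writeMosaic(mos, file.path(outDir, "mosaic.tif"),
                file.path(outDir, "placements.csv"))
    prof <- scoreProfile(track, scores, assoc, cal, config$profile$binWidthMm)
    utils::write.csv(prof, file.path(outDir, "profile.csv"), row.names = FALSE)
    outs$mosaic <- file.path(outDir, "mosaic.tif")
    outs$profile <- file.path(outDir, "profile.csv")
    logLine("mosaic: %d frames, width %.2f mm", length(frames), mosaicWidthMm(mos))
  }
  invisible(outs)
}

#' Evaluate pipeline outputs against session ground truth
#'
#' Aggregates tracking accuracy, guidance-map overlap with the true lesion,
#' and scorer discrimination (AUROC against the per-frame regime labels)
#' into one metrics report.
#'
#' @param outDir pipeline output directory from [runPipeline]
#' @param sessionDir session directory holding the ground truth
#' @param cal a [CalibrationModel-class]
#' @return list: tracking (meanErrorMm, p95ErrorMm, validFraction),
#'   guidance (precision, recall, areaPx), scorer (auroc, nScored)
#' @export
evaluateSession <- function(outDir, sessionDir, cal = calibrationModel()) {
  need <- c(file.path(outDir, "track.csv"), file.path(outDir, "scores.csv"),
            file.path(outDir, "guidance.png"))
  .assert(all(file.exists(need)),
          paste("missing stage outputs:", paste(need[!file.exists(need)], collapse = ", ")))
  track <- readTrack(file.path(outDir, "track.csv"))
  truth <- readTrack(file.path(sessionDir, "truth_track.csv"))
  trk <- evaluateTracking(track, truth, cal)

  lesion <- readMask(file.path(sessionDir, "lesion_mask.png"))
  gm <- readMask(file.path(outDir, "guidance.png"))
  tp <- sum(gm & lesion)
  guidance <- list(precision = if (sum(gm) > 0) tp / sum(gm) else NA_real_,
                   recall = tp / sum(lesion), areaPx = sum(gm))

  scores <- readScores(file.path(outDir, "scores.csv"))
  labels <- utils::read.csv(file.path(sessionDir, "truth_labels.csv"))
  j <- merge(scores[!is.na(scores$score), c("frame_index", "score")], labels,
             by = "frame_index")
  auroc <- NA_real_
  if (length(unique(j$regime)) == 2) {
    r <- pROC::roc(response = j$regime, predictor = j$score,
                   levels = c("normal", "dysplastic"), direction = "<",
                   quiet = TRUE)
    auroc <- as.numeric(pROC::auc(r))
  }
  list(tracking = trk, guidance = guidance,
       scorer = list(auroc = auroc, nScored = nrow(j)))
}
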