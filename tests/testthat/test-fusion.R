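# small helper: risk map + field on a toy grid with controllable values
toyRisk <- function(w = 20, h = 20, seed = 1) {
  set.seed(seed)
  af <- array(runif(w * h * 3, 1, 255), c(w, h, 3))
  mask <- matrix(runif(w * h) > 0.15, w, h)
  computeRGRatio(af, mask)
}

toyField <- function(w = 20, h = 20, seed = 2, fillFrac = 0.6) {
  set.seed(seed)
  track <- probeTrack(data.frame(
    frame_index = 0L, timestamp_s = 0, x_px = 0, y_px = 0,
    blob_area_px2 = 1, valid = TRUE, interpolated = FALSE))
  # build by hand through accumulateScores with single-pixel deposits
  n <- round(fillFrac * w * h)
  xs <- sample(0:(w - 1), n, replace = TRUE)
  ys <- sample(0:(h - 1), n, replace = TRUE)
  sc <- runif(n)
  field <- NULL
  for (k in seq_len(n)) {
    tr <- probeTrack(data.frame(
      frame_index = 0L, timestamp_s = 0, x_px = xs[k], y_px = ys[k],
      blob_area_px2 = 1, valid = TRUE, interpolated = FALSE))
    scores <- data.frame(frame_index = 0L, score = sc[k])
    assoc <- data.frame(micro_index = 0L, widefield_index = 0L, dt_s = 0)
    f <- accumulateScores(tr, scores, assoc, footprintRadiusPx = 0, dims = c(w, h))
    field <- if (is.null(field)) f else
      methods::new("ScoreField", sum = fieldSum(field) + fieldSum(f),
                   count = fieldCount(field) + fieldCount(f))
  }
  field
}

test_that("timestamp association matches brute-force nearest neighbor", {
  t <- seq(0, 1, by = 0.05)
  a <- associateFrames(t, t, tolerance = 0.01)
  expect_equal(a$micro_index, a$widefield_index)
  expect_true(all(a$dt_s == 0))

  mt <- (0:89) / 90; wt <- (0:19) / 20
  a2 <- associateFrames(mt, wt, tolerance = 0.1)
  expect_equal(nrow(a2), 90)
  perWf <- table(a2$widefield_index)
  interior <- perWf[!names(perWf) %in% c("0", "19")]  # ends collect the tails
  expect_true(all(interior >= 4 & interior <= 5))
  # brute-force oracle with earlier-frame tie break
  for (i in seq_along(mt)) {
    d <- abs(mt[i] - wt)
    expect_equal(a2$widefield_index[i], which(d == min(d))[1] - 1L)
  }

  a3 <- associateFrames(c(wt, max(wt) + 10), wt, tolerance = 0.1)
  expect_equal(nrow(a3), length(wt))  # the straggler is dropped
  expect_error(associateFrames(numeric(0), wt), "nonempty")
})

test_that("score accumulation deposits sums and counts correctly", {
  tr <- probeTrack(data.frame(
    frame_index = 0L, timestamp_s = 0, x_px = 10, y_px = 12,
    blob_area_px2 = 1, valid = TRUE, interpolated = FALSE))
  assoc <- data.frame(micro_index = 0L, widefield_index = 0L, dt_s = 0)
  f1 <- accumulateScores(tr, data.frame(frame_index = 0L, score = 0.8), assoc,
                         footprintRadiusPx = 0, dims = c(30, 30))
  expect_equal(sum(fieldCount(f1)), 1)
  expect_equal(fieldMean(f1)[11, 13], 0.8)

  assoc2 <- data.frame(micro_index = 0:1, widefield_index = c(0L, 0L), dt_s = 0)
  f2 <- accumulateScores(tr, data.frame(frame_index = 0:1, score = c(0.2, 0.6)),
                         assoc2, footprintRadiusPx = 0, dims = c(30, 30))
  expect_equal(fieldMean(f2)[11, 13], 0.4)
})

test_that("accumulated field equals a nested-loop oracle on a small session", {
  set.seed(17)
  nW <- 8; nM <- 30
  track <- probeTrack(data.frame(
    frame_index = 0:(nW - 1), timestamp_s = (0:(nW - 1)) / 20,
    x_px = round(runif(nW, 8, 40)), y_px = round(runif(nW, 8, 40)),
    blob_area_px2 = 50, valid = c(TRUE, TRUE, FALSE, rep(TRUE, nW - 3)),
    interpolated = FALSE))
  scores <- data.frame(frame_index = 0:(nM - 1),
                       score = round(runif(nM), 3))
  scores$score[c(4, 9)] <- NA  # QC failures
  assoc <- associateFrames((0:(nM - 1)) / 90, (0:(nW - 1)) / 20, 0.1)
  r <- 2.5
  field <- accumulateScores(track, scores, assoc, footprintRadiusPx = r,
                            dims = c(50, 50))

  e <- trackEntries(track)
  sumO <- matrix(0, 50, 50); cntO <- matrix(0, 50, 50)
  for (k in seq_len(nrow(scores))) {
    if (is.na(scores$score[k])) next
    ai <- which(assoc$micro_index == scores$frame_index[k])
    if (!length(ai)) next
    ti <- which(e$frame_index == assoc$widefield_index[ai])
    if (!length(ti) || !e$valid[ti]) next
    for (x in 0:49) for (y in 0:49) {
      if ((x - round(e$x_px[ti]))^2 + (y - round(e$y_px[ti]))^2 <= r^2) {
        sumO[x + 1, y + 1] <- sumO[x + 1, y + 1] + scores$score[k]
        cntO[x + 1, y + 1] <- cntO[x + 1, y + 1] + 1
      }
    }
  }
  expect_equal(fieldSum(field), sumO)
  expect_equal(unname(fieldCount(field)), unname(cntO))
})

test_that("field count is conserved for interior footprints", {
  set.seed(18)
  nW <- 10
  track <- probeTrack(data.frame(
    frame_index = 0:(nW - 1), timestamp_s = (0:(nW - 1)) / 20,
    x_px = runif(nW, 20, 80), y_px = runif(nW, 20, 80),
    blob_area_px2 = 50, valid = TRUE, interpolated = FALSE))
  nM <- 45
  scores <- data.frame(frame_index = 0:(nM - 1), score = runif(nM))
  assoc <- associateFrames((0:(nM - 1)) / 90, (0:(nW - 1)) / 20, 0.1)
  r <- 4.7
  field <- accumulateScores(track, scores, assoc, footprintRadiusPx = r,
                            dims = c(100, 100))
  discSize <- sum(outer((-4:4)^2, (-4:4)^2, "+") <= r^2)
  expect_equal(sum(fieldCount(field)), nM * discSize)
})

test_that("guidance map equals brute force and update == compute", {
  risk <- toyRisk(20, 20, seed = 19)
  field <- toyField(20, 20, seed = 20)
  meanS <- fieldMean(field)

  gm0 <- computeGuidanceMap(risk, field, 0, 0)
  expect_identical(guidanceMask(gm0), riskMask(risk) & fieldCount(field) > 0)

  gmHi <- computeGuidanceMap(risk, field, 0, 1)
  expect_lte(sum(guidanceMask(gmHi)), sum(meanS >= 1, na.rm = TRUE))

  for (tau in list(c(0.5, 0.3), c(1.0, 0.5), c(1.5, 0.8))) {
    gm <- computeGuidanceMap(risk, field, tau[1], tau[2])
    up <- updateThresholds(risk, field, tau[1], tau[2])
    expect_identical(guidanceMask(gm), guidanceMask(up))
    for (x in 1:20) for (y in 1:20) {
      expected <- isTRUE(riskMask(risk)[x, y]) &&
        fieldCount(field)[x, y] > 0 &&
        !is.na(riskValues(risk)[x, y]) && riskValues(risk)[x, y] >= tau[1] &&
        meanS[x, y] >= tau[2]
      expect_identical(guidanceMask(gm)[x, y], expected)
    }
  }
})

test_that("guidance masks shrink as thresholds rise (antitone)", {
  risk <- toyRisk(25, 25, seed = 21)
  field <- toyField(25, 25, seed = 22)
  taus <- expand.grid(rg = c(0, 0.5, 1, 1.5), mtn = c(0, 0.3, 0.6, 0.9))
  for (i in seq_len(nrow(taus))) for (j in seq_len(nrow(taus))) {
    if (taus$rg[j] >= taus$rg[i] && taus$mtn[j] >= taus$mtn[i]) {
      hi <- guidanceMask(computeGuidanceMap(risk, field, taus$rg[j], taus$mtn[j]))
      lo <- guidanceMask(computeGuidanceMap(risk, field, taus$rg[i], taus$mtn[i]))
      expect_true(all(lo[hi]))
    }
  }
})

test_that("guidance projection warps the mask and round trips", {
  risk <- toyRisk(40, 40, seed = 23)
  field <- toyField(40, 40, seed = 24, fillFrac = 1.5)
  gm <- computeGuidanceMap(risk, field, 0.3, 0.1)

  expect_identical(projectGuidance(gm, planarHomography(diag(3))),
                   guidanceMask(gm))

  trH <- planarHomography(matrix(c(1, 0, 5, 0, 1, 3, 0, 0, 1), 3, 3, byrow = TRUE))
  proj <- projectGuidance(gm, trH, c(60, 60))
  m <- guidanceMask(gm)
  for (k in which(m)) {
    x <- (k - 1) %% 40; y <- (k - 1) %/% 40
    expect_true(proj[x + 5 + 1, y + 3 + 1])
  }

  # camera -> projector -> camera round trip keeps >= 98% of a 500-px blob
  blob <- matrix(FALSE, 960, 600); blob[300:324, 200:219] <- TRUE
  h <- planarHomography(matrix(c(cos(0.02), -sin(0.02), 6,
                                 sin(0.02), cos(0.02), -4,
                                 5e-6, -3e-6, 1), 3, 3, byrow = TRUE))
  there <- warpBinaryMask(h, blob)
  back <- warpBinaryMask(invertHomography(h), there)
  expect_gte(sum(back & blob) / sum(blob), 0.98)
})

test_that("threshold sweep tabulates mask area over the grid", {
  risk <- toyRisk(15, 15, seed = 25)
  field <- toyField(15, 15, seed = 26)
  sw <- thresholdSweep(risk, field, c(0, 1), c(0, 0.5))
  expect_equal(nrow(sw), 4)
  expect_equal(sw$mask_area_px[sw$tau_rg == 0 & sw$tau_mtn == 0],
               sum(riskMask(risk) & fieldCount(field) > 0))
})
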