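test_that("block-mean downsampling preserves intensity and closed forms", {
  fr <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  expect_identical(downsampleWidefield(fr, 1), fr)

  # checkerboard of 0/100 averages to uniform 50
  cb <- matrix(c(0, 100, 100, 0), 2, 2)[rep(1:2, 2), rep(1:2, 2)]
  expect_equal(downsampleWidefield(cb, 2), matrix(50, 2, 2))

  # conservation: total intensity x factor^2
  d <- downsampleWidefield(fr, 4)
  expect_equal(dim(d), c(2L, 2L, 3L))
  expect_equal(sum(d) * 16, sum(fr), tolerance = 1e-9)

  expect_error(downsampleWidefield(matrix(0, 9, 9), 2), "divisible")
  expect_error(downsampleWidefield(fr, 1.5), "positive integer")
})

test_that("configuration round trips as YAML and rejects unknown keys", {
  cfg <- defaultConfig()
  cfg$guidance$tauRG <- 2.2
  p <- withr::local_tempfile(fileext = ".yaml")
  writeConfig(cfg, p)
  back <- readConfig(p)
  expect_equal(back$guidance$tauRG, 2.2)
  expect_equal(back$gate$hueLo, cfg$gate$hueLo)
  expect_equal(back$calibration$mmPerPxX, cfg$calibration$mmPerPxX)

  bad <- cfg; bad$frobnicate <- 1
  writeConfig(bad, p)
  expect_error(readConfig(p), "unknown config keys")
  bad2 <- defaultConfig(); bad2$gate$shimmer <- 1
  writeConfig(bad2, p)
  expect_error(readConfig(p), "gate")
})

test_that("image and risk-map serialization round trips", {
  img <- array(sample(0:255, 24 * 16 * 3, replace = TRUE), c(24, 16, 3))
  p <- withr::local_tempfile(fileext = ".png")
  writeImageRGB(img, p)
  expect_equal(readImageRGB(p), img, tolerance = 1e-9)

  m <- matrix(runif(24 * 16) > 0.5, 24, 16)
  pm <- withr::local_tempfile(fileext = ".png")
  writeMask(m, pm)
  expect_identical(readMask(pm), m)

  set.seed(61)
  af <- array(runif(24 * 16 * 3, 1, 255), c(24, 16, 3))
  risk <- computeRGRatio(af, m | !m)
  d <- withr::local_tempdir()
  writeRiskMap(risk, d)
  back <- readRiskMap(d)
  expect_equal(riskValues(back), riskValues(risk), tolerance = 1e-6)
  expect_equal(normalizationConstant(back), normalizationConstant(risk),
               tolerance = 1e-12)
})

# a compact session whose trajectory crosses the lesion boundary early, so
# even a short run produces both regimes and guidance output
smallSessionSpec <- function(seed = 71) {
  phantomSpec(seed = seed, durationS = 0.5,
              trajectory = cbind(c(430, 560), c(300, 300)))
}

test_that("pipeline driver runs end to end, resumes, and reports errors", {
  ses <- generateSession(smallSessionSpec())
  sdir <- withr::local_tempdir(); odir <- withr::local_tempdir()
  writeSession(ses, sdir)
  cfg <- defaultConfig()
  outs <- runPipeline(sdir, odir, cfg)
  for (f in c("track.csv", "scores.csv", "guidance.png", "run_log.txt",
              "scorefield_sum.tif", "scorefield_count.tif"))
    expect_true(file.exists(file.path(odir, f)))
  expect_true(file.exists(file.path(odir, "risk", "rg.tif")))
  gm <- readMask(file.path(odir, "guidance.png"))
  expect_gt(sum(gm), 0)

  # rerun: byte-identical outputs, stages skipped
  h1 <- tools::md5sum(c(file.path(odir, "guidance.png"),
                        file.path(odir, "track.csv"),
                        file.path(odir, "scores.csv")))
  runPipeline(sdir, odir, cfg)
  expect_identical(h1, tools::md5sum(names(h1)))
  log <- readLines(file.path(odir, "run_log.txt"))
  expect_true(any(grepl("skipped", log)))

  # a manifest pointing at a missing AF image names the missing path
  broken <- withr::local_tempdir()
  file.copy(list.files(sdir, full.names = TRUE), broken, recursive = TRUE)
  unlink(file.path(broken, "af.png"))
  expect_error(runPipeline(broken, withr::local_tempdir(), cfg), "af.png")
})

test_that("session evaluation scores oracle outputs perfectly", {
  ses <- generateSession(smallSessionSpec(seed = 72))
  sdir <- withr::local_tempdir(); odir <- withr::local_tempdir()
  writeSession(ses, sdir)
  dir.create(odir, showWarnings = FALSE)
  # substitute perfect outputs: truth track, lesion mask as guidance,
  # scores equal to the regime indicator
  writeTrack(ses$truth$track, file.path(odir, "track.csv"))
  writeMask(ses$lesionMask, file.path(odir, "guidance.png"))
  sc <- data.frame(frame_index = 0:(ses$nMicro - 1),
                   timestamp_s = ses$microTimestamps,
                   coverage_fraction = 1, sharpness = 10, qc_pass = TRUE,
                   score = ifelse(ses$truth$regimes == "dysplastic", 0.9, 0.1),
                   scorer_id = "oracle")
  writeScores(sc, file.path(odir, "scores.csv"))
  ev <- evaluateSession(odir, sdir)
  expect_equal(ev$tracking$meanErrorMm, 0)
  expect_equal(ev$guidance$precision, 1)
  expect_equal(ev$guidance$recall, 1)
  if (length(unique(ses$truth$regimes)) == 2) {
    expect_equal(ev$scorer$auroc, 1)
  }

  # shuffled scores carry no signal: AUROC ~ 0.5 on average
  if (length(unique(ses$truth$regimes)) == 2) {
    set.seed(73)
    aurocs <- vapply(1:20, function(i) {
      sc2 <- sc; sc2$score <- sample(sc$score)
      writeScores(sc2, file.path(odir, "scores.csv"))
      evaluateSession(odir, sdir)$scorer$auroc
    }, numeric(1))
    expect_lt(abs(mean(aurocs) - 0.5), 0.05)
  }

  unlink(file.path(odir, "scores.csv"))
  expect_error(evaluateSession(odir, sdir), "missing stage outputs")
})
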