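corners <- cbind(c(0, 959, 959, 0), c(0, 0, 599, 599))

test_that("homography estimation recovers identity and known transforms", {
  h <- estimateHomography(corners, corners, method = "exact4")
  expect_lt(max(abs(homographyMatrix(h) - diag(3))), 1e-9)

  Ht <- matrix(c(1, 0, 5, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  set.seed(11)
  src <- cbind(runif(12, 0, 959), runif(12, 0, 599))
  dst <- applyHomography(planarHomography(Ht), src)
  h2 <- estimateHomography(src, dst)
  expect_lt(max(abs(homographyMatrix(h2) - Ht)), 1e-6)
})

test_that("exact4 interpolates any non-degenerate noiseless correspondence", {
  for (seed in 1:5) {
    set.seed(seed)
    Hg <- matrix(c(1.1, 0.05, 20, -0.04, 0.95, -10,
                   1e-5, -2e-5, 1), 3, 3, byrow = TRUE)
    src <- cbind(runif(4, 50, 900), runif(4, 50, 550))
    if (anyDuplicated(round(src))) next
    dst <- applyHomography(planarHomography(Hg), src)
    h <- tryCatch(estimateHomography(src, dst, method = "exact4"),
                  error = function(e) NULL)
    if (is.null(h)) next  # drew a (near-)collinear quad
    expect_lt(max(abs(applyHomography(h, src) - dst)), 1e-6)
  }
})

test_that("estimation from noisy fiducials stays near the noise floor", {
  Hg <- planarHomography(matrix(c(cos(0.03), -sin(0.03), 8,
                                  sin(0.03), cos(0.03), -5,
                                  1e-5, 5e-6, 1), 3, 3, byrow = TRUE))
  grid <- as.matrix(expand.grid(seq(80, 880, length.out = 5),
                                seq(80, 520, length.out = 5)))
  errs <- vapply(1:5, function(seed) {
    set.seed(seed)
    dst <- applyHomography(Hg, grid) + matrix(rnorm(50, 0, 0.5), ncol = 2)
    h <- estimateHomography(grid, dst)
    held <- cbind(runif(50, 0, 959), runif(50, 0, 599))
    mean(sqrt(rowSums((applyHomography(h, held) -
                         applyHomography(Hg, held))^2)))
  }, numeric(1))
  expect_lt(mean(errs), 1)
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:4 * 10, 1:4 * 10)
  expect_error(estimateHomography(line, line + 1, method = "exact4"), "collinear")
  expect_error(estimateHomography(corners, corners[1:3, ]), "same number")
  expect_error(estimateHomography(corners[1:3, ], corners[1:3, ]), "at least 4")
  expect_error(planarHomography(matrix(0, 3, 3)), "nonzero")
})

test_that("applyHomography matches a per-point brute-force oracle", {
  h <- planarHomography(matrix(c(0.9, 0.1, 12, -0.2, 1.05, 3,
                                 2e-5, -1e-5, 1), 3, 3, byrow = TRUE))
  expect_equal(applyHomography(planarHomography(diag(3)), cbind(7, 9)),
               cbind(x = 7, y = 9))
  tr <- planarHomography(matrix(c(1, 0, 3, 0, 1, -2, 0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(applyHomography(tr, cbind(10, 10)), cbind(x = 13, y = 8))

  set.seed(3)
  pts <- cbind(runif(20, 0, 959), runif(20, 0, 599))
  got <- applyHomography(h, pts)
  M <- homographyMatrix(h)
  for (i in seq_len(nrow(pts))) {
    v <- M %*% c(pts[i, ], 1)
    expect_equal(as.numeric(got[i, ]), as.numeric(v[1:2] / v[3]), tolerance = 1e-12)
  }
})

test_that("forward-then-inverse round trip is exact to 1e-6 px", {
  h <- planarHomography(matrix(c(1.02, 0.03, 15, -0.01, 0.98, -8,
                                 1.5e-5, -8e-6, 1), 3, 3, byrow = TRUE))
  hinv <- invertHomography(h)
  set.seed(4)
  pts <- cbind(runif(1000, 0, 959), runif(1000, 0, 599))
  back <- applyHomography(hinv, applyHomography(h, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("binary mask warping is exact for identity and translations", {
  set.seed(5)
  m <- matrix(runif(120 * 80) > 0.85, 120, 80)
  expect_identical(warpBinaryMask(planarHomography(diag(3)), m), m)

  tr <- planarHomography(matrix(c(1, 0, 10, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  single <- matrix(FALSE, 120, 80); single[31, 41] <- TRUE  # pixel (30, 40)
  w <- warpBinaryMask(tr, single)
  expect_identical(which(w), which(matrix(seq_len(120 * 80), 120, 80) ==
                                     (41 - 1) * 120 + 41))  # pixel (40, 40)

  blob <- matrix(FALSE, 120, 80)
  blob[40:49, 30:39] <- TRUE  # 100-px blob
  for (t in list(c(7, 0), c(0, -6), c(5, 5))) {
    H <- planarHomography(matrix(c(1, 0, t[1], 0, 1, t[2], 0, 0, 1), 3, 3,
                                 byrow = TRUE))
    wb <- warpBinaryMask(H, blob)
    expect_lte(abs(sum(wb) - sum(blob)) / sum(blob), 0.02)
  }
})

test_that("pixel displacements convert to millimeters", {
  cal <- calibrationModel()
  expect_equal(pixelsToMm(cal, 0, 0), 0)
  expect_equal(pixelsToMm(cal, 12, 0), 1.0)  # 12 px at 80 mm / 960 px
  cal1 <- calibrationModel(100L, 100L, 1, 1)
  expect_equal(pixelsToMm(cal1, 3, 4), 5)
  # default field of view spans ~80 mm across the frame
  expect_lt(abs(960 * calibrationModel()@mmPerPxX - 80) / 80, 0.1)
})

test_that("homography JSON round trips", {
  h <- planarHomography(matrix(c(1.1, 0, 4, 0, 0.9, 2, 1e-5, 0, 1), 3, 3,
                               byrow = TRUE))
  p <- withr::local_tempfile(fileext = ".json")
  writeHomography(h, p)
  expect_equal(homographyMatrix(readHomography(p)), homographyMatrix(h),
               tolerance = 1e-12)
})
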