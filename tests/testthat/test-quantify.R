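roiAt <- function(coords) suppressWarnings(ReferenceROI(coords))

test_that("ROI statistics use the sample SD and flag small ROIs", {
  arr <- array(0, c(20, 20, 2))
  arr[1:10, 1:20, 1] <- 100
  img <- ImageVolume(arr)
  co <- as.matrix(expand.grid(row = 1:10, col = 1:20, slice = 1))
  rs <- expect_silent(roiStats(img, roiAt(co)))
  expect_equal(rs$mean, 100)
  expect_equal(rs$sd, 0)
  expect_equal(rs$n, 200L)

  arr[1, 1, 2] <- 90; arr[2, 1, 2] <- 110
  img <- ImageVolume(arr)
  expect_warning(
    rs2 <- roiStats(img, roiAt(rbind(c(1, 1, 2), c(2, 1, 2)))), "200")
  expect_equal(rs2$mean, 100)
  expect_equal(rs2$sd, 20 / sqrt(2))  # |110 - 90| / sqrt(2)
  expect_error(roiStats(img, roiAt(cbind(25, 1, 1))), "outside")
})

test_that("ROI statistics match a two-pass oracle on random draws", {
  set.seed(31)
  arr <- array(rlnorm(6000, 4, 0.5), c(30, 20, 10))
  img <- ImageVolume(arr)
  idx <- sample(length(arr), 300)
  co <- arrayInd(idx, dim(arr))
  rs <- roiStats(img, ReferenceROI(co))
  vals <- arr[co]
  m <- sum(vals) / 300
  s <- sqrt(sum((vals - m)^2) / 299)
  expect_equal(rs$mean, m, tolerance = 1e-10)
  expect_equal(rs$sd, s, tolerance = 1e-10)
})

test_that("the threshold is mean + k * SD with the anatomy presets", {
  expect_equal(computeThreshold(100, 10, 4.15), 141.5)
  expect_equal(computeThreshold(100, 10, 0), 100)
  expect_equal(computeThreshold(50, 20, 2.64), 102.8)
  expect_equal(presetK("spine"), 4.15)
  expect_equal(presetK("si"), 2.64)
  expect_error(computeThreshold(100, -1, 2), "sd")
  expect_error(computeThreshold(100, 10, -0.5), "k")
})

test_that("hyper-intense masking is strict and confined to bone", {
  arr <- array(c(100, 141.5, 141.6, 200, 90, 300, 300, 300), c(2, 2, 2))
  img <- ImageVolume(arr)
  bone <- array(TRUE, c(2, 2, 2)); bone[2, 2, 2] <- FALSE  # excludes a 300
  bm <- new("RegionMask", voxels = bone, id = "b")
  sel <- voxels(maskHyperintense(img, bm, 141.5))
  expect_equal(sum(sel), 4)            # 141.6, 200, and two 300s in bone
  expect_false(sel[2, 1, 1])           # exactly at T: excluded
  expect_false(sel[2, 2, 2])           # outside bone
  # T below all intensities: mask == bone; above all: empty
  expect_identical(voxels(maskHyperintense(img, bm, 0)), bone)
  expect_equal(sum(voxels(maskHyperintense(img, bm, 1e6))), 0)
  expect_error(
    maskHyperintense(img, new("RegionMask", voxels = array(TRUE, c(3, 3, 3)),
                              id = "x"), 1), "mismatch")
})

test_that("connectivity definitions separate corner-touching voxels", {
  m <- array(FALSE, c(5, 5, 5))
  m[1, 1, 1] <- TRUE; m[5, 5, 5] <- TRUE
  expect_equal(max(labelComponents(new("RegionMask", voxels = m, id = "m"),
                                   26)), 2)
  m2 <- array(FALSE, c(3, 3, 3))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE   # touch only at a corner
  msk2 <- new("RegionMask", voxels = m2, id = "m2")
  expect_equal(max(labelComponents(msk2, 26)), 1)
  expect_equal(max(labelComponents(msk2, 6)), 2)
  expect_equal(max(labelComponents(msk2, 18)), 2)
})

test_that("in-plane connectivities never join voxels across slices", {
  m <- array(FALSE, c(4, 4, 3))
  m[2, 2, 1] <- TRUE; m[2, 2, 2] <- TRUE  # stacked: one object in 3D
  msk <- new("RegionMask", voxels = m, id = "m")
  expect_equal(max(labelComponents(msk, 6)), 1)
  expect_equal(max(labelComponents(msk, 4)), 2)
  expect_equal(max(labelComponents(msk, 8)), 2)
})

test_that("component labelling matches the union-find oracle", {
  for (seed in 1:6) {
    msk <- randomMask(c(20, 20, 10), 0.2, seed = 300 + seed)
    for (conn in c(6, 18, 26, 4, 8)) {
      got <- labelComponents(msk, conn)
      want <- unionFindLabel(voxels(msk), oracleOffsets(conn))
      expect_true(samePartition(got, want),
                  label = sprintf("seed %d connectivity %s", seed, conn))
    }
  }
})

test_that("the size filter keeps components of at least minSize voxels", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:9, 1, 1] <- TRUE            # 9 voxels: removed
  m[1:10, 3, 1] <- TRUE           # 10 voxels: kept
  m[1:3, 5, 1] <- TRUE            # 3 voxels: removed
  m[1:5, 7:11 - 4, 5] <- TRUE     # 25 voxels: kept
  lab <- labelComponents(new("RegionMask", voxels = m, id = "m"), 26)
  expect_setequal(tabulate(lab[lab > 0]), c(9, 10, 3, 25))
  kept <- filterSmall(lab, 10)
  expect_setequal(tabulate(kept[kept > 0]), c(10, 25))
  # minSize = 1 is the identity; empty input stays empty
  expect_identical(filterSmall(lab, 1), lab)
  expect_identical(filterSmall(array(0L, c(2, 2, 2))),
                   array(0L, c(2, 2, 2)))
  expect_error(filterSmall(lab, 0), "minSize")
})

test_that("relative intensity normalizes to the marrow mean", {
  expect_equal(relativeIntensity(100, 100), 0)
  expect_equal(relativeIntensity(200, 100), 1)
  expect_equal(relativeIntensity(150, 100), 0.5)
  expect_equal(relativeIntensity(c(100, 150), 100), c(0, 0.5))
  expect_error(relativeIntensity(100, 0), "positive")
  expect_error(relativeIntensity(100, -5), "positive")
})

test_that("summaries pool voxels and use interpolated percentiles", {
  # 1 lesion of 500 voxels at voxel volume 0.004 -> 2 cm^3
  m <- array(FALSE, c(10, 10, 10)); m[1:5, 1:10, 1:10] <- TRUE
  arr <- array(100, c(10, 10, 10)); arr[m] <- 300
  img <- ImageVolume(arr, spacing = c(1, 1, 4))
  lab <- labelComponents(new("RegionMask", voxels = m, id = "m"), 26)
  ls <- lesionSetFromLabels(lab, img, roiMean = 100, vv = 0.004)
  q <- summarizeLesions(ls, roiMean = 100, roiSD = 10, roiN = 200L,
                        threshold = 141.5, k = 4.15)
  expect_equal(volumeHyper(q), 2.0)
  expect_equal(nLesions(q), 1L)
  expect_equal(relIntensitySummary(q)[["mean"]], 2)

  # explicit pooled values
  vals <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(mean(vals), 0.5)
  ls2 <- new("LesionSet", voxelVolume = 0.004, lesions = list(list(
    label = 1L, coords = cbind(1:4, 1, 1), size = 4L, volume = 0.016,
    sHyper = 100 * (1 + vals), sRelHyper = vals)))
  q2 <- summarizeLesions(ls2)
  expect_equal(relIntensitySummary(q2)[["mean"]], 0.5)
  expect_equal(relIntensitySummary(q2)[["median"]], 0.5)
})

test_that("percentiles agree with the sorting oracle on random pools", {
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(1000)
    ls <- new("LesionSet", voxelVolume = 1, lesions = list(list(
      label = 1L, coords = cbind(seq_along(x), 1, 1),
      size = length(x), volume = length(x), sHyper = x + 2, sRelHyper = x)))
    s <- relIntensitySummary(summarizeLesions(ls))
    expect_equal(s[["p75"]], percentileOracle(x, 0.75), tolerance = 1e-10)
    expect_equal(s[["p90"]], percentileOracle(x, 0.90), tolerance = 1e-10)
    expect_equal(s[["median"]], percentileOracle(x, 0.5), tolerance = 1e-10)
  }
})

test_that("an empty lesion set reports zero volume and absent summaries", {
  ls <- new("LesionSet", lesions = list(), voxelVolume = 0.004)
  q <- summarizeLesions(ls)
  expect_equal(volumeHyper(q), 0)
  expect_equal(nLesions(q), 0L)
  expect_true(all(is.na(relIntensitySummary(q))))
})

test_that("lesion voxel sets shrink as k grows and exceed the threshold", {
  ph <- generatePhantom(smallPhantomConfig(
    lesions = list(list(center = c(16, 16, 7), semiAxes = c(5, 5, 2),
                        delta = 5))), seed = 41)
  kGrid <- c(1, 2, 2.64, 3, 4.15, 5)
  sets <- lapply(kGrid, function(k) {
    q <- quantifyEdema(ph$image, ph$bone, ph$roi, k = k)
    do.call(rbind, lapply(lesions(q), `[[`, "coords"))
  })
  asKey <- function(co) if (is.null(co)) character() else
    paste(co[, 1], co[, 2], co[, 3])
  for (j in 2:length(kGrid)) {
    expect_true(all(asKey(sets[[j]]) %in% asKey(sets[[j - 1]])),
                label = sprintf("nesting at k = %g", kGrid[j]))
  }
  # every reported relative intensity exceeds the relative threshold
  q <- quantifyEdema(ph$image, ph$bone, ph$roi, k = 2.64)
  relT <- (threshold(q) - q@roiMean) / q@roiMean
  pooled <- unlist(lapply(lesions(q), `[[`, "sRelHyper"))
  expect_true(all(pooled > relT))
})

test_that("the lesion voxel set is invariant to intensity rescaling", {
  ph <- generatePhantom(smallPhantomConfig(
    lesions = list(list(center = c(16, 16, 7), semiAxes = c(4, 4, 2),
                        delta = 6))), seed = 42)
  q1 <- quantifyEdema(ph$image, ph$bone, ph$roi, preset = "si")
  scaled <- ImageVolume(voxels(ph$image) * 3.7, spacing = spacing(ph$image),
                        sliceGapFraction = sliceGapFraction(ph$image))
  q2 <- quantifyEdema(scaled, ph$bone, ph$roi, preset = "si")
  expect_equal(volumeHyper(q2), volumeHyper(q1))
  expect_equal(nLesions(q2), nLesions(q1))
  expect_equal(relIntensitySummary(q2), relIntensitySummary(q1),
               tolerance = 1e-12)
  co1 <- lapply(lesions(q1), `[[`, "coords")
  co2 <- lapply(lesions(q2), `[[`, "coords")
  expect_identical(co1, co2)
})

test_that("volume_hyper equals surviving voxel count times voxel volume", {
  ph <- generatePhantom(smallPhantomConfig(
    lesions = list(list(center = c(16, 16, 7), semiAxes = c(5, 5, 2),
                        delta = 6))), seed = 43)
  q <- quantifyEdema(ph$image, ph$bone, ph$roi, preset = "spine")
  nvox <- sum(vapply(lesions(q), `[[`, integer(1), "size"))
  expect_equal(volumeHyper(q), nvox * voxelVolume(ph$image))
  # with the gap included the voxel volume inflates by 1 + gap fraction
  qg <- quantifyEdema(ph$image, ph$bone, ph$roi, preset = "spine",
                      includeGap = TRUE)
  expect_equal(volumeHyper(qg), volumeHyper(q) * 1.1)
})
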