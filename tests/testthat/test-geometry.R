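test_that("component labelling matches an exhaustive flood-fill oracle", {
  set.seed(42)
  for (conn in c(6, 26)) {
    for (rep in 1:10) {
      d <- sample(2:6, 3, replace = TRUE)
      m <- array(runif(prod(d)) < 0.4, d)
      got <- canonicalLabels(labelComponents(m, conn))
      want <- canonicalLabels(floodFillLabels(m, conn))
      expect_identical(got, want)
    }
  }
  # diagonal voxels: one component under 26, two under 6
  m2 <- array(FALSE, c(2, 2, 1)); m2[1, 1, 1] <- m2[2, 2, 1] <- TRUE
  expect_equal(max(labelComponents(m2, 26)), 1L)
  expect_equal(max(labelComponents(m2, 6)), 2L)
})

test_that("preprocessing resamples and smooths as specified", {
  # 20 voxels at 1.036 um resampled to 0.2072 um -> 100 voxels
  v <- Volume3D(array(1, c(20, 20, 20)), spacing = rep(1.036, 3))
  pv <- preprocessVolume(v, 0.2072, 5)
  expect_equal(dim(pv), c(100, 100, 100))
  expect_equal(spacing(pv), rep(0.2072, 3))
  # constants pass through untouched
  expect_true(all(abs(intensities(pv) - 1) < 1e-12))
  # a single bright voxel spreads uniformly over the 5^3 neighbourhood
  a <- array(0, c(11, 11, 11)); a[6, 6, 6] <- 125
  sm <- intensities(preprocessVolume(Volume3D(a), 1, 5))
  expect_equal(sm[6, 6, 6], 1)
  expect_equal(sm[4, 4, 4], 1)
  expect_equal(sm[8, 8, 8], 1)
  expect_equal(sm[3, 6, 6], 0)
  expect_equal(sum(sm), 125)
  # trilinear interpolation against a hand-computed linear ramp
  ramp <- Volume3D(array(rep(1:4, 16), c(4, 4, 4)), spacing = rep(1, 3))
  half <- preprocessVolume(ramp, 0.5, 1)
  expect_equal(dim(half), c(8, 8, 8))
  expect_equal(half@intensities[3, 1, 1], 1.75)  # centre 1.25 -> source pos 1.75
  expect_error(preprocessVolume(ramp, 10, 1), "extent")
  expect_error(preprocessVolume(ramp, 0.5, 4))   # even width rejected
})

test_that("cluster extraction follows the quantile/trim/size rules exactly", {
  # two-level volume: exactly 20% bright voxels forming one blob
  x <- array(10, c(10, 10, 10))
  blob <- arrayInd(1:200, c(10, 10, 2))
  x[cbind(blob[, 1], blob[, 2], blob[, 3])] <- 100
  cs <- extractInterstitialClusters(Volume3D(x), minSize = 50)
  expect_equal(nClusters(cs), 1L)
  expect_equal(unname(clusterSizes(cs)), 200L)

  # distinct intensities: foreground count is exactly floor(0.2 N)
  set.seed(7)
  xs <- array(sample(seq_len(8000)), c(20, 20, 20))
  csD <- extractInterstitialClusters(Volume3D(xs), minSize = 1)
  expect_equal(sum(labelArray(csD) > 0), floor(0.2 * 8000))

  # all-equal intensities: strict inequality leaves no foreground
  flat <- extractInterstitialClusters(Volume3D(array(5, c(8, 8, 8))))
  expect_equal(nClusters(flat), 0L)

  # a 49-voxel blob is deleted; its 151-voxel companion survives
  y <- array(10, c(10, 10, 10))
  y[1:7, 1:7, 1] <- 100              # 49 voxels
  y[, , 9] <- 100                    # 100 voxels
  y[1:10, 1:5, 10] <- 100            # +50, connected to the z = 9 layer
  y[1, 6, 10] <- 100                 # +1 -> bright total 200 = 20%
  csY <- extractInterstitialClusters(Volume3D(y), minSize = 50)
  expect_equal(nClusters(csY), 1L)
  expect_equal(unname(clusterSizes(csY)), 151L)
})

test_that("huge-cluster trimming keeps exactly the top intensity half", {
  # one 6000-voxel component with a known ranking: intensity increases
  # monotonically along x so the retained half is the brighter block
  x <- array(0, c(40, 30, 20))
  x[1:20, 1:20, 1:15] <- seq_len(6000) + 100   # bright blob, ranked
  csH <- extractInterstitialClusters(Volume3D(x), topFraction = 0.25,
                                     hugeSize = 5000, trimFraction = 0.5,
                                     minSize = 1)
  expect_equal(sum(labelArray(csH) > 0), 3000L)
  # brute-force oracle: retained voxels are exactly the 3000 brightest
  blobVals <- x[x > 100]
  keepMin <- sort(blobVals, decreasing = TRUE)[3000]
  expect_true(all(x[labelArray(csH) > 0] >= keepMin))
})

test_that("extraction filters are monotone", {
  set.seed(21)
  x <- array(rnorm(16^3), c(16, 16, 16))
  v <- Volume3D(x)
  nCl <- vapply(c(1, 5, 20, 60), function(ms)
    nClusters(extractInterstitialClusters(v, minSize = ms)), numeric(1))
  expect_true(all(diff(nCl) <= 0))
  fgN <- vapply(c(0.3, 0.2, 0.1, 0.05), function(tf)
    sum(labelArray(extractInterstitialClusters(v, topFraction = tf,
                                               minSize = 1)) > 0), numeric(1))
  expect_true(all(diff(fgN) <= 0))
})

test_that("moment ellipses reproduce analytic shapes and equivariances", {
  mkSet <- function(m) {
    lab <- labelComponents(m, 26)
    ifshear:::clusterSetFromLabels(lab, array(1, dim(m)), c(1, 1, 1))
  }
  # filled disk of radius r: major ~ minor ~ 2 r, angle 0 by convention
  m <- array(FALSE, c(41, 41, 3))
  for (i in 1:41) for (j in 1:41)
    if ((i - 21)^2 + (j - 21)^2 <= 100) m[i, j, 2] <- TRUE
  ef <- fitClusterEllipses(mkSet(m), slice = 2, stackAxis = 3)
  expect_equal(ef$major, 20, tolerance = 0.02)
  expect_equal(ef$minor, 20, tolerance = 0.02)
  expect_equal(ef$angle, 0)
  # 1-voxel-wide segment of length L along x: major = 4 L / sqrt(12), angle 0
  m2 <- array(FALSE, c(30, 10, 3)); m2[6:20, 5, 2] <- TRUE
  ef2 <- fitClusterEllipses(mkSet(m2), slice = 2, stackAxis = 3)
  expect_equal(ef2$major, 15 * 4 / sqrt(12), tolerance = 1e-6)
  expect_equal(ef2$angle, 0, tolerance = 1e-10)
  expect_gt(ef2$minor, 0)
  # rotating a footprint by 90 deg keeps axes, shifts angle by pi/2 (mod pi)
  m3 <- array(FALSE, c(25, 25, 1))
  m3[5:20, 10:13, 1] <- TRUE; m3[5:9, 14:16, 1] <- TRUE
  rot <- array(FALSE, c(25, 25, 1))
  rot[, , 1] <- t(m3[25:1, , 1])
  e3 <- fitClusterEllipses(mkSet(m3), slice = 1, stackAxis = 3)
  e4 <- fitClusterEllipses(mkSet(rot), slice = 1, stackAxis = 3)
  expect_equal(e3$major, e4$major, tolerance = 1e-9)
  expect_equal(e3$minor, e4$minor, tolerance = 1e-9)
  dAng <- (e4$angle - e3$angle) %% pi
  expect_equal(dAng, pi / 2, tolerance = 1e-9)
  # too-small footprints are skipped with a reason
  m5 <- array(FALSE, c(10, 10, 1)); m5[3:4, 3, 1] <- TRUE
  e5 <- fitClusterEllipses(mkSet(m5), slice = 1, stackAxis = 3)
  expect_equal(nrow(e5), 0)
  expect_match(attr(e5, "skipped")$reason, "footprint")
})
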