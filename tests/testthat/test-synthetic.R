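test_that("pore-volume generator is seed-deterministic and honours the empty case", {
  sp <- poreVolumeSpec(shape = c(24, 24, 16), nChannels = 3, seed = 11)
  g1 <- generatePoreVolume(sp)
  g2 <- generatePoreVolume(sp)
  expect_identical(intensities(g1$volume), intensities(g2$volume))
  expect_identical(g1$groundTruth, g2$groundTruth)
  g3 <- generatePoreVolume(poreVolumeSpec(shape = c(24, 24, 16), nChannels = 3,
                                          seed = 12))
  expect_false(identical(intensities(g1$volume), intensities(g3$volume)))

  empty <- generatePoreVolume(poreVolumeSpec(shape = c(16, 16, 8),
                                             nChannels = 0, seed = 1))
  expect_equal(nrow(empty$groundTruth), 0)
  # pure background noise: all intensities near bgIntensity
  expect_lt(max(abs(intensities(empty$volume) - 10)), 6 * 5)
})

test_that("a noiseless single tube matches the brute-force voxelised area", {
  va <- 0.2072^2
  A <- 9 * pi * va                       # radius = 3 voxels
  sp <- poreVolumeSpec(shape = c(32, 32, 12), nChannels = 1,
                       logMu = log(A), logSigma = 1e-6,
                       orientationAxis = c(0, 0, 1), orientationJitter = 0,
                       noiseSd = 0, seed = 4)
  g <- generatePoreVolume(sp)
  fg <- intensities(g$volume) > 50
  perSlice <- apply(fg, 3, sum)
  centre <- as.numeric(g$groundTruth[1, c("cx", "cy", "cz")])
  r <- sqrt(g$groundTruth$area[1] / pi)
  oracle <- bruteTubeSliceCounts(c(32, 32, 12), rep(0.2072, 3), centre, r)
  expect_identical(as.integer(perSlice), oracle)
  # voxelised area close to the drawn analytic area
  expect_lt(abs(mean(perSlice) * va - g$groundTruth$area[1]),
            0.15 * g$groundTruth$area[1])
})

test_that("channel area draws converge to the log-normal mean", {
  a <- ifshear:::withSeed(99, ifshear:::drawChannelAreas(1e4, 0.69, 0.4))
  expect_lt(abs(mean(a) / exp(0.69 + 0.4^2 / 2) - 1), 0.05)
})

test_that("pore spec invariants are enforced", {
  expect_error(poreVolumeSpec(fgIntensity = 5, bgIntensity = 10), "exceed")
  expect_error(poreVolumeSpec(orientationJitter = 2), "pi/2")
  expect_error(poreVolumeSpec(logSigma = 0), "logSigma")
})

test_that("tracer volumes carry analytic ground truth and flag truncation", {
  g <- generateTracerVolumes(c(0.3, 0.3, 0.3), c(0.3, 0.6, 0.3),
                             shape = c(48, 48, 48), spacing = rep(0.1, 3))
  expect_false(any(g$groundTruth$truncated))
  expect_equal(g$groundTruth$postExtent[2], 2 * g$groundTruth$preExtent[2])
  expect_equal(g$groundTruth$postExtent[1], g$groundTruth$preExtent[1])
  # identical sds -> identical volumes
  gSame <- generateTracerVolumes(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3),
                                 shape = c(32, 32, 32), spacing = rep(0.1, 3))
  expect_identical(intensities(gSame$pre), intensities(gSame$post))
  # oversize blob is flagged as truncated
  gBig <- generateTracerVolumes(rep(2, 3), rep(2, 3), shape = c(32, 32, 32),
                                spacing = rep(0.1, 3))
  expect_true(all(gBig$groundTruth$truncated))
  expect_match(gBig$groundTruth$warning, "truncated")
  expect_error(generateTracerVolumes(c(1, 1, 1), c(1, 0.5, 1)))
})

test_that("beat-series generator matches its stated model", {
  # no modulation, no artifacts -> constant RRI and SBP
  flat <- generateBeatSeries(beatSeriesSpec(duration = 120, lfAmpRri = 0,
    hfAmpRri = 0, lfAmpSbp = 0, ectopicRate = 0, dropoutRate = 0, seed = 2))
  expect_true(all(abs(flat$series@rri - 1.0) < 1e-12))
  expect_true(all(abs(flat$series@sbp - 140) < 1e-12))
  # beat count ~ duration / meanRri
  g600 <- generateBeatSeries(beatSeriesSpec(duration = 600, meanRri = 1.0,
    ectopicRate = 0, dropoutRate = 0, seed = 3))
  expect_lt(abs(length(g600$series) - 600), 5)
  # invariant: RRI_i = t_i - t_{i-1}
  s <- g600$series
  expect_equal(diff(s@time), s@rri[-1])
  # determinism
  gA <- generateBeatSeries(beatSeriesSpec(seed = 7))
  gB <- generateBeatSeries(beatSeriesSpec(seed = 7))
  expect_identical(as.data.frame(gA$series), as.data.frame(gB$series))
  # artifact ground truth: rates map to exact counts
  gArt <- generateBeatSeries(beatSeriesSpec(duration = 400,
    ectopicRate = 5 / 400, dropoutRate = 4 / 400, seed = 5))
  expect_length(gArt$groundTruth$ectopicIdx, round(5 / 400 * length(gArt$series)))
  expect_length(gArt$groundTruth$dropoutIdx, round(4 / 400 * length(gArt$series)))
  expect_true(all(is.na(gArt$series@sbp[gArt$groundTruth$dropoutIdx])))
  expect_true(all(!gArt$series@bpValid[gArt$groundTruth$dropoutIdx]))
})

test_that("nerve-signal generator obeys its additive model", {
  bt <- seq(0.5, 8, by = 0.8)
  # burstAmp 0 -> offset + noise only
  g0 <- generateNerveSignal(3000, bt, burstAmp = 0, noiseSd = 0.1,
                            dcOffset = 2, seed = 3)
  expect_lt(abs(mean(g0$signal@samples) - 2), 0.01)
  expect_true(all(g0$groundTruth$burstEnergy == 0))
  # noiseless identical bursts -> equal per-beat ground-truth energy
  g1 <- generateNerveSignal(3000, bt, burstAmp = 1, noiseSd = 0, seed = 3)
  interior <- g1$groundTruth$burstEnergy[2:(length(bt) - 1)]
  expect_lt(diff(range(interior)) / mean(interior), 1e-6)
  # doubling burst amplitude quadruples burst energy (amplitude scales 2x)
  g2 <- generateNerveSignal(3000, bt, burstAmp = 2, noiseSd = 0, seed = 3)
  expect_equal(g2$groundTruth$burstEnergy, 4 * g1$groundTruth$burstEnergy,
               tolerance = 1e-10)
  # determinism
  gA <- generateNerveSignal(3000, bt, seed = 9)
  gB <- generateNerveSignal(3000, bt, seed = 9)
  expect_identical(gA$signal@samples, gB$signal@samples)
})
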