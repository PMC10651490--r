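#' Specification for a synthetic interstitial-channel volume
#'
#' Defaults emulate the imaged interstitial space of the rat brainstem:
#' channels oriented along the rostral--caudal (y) axis with small angular
#' jitter, on the 0.2072 um isotropic grid the imaging analysis works at,
#' sized so the channels jointly occupy roughly the ~20\% volume fraction
#' that brain extracellular space occupies (the premise of the top-20\%
#' extraction rule). The default log-normal (logMu = 0.69, logSigma = 0.4,
#' modal area ~1.7 um^2, i.e. ~40 voxels across) keeps every channel
#' resolvable on this grid; the measured-tissue envelope 0.0083--0.18 um^2
#' corresponds to logMu = -1.55, logSigma = 1.31 and is sub-voxel here, so
#' use it only where the distributional fit alone is exercised.
#'
#' @param shape integer(3) voxel counts per axis.
#' @param spacing numeric(3) um per voxel.
#' @param nChannels number of channels.
#' @param logMu,logSigma log-normal parameters of the cross-sectional area
#'   distribution (log um^2).
#' @param orientationAxis preferred direction (normalised internally).
#' @param orientationJitter s.d. of angular deviation, radians, in [0, pi/2).
#' @param aspectRatio elliptical cross-section major/minor ratio (>= 1).
#' @param fgIntensity,bgIntensity channel and background intensity (a.u.).
#' @param noiseSd additive Gaussian noise s.d. (a.u.).
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{PoreVolumeSpec}.
#' @export
poreVolumeSpec <- function(shape = c(64, 64, 64), spacing = rep(0.2072, 3),
                           nChannels = 16L, logMu = 0.69, logSigma = 0.4,
                           orientationAxis = c(0, 1, 0), orientationJitter = 0.1,
                           aspectRatio = 1, fgIntensity = 100, bgIntensity = 10,
                           noiseSd = 5, seed = 1L) {
  axis <- as.numeric(orientationAxis)
  axis <- axis / sqrt(sum(axis^2))
  new("PoreVolumeSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      nChannels = as.integer(nChannels), logMu = logMu, logSigma = logSigma,
      orientationAxis = axis, orientationJitter = orientationJitter,
      aspectRatio = aspectRatio, fgIntensity = fgIntensity,
      bgIntensity = bgIntensity, noiseSd = noiseSd, seed = as.integer(seed))
}

# Cross-sectional area draws shared by the generator (log-normal in um^2).
drawChannelAreas <- function(n, logMu, logSigma) {
  exp(stats::rnorm(n, logMu, logSigma))
}

# Orthonormal basis perpendicular to unit vector v.
orthoBasis <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- ref - sum(ref * v) * v
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(v[2] * n1[3] - v[3] * n1[2],
          v[3] * n1[1] - v[1] * n1[3],
          v[1] * n1[2] - v[2] * n1[1])
  rbind(n1, n2)
}

# Voxel-centre membership mask of an infinite elliptic cylinder.
# centre/direction in physical units; area in squared physical units.
cylinderMask <- function(shape, spacing, centre, direction, area, aspect = 1,
                         pad = 0) {
  cx <- voxelCenters(shape[1], spacing[1])
  cy <- voxelCenters(shape[2], spacing[2])
  cz <- voxelCenters(shape[3], spacing[3])
  P1 <- array(rep(cx, times = shape[2] * shape[3]), shape) - centre[1]
  P2 <- array(rep(rep(cy, each = shape[1]), times = shape[3]), shape) - centre[2]
  P3 <- array(rep(cz, each = shape[1] * shape[2]), shape) - centre[3]
  nb <- orthoBasis(direction)
  sMinor <- sqrt(area / (pi * aspect)) + pad
  sMajor <- aspect * sqrt(area / (pi * aspect)) + pad
  q1 <- (P1 * nb[1, 1] + P2 * nb[1, 2] + P3 * nb[1, 3]) / sMajor
  q2 <- (P1 * nb[2, 1] + P2 * nb[2, 2] + P3 * nb[2, 3]) / sMinor
  q1 * q1 + q2 * q2 <= 1
}

#' Generate a synthetic interstitial-channel volume with ground truth
#'
#' Places \code{nChannels} straight elliptic-cylinder channels whose
#' cross-sectional areas are i.i.d. log-normal and whose directions deviate
#' from the preferred axis by N(0, orientationJitter) polar angles at uniform
#' azimuth, then adds Gaussian noise. Channel centres sit on a jittered
#' square lattice in the plane transverse to the preferred axis (real
#' interstitial channels are roughly evenly spaced, and a lattice keeps the
#' target ~20\% occupancy packable); a candidate whose clearance-padded
#' cross-section touches an existing channel is re-jittered, and persistent
#' overlap raises an error. Identical spec and seed give bit-identical
#' output.
#'
#' @param spec a \linkS4class{PoreVolumeSpec}.
#' @param maxRetries placement retries per channel before failing.
#' @param clearance minimum gap between channel surfaces (same units as
#'   spacing, default 0.5 um) so channels stay separable after the ~1 um
#'   smoothing of the analysis chain.
#' @return list with \code{volume} (\linkS4class{Volume3D}) and
#'   \code{groundTruth}: data.frame of per-channel \code{area} (um^2),
#'   direction cosines \code{dx,dy,dz}, polar deviation \code{theta}, and
#'   centre coordinates.
#' @examples
#' gp <- generatePoreVolume(poreVolumeSpec(shape = c(24, 24, 24), nChannels = 3,
#'   logMu = log(0.6), logSigma = 0.3, seed = 7))
#' gp$groundTruth$area
#' @export
generatePoreVolume <- function(spec, maxRetries = 200L, clearance = 0.5) {
  validObject(spec)
  shape <- spec@shape
  withSeed(spec@seed, {
    vol <- array(spec@bgIntensity, shape)
    fgAll <- array(FALSE, shape)
    extent <- shape * spec@spacing
    n <- spec@nChannels
    gt <- data.frame(area = numeric(0), dx = numeric(0), dy = numeric(0),
                     dz = numeric(0), theta = numeric(0),
                     cx = numeric(0), cy = numeric(0), cz = numeric(0))
    areas <- drawChannelAreas(n, spec@logMu, spec@logSigma)
    thetas <- if (spec@orientationJitter > 0)
      stats::rnorm(n, 0, spec@orientationJitter) else numeric(n)
    phis <- stats::runif(n, 0, 2 * pi)
    nb <- orthoBasis(spec@orientationAxis)
    # jittered square lattice in the transverse (n1, n2) plane
    volCentre <- extent / 2
    e1 <- sum(abs(nb[1, ]) * extent)
    e2 <- sum(abs(nb[2, ]) * extent)
    k <- ceiling(sqrt(n))
    cell1 <- e1 / k
    cell2 <- e2 / k
    cells <- expand.grid(i = seq_len(k), j = seq_len(k))
    cells <- cells[sample(nrow(cells), n), , drop = FALSE]
    # biggest channels claim space first; gt rows keep the draw order
    for (i in order(areas, decreasing = TRUE)) {
      area <- areas[i]
      theta <- thetas[i]
      phi <- phis[i]
      dirn <- cos(theta) * spec@orientationAxis +
        sin(theta) * (cos(phi) * nb[1, ] + sin(phi) * nb[2, ])
      u0 <- (cells$i[i] - 0.5) * cell1 - e1 / 2
      v0 <- (cells$j[i] - 0.5) * cell2 - e2 / 2
      placed <- FALSE
      for (try in seq_len(maxRetries)) {
        if (try <= maxRetries / 2) {
          u <- u0 + stats::runif(1, -0.15, 0.15) * cell1
          v <- v0 + stats::runif(1, -0.15, 0.15) * cell2
        } else {      # cell too crowded: fall back to free placement
          u <- stats::runif(1, -0.45, 0.45) * e1
          v <- stats::runif(1, -0.45, 0.45) * e2
        }
        centre <- volCentre + u * nb[1, ] + v * nb[2, ]
        mPad <- cylinderMask(shape, spec@spacing, centre, dirn, area,
                             spec@aspectRatio, pad = clearance)
        if (!any(mPad & fgAll)) {
          fgAll <- fgAll | cylinderMask(shape, spec@spacing, centre, dirn,
                                        area, spec@aspectRatio)
          gt[i, ] <- c(area, dirn, theta, centre)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place channel ", i, " without overlap after ",
             maxRetries, " retries")
    }
    vol[fgAll] <- spec@fgIntensity
    if (spec@noiseSd > 0)
      vol <- vol + stats::rnorm(length(vol), 0, spec@noiseSd)
    list(volume = Volume3D(vol, spacing = spec@spacing),
         groundTruth = gt)
  })
}

#' Generate paired pre/post tracer volumes with an air reference region
#'
#' Two CT-like volumes share an anisotropic Gaussian tracer blob (standard
#' deviations per axis in the volume's spatial units) on a background equal
#' to the air level, so that only the blob exceeds the 1.02 x air threshold
#' used downstream. The air reference is a fixed corner sub-volume. Ground
#' truth records the analytic per-axis extent of the super-threshold region;
#' blobs truncated by the volume boundary are flagged in the metadata.
#'
#' @param preSpreadSd,postSpreadSd numeric(3) Gaussian s.d. per axis;
#'   post must be >= pre elementwise.
#' @param airIntensity mean air level (a.u.).
#' @param tracerPeak blob peak amplitude above background (a.u.).
#' @param shape,spacing volume geometry (spacing in mm for CT data).
#' @param noiseSd additive Gaussian noise s.d. (default 0, exact volumes).
#' @param thresholdRatio threshold used for the analytic ground-truth extent.
#' @param seed integer RNG seed (used only when noiseSd > 0).
#' @return list with \code{pre}, \code{post} (\linkS4class{Volume3D}),
#'   \code{airRoi} (2 x 3 index matrix of the corner box), and
#'   \code{groundTruth} (centre, sds, analytic extents, truncation flags).
#' @export
generateTracerVolumes <- function(preSpreadSd, postSpreadSd,
                                  airIntensity = 100, tracerPeak = 50,
                                  shape = c(48, 48, 48), spacing = rep(0.1, 3),
                                  noiseSd = 0, thresholdRatio = 1.02,
                                  seed = 1L) {
  preSpreadSd <- rep_len(as.numeric(preSpreadSd), 3)
  postSpreadSd <- rep_len(as.numeric(postSpreadSd), 3)
  stopifnot(all(postSpreadSd >= preSpreadSd), all(preSpreadSd > 0),
            airIntensity > 0, tracerPeak > 0)
  shape <- as.integer(shape)
  extent <- shape * spacing
  airBox <- rbind(c(1, 1, 1), pmax(1L, shape %/% 5L))
  rownames(airBox) <- c("from", "to")
  # blob centred in the far corner's opposite half so it clears the air box
  centre <- 0.6 * extent
  blob <- function(sd3) {
    g1 <- exp(-0.5 * ((voxelCenters(shape[1], spacing[1]) - centre[1]) / sd3[1])^2)
    g2 <- exp(-0.5 * ((voxelCenters(shape[2], spacing[2]) - centre[2]) / sd3[2])^2)
    g3 <- exp(-0.5 * ((voxelCenters(shape[3], spacing[3]) - centre[3]) / sd3[3])^2)
    airIntensity + tracerPeak * (array(g1, shape) *
      array(rep(g2, each = shape[1]), shape) *
      array(rep(g3, each = shape[1] * shape[2]), shape))
  }
  vols <- withSeed(seed, {
    lapply(list(preSpreadSd, postSpreadSd), function(sd3) {
      v <- blob(sd3)
      if (noiseSd > 0) v <- v + stats::rnorm(length(v), 0, noiseSd)
      Volume3D(v, spacing = spacing)
    })
  })
  # analytic half-width where the blob crosses thresholdRatio * air
  lvl <- (thresholdRatio - 1) * airIntensity
  halfWidth <- function(sd3) {
    if (tracerPeak <= lvl) return(rep(0, 3))
    sd3 * sqrt(2 * log(tracerPeak / lvl))
  }
  hwPre <- halfWidth(preSpreadSd)
  hwPost <- halfWidth(postSpreadSd)
  truncated <- (centre - hwPost < 0) | (centre + hwPost > extent)
  gt <- list(centre = centre, preSd = preSpreadSd, postSd = postSpreadSd,
             preExtent = 2 * hwPre, postExtent = 2 * hwPost,
             truncated = truncated)
  if (any(truncated))
    gt$warning <- "tracer blob truncated by the volume boundary"
  list(pre = vols[[1]], post = vols[[2]], airRoi = airBox, groundTruth = gt)
}

#' Specification for a synthetic beat-by-beat series
#'
#' Defaults emulate a 10-min resting recording in a hypertensive adult:
#' mean RRI 1 s, SBP around 140 mm Hg, LF modulation at 0.1 Hz and HF
#' (respiratory) modulation at 0.25 Hz, with 2% ectopic and 2% pressure
#' dropout artifacts.
#'
#' @param duration recording length (s).
#' @param meanRri mean interbeat interval (s).
#' @param lfFreq,hfFreq modulation frequencies (Hz).
#' @param lfAmpRri,hfAmpRri RRI modulation amplitudes (s).
#' @param meanSbp,meanDbp mean pressures (mm Hg).
#' @param lfAmpSbp SBP modulation amplitude (mm Hg).
#' @param ectopicRate,dropoutRate artifact fractions of beats; the realised
#'   count is \code{round(rate * nBeats)}, so rates map to exact counts.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{BeatSeriesSpec}.
#' @export
beatSeriesSpec <- function(duration = 600, meanRri = 1.0,
                           lfFreq = 0.10, hfFreq = 0.25,
                           lfAmpRri = 0.03, hfAmpRri = 0.02,
                           meanSbp = 140, meanDbp = 85, lfAmpSbp = 3,
                           ectopicRate = 0.02, dropoutRate = 0.02, seed = 1L) {
  new("BeatSeriesSpec", duration = duration, meanRri = meanRri,
      lfFreq = lfFreq, hfFreq = hfFreq, lfAmpRri = lfAmpRri,
      hfAmpRri = hfAmpRri, meanSbp = meanSbp, meanDbp = meanDbp,
      lfAmpSbp = lfAmpSbp, ectopicRate = ectopicRate,
      dropoutRate = dropoutRate, seed = as.integer(seed))
}

#' Generate a synthetic beat series with ground truth
#'
#' Beats are laid down iteratively: the interval ending at beat i is
#' \code{meanRri + lfAmpRri*sin(2*pi*lfFreq*t) + hfAmpRri*sin(2*pi*hfFreq*t)}
#' evaluated at the previous beat time; SBP is modulated analogously with
#' \code{lfAmpSbp}. Ectopic artifacts halve or double the interval at
#' \code{round(ectopicRate * n)} seeded positions (only after the 15th beat,
#' so every ectopic has the 10-interval history the relative cleaning rule
#' needs); dropouts blank the pressures at \code{round(dropoutRate * n)}
#' positions. Beat times are the cumulative sum of the final intervals, so
#' the series invariant RRI_i = t_i - t_{i-1} holds exactly.
#'
#' @param spec a \linkS4class{BeatSeriesSpec}.
#' @return list with \code{series} (\linkS4class{BeatSeries}) and
#'   \code{groundTruth}: modulation parameters plus \code{ectopicIdx},
#'   \code{ectopicType} ("halved"/"doubled") and \code{dropoutIdx}.
#' @export
generateBeatSeries <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    rri <- numeric(0)
    t <- 0
    repeat {
      r <- spec@meanRri + spec@lfAmpRri * sin(2 * pi * spec@lfFreq * t) +
        spec@hfAmpRri * sin(2 * pi * spec@hfFreq * t)
      if (t + r > spec@duration) break
      rri <- c(rri, r)
      t <- t + r
    }
    n <- length(rri)
    if (n < 1L) stop("duration too short for a single beat")
    nEct <- round(spec@ectopicRate * n)
    eligible <- seq_len(n)[seq_len(n) > 15L]
    if (nEct > length(eligible))
      stop("too many ectopic beats for the series length")
    ectopicIdx <- sort(sample(eligible, nEct))
    ectopicType <- sample(c("halved", "doubled"), nEct, replace = TRUE)
    rri[ectopicIdx] <- rri[ectopicIdx] *
      ifelse(ectopicType == "halved", 0.5, 2)
    time <- cumsum(rri)
    sbp <- spec@meanSbp + spec@lfAmpSbp * sin(2 * pi * spec@lfFreq * time)
    dbp <- rep(spec@meanDbp, n)
    bpValid <- rep(TRUE, n)
    nDrop <- round(spec@dropoutRate * n)
    dropoutIdx <- sort(sample(setdiff(seq_len(n), ectopicIdx), nDrop))
    sbp[dropoutIdx] <- NA_real_
    dbp[dropoutIdx] <- NA_real_
    bpValid[dropoutIdx] <- FALSE
    list(series = BeatSeries(time, sbp, dbp, rri, bpValid),
         groundTruth = list(lfFreq = spec@lfFreq, hfFreq = spec@hfFreq,
                            lfAmpRri = spec@lfAmpRri, hfAmpRri = spec@hfAmpRri,
                            lfAmpSbp = spec@lfAmpSbp,
                            ectopicIdx = ectopicIdx, ectopicType = ectopicType,
                            dropoutIdx = dropoutIdx))
  })
}

#' Generate a synthetic multifibre nerve signal with cardiac-locked bursts
#'
#' Additive model: DC offset + one Gaussian-envelope burst per heartbeat
#' (carrier within the 50 Hz -- Nyquist pass band) + white noise. The burst
#' component is recorded separately so per-beat ground-truth burst energy is
#' available to recovery tests.
#'
#' @param fs sampling frequency (Hz, >= 1000; recordings use 3 kHz).
#' @param beatTimes heartbeat times (s), strictly increasing.
#' @param burstAmp burst peak amplitude (a.u.); scalar or one per beat.
#' @param noiseSd white-noise s.d. (a.u.).
#' @param dcOffset constant offset (a.u.).
#' @param burstDelay burst latency after the beat (s).
#' @param burstWidth Gaussian envelope s.d. (s).
#' @param carrierHz burst carrier frequency (Hz).
#' @param duration total length (s); default covers the last beat + 0.5 s.
#' @param seed integer RNG seed.
#' @return list with \code{signal} (\linkS4class{NerveSignal}) and
#'   \code{groundTruth}: per-beat burst amplitude and energy (sum of squared
#'   burst samples / fs) over each beat interval.
#' @export
generateNerveSignal <- function(fs = 3000, beatTimes, burstAmp = 1,
                                noiseSd = 0.05, dcOffset = 0,
                                burstDelay = 0.05, burstWidth = 0.02,
                                carrierHz = 300, duration = NULL, seed = 1L) {
  stopifnot(fs >= 1000, length(beatTimes) >= 1, all(diff(beatTimes) > 0))
  if (is.null(duration)) duration <- max(beatTimes) + 0.5
  nSamp <- floor(duration * fs)
  tt <- (seq_len(nSamp) - 1) / fs
  amp <- rep_len(burstAmp, length(beatTimes))
  burst <- numeric(nSamp)
  for (b in seq_along(beatTimes)) {
    tb <- beatTimes[b] + burstDelay
    sel <- which(abs(tt - tb) < 5 * burstWidth)
    burst[sel] <- burst[sel] + amp[b] *
      exp(-0.5 * ((tt[sel] - tb) / burstWidth)^2) *
      sin(2 * pi * carrierHz * (tt[sel] - beatTimes[b]))
  }
  x <- withSeed(seed, {
    dcOffset + burst + if (noiseSd > 0) stats::rnorm(nSamp, 0, noiseSd) else 0
  })
  edges <- c(beatTimes, duration)
  energy <- vapply(seq_along(beatTimes), function(b) {
    sel <- tt >= edges[b] & tt < edges[b + 1]
    sum(burst[sel]^2) / fs
  }, numeric(1))
  list(signal = NerveSignal(x, rate = fs, beatTimes = beatTimes),
       groundTruth = list(burstAmp = amp, burstEnergy = energy))
}
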