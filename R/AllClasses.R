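#' @import methods
NULL

#' Volume3D: a 3D intensity grid with physical voxel spacing
#'
#' Carrier for fluorescence, MRI-mask and CT-like data. Axis order is
#' x (left--right), y (rostral--caudal), z (dorsal--ventral); physical
#' coordinates of voxel centres are \code{(index - 0.5) * spacing} with
#' 1-based indices, so outputs of downstream operations are always in
#' physical units (micrometres or millimetres, whichever the volume uses).
#'
#' @slot intensities 3D numeric array of non-negative intensities (a.u.).
#' @slot spacing numeric(3), physical size of one voxel per axis (> 0).
#' @slot axes character(3) axis labels, default \code{c("x","y","z")}.
#' @exportClass Volume3D
setClass("Volume3D",
  representation(intensities = "array", spacing = "numeric", axes = "character"),
  prototype(spacing = c(1, 1, 1), axes = c("x", "y", "z")),
  validity = function(object) {
    msg <- character()
    d <- dim(object@intensities)
    if (length(d) != 3L) msg <- c(msg, "intensities must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite numbers")
    if (!is.null(d) && any(d < 1L)) msg <- c(msg, "each axis must have length >= 1")
    if (length(object@axes) != 3L) msg <- c(msg, "axes must have length 3")
    if (length(msg)) msg else TRUE
  })

#' Construct a Volume3D
#'
#' @param intensities 3D numeric array.
#' @param spacing numeric(3), physical voxel size per axis.
#' @param axes character(3) axis labels.
#' @return A \linkS4class{Volume3D}.
#' @examples
#' v <- Volume3D(array(runif(8 * 8 * 4), c(8, 8, 4)), spacing = c(0.5, 0.5, 1))
#' spacing(v)
#' @export
Volume3D <- function(intensities, spacing = c(1, 1, 1), axes = c("x", "y", "z")) {
  new("Volume3D", intensities = intensities, spacing = as.numeric(spacing),
      axes = axes)
}

#' ClusterSet: labelled connected voxel components
#'
#' Result of connected-component segmentation of a \linkS4class{Volume3D}.
#' Label 0 is background; each surviving component keeps its voxel indices
#' (1-based, n x 3 integer matrix) and the original voxel intensities.
#'
#' @slot labels 3D integer array, 0 = background.
#' @slot clusters list; each element has \code{id}, \code{voxels} (n x 3
#'   integer matrix), \code{intensities} (numeric) and \code{size}.
#' @slot spacing numeric(3) carried over from the source volume.
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(labels = "array", clusters = "list", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be 3D")
    ids <- vapply(object@clusters, function(cl) cl$id, integer(1))
    if (anyDuplicated(ids)) msg <- c(msg, "cluster ids must be unique")
    sizes <- vapply(object@clusters, function(cl) cl$size, integer(1))
    if (length(sizes) && any(sizes < 1L)) msg <- c(msg, "cluster sizes must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Pore-size distribution: log-normal fit over cross-sectional areas
#'
#' Maximum-likelihood log-normal fit of pore (interstitial channel)
#' cross-sectional areas, summarised by the mode and the full width at
#' half maximum of the fitted density.
#'
#' @slot logMu,logSigma log-normal parameters (log of area units).
#' @slot mode most probable area, \code{exp(logMu - logSigma^2)}.
#' @slot fwhmLow,fwhmHigh areas at which the fitted density falls to half
#'   its modal value.
#' @slot n number of areas fitted.
#' @exportClass PoreSizeDistribution
setClass("PoreSizeDistribution",
  representation(logMu = "numeric", logSigma = "numeric", mode = "numeric",
                 fwhmLow = "numeric", fwhmHigh = "numeric", n = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@logSigma <= 0) msg <- c(msg, "logSigma must be > 0")
    if (!(object@fwhmLow < object@mode && object@mode < object@fwhmHigh))
      msg <- c(msg, "fwhmLow < mode < fwhmHigh must hold")
    if (length(msg)) msg else TRUE
  })

#' Centroidal line of a binary mask
#'
#' Per-slice centre-of-mass curve along a parameter axis, fitted by linear
#' least squares in one transverse coordinate and a 4-parameter sigmoid in
#' the other (with linear fallback when the sigmoid fit fails).
#'
#' @slot parameterAxis integer axis index (1 = x, 2 = y, 3 = z).
#' @slot param numeric physical coordinates along the parameter axis.
#' @slot centroids n x 2 matrix of raw per-slice centroids (transverse axes).
#' @slot fitted n x 2 matrix of fitted transverse coordinates.
#' @slot residuals n x 2 matrix of fit residuals.
#' @slot sigmoidPars numeric(4) \code{c(c, d, y0, s)} or NA when linear fallback.
#' @slot linearCoef numeric(2) intercept/slope of the linear transverse fit.
#' @slot fallbackCoef numeric(2) used when \code{linearFallback}.
#' @slot linearFallback logical, TRUE when the sigmoid fit did not converge.
#' @exportClass CenterLine
setClass("CenterLine",
  representation(parameterAxis = "integer", param = "numeric",
                 centroids = "matrix", fitted = "matrix", residuals = "matrix",
                 sigmoidPars = "numeric", linearCoef = "numeric",
                 fallbackCoef = "numeric", linearFallback = "logical"))

#' BeatSeries: beat-by-beat physiological samples
#'
#' @slot time beat times in seconds, strictly increasing.
#' @slot sbp,dbp per-beat systolic/diastolic pressure (mm Hg; NA = missing).
#' @slot rri per-beat interbeat interval (s).
#' @slot bpValid logical per-beat blood-pressure validity flag.
#' @exportClass BeatSeries
setClass("BeatSeries",
  representation(time = "numeric", sbp = "numeric", dbp = "numeric",
                 rri = "numeric", bpValid = "logical"),
  validity = function(object) {
    msg <- character()
    n <- length(object@time)
    if (any(diff(object@time) <= 0)) msg <- c(msg, "beat times must be strictly increasing")
    if (length(object@sbp) != n || length(object@dbp) != n ||
        length(object@rri) != n || length(object@bpValid) != n)
      msg <- c(msg, "all per-beat vectors must share the same length")
    if (length(msg)) msg else TRUE
  })

#' Construct a BeatSeries
#' @param time,sbp,dbp,rri,bpValid per-beat vectors; see class slots.
#' @return A \linkS4class{BeatSeries}.
#' @export
BeatSeries <- function(time, sbp, dbp, rri, bpValid = rep(TRUE, length(time))) {
  new("BeatSeries", time = as.numeric(time), sbp = as.numeric(sbp),
      dbp = as.numeric(dbp), rri = as.numeric(rri), bpValid = as.logical(bpValid))
}

#' SpectralSummary: band powers of a beat-indexed signal
#'
#' @slot signal name of the analysed signal ("sbp" or "rri").
#' @slot lfPower,hfPower band powers in (input units)^2.
#' @slot lfHfRatio LF/HF ratio (NA when HF power is 0).
#' @slot lfBand,hfBand band edges in Hz.
#' @slot segmentLength analysed segment length in seconds.
#' @exportClass SpectralSummary
setClass("SpectralSummary",
  representation(signal = "character", lfPower = "numeric", hfPower = "numeric",
                 lfHfRatio = "numeric", lfBand = "numeric", hfBand = "numeric",
                 segmentLength = "numeric"),
  validity = function(object) {
    if (object@lfPower < 0 || object@hfPower < 0) "band powers must be >= 0" else TRUE
  })

#' CleaningReport: itemised record of RRI artifact removal
#'
#' @slot nInput number of input intervals.
#' @slot removed data.frame with columns index, value, reason
#'   ("absolute" or "relative").
#' @slot removalFraction total removed / nInput.
#' @exportClass CleaningReport
setClass("CleaningReport",
  representation(nInput = "integer", removed = "data.frame",
                 removalFraction = "numeric"))

#' TracerSpread: per-axis extent of a segmented tracer cluster
#'
#' @slot extents named numeric(3), axis-aligned extents in the volume's
#'   spatial units (0 for an empty cluster).
#' @slot voxelCount voxels in the tracer cluster.
#' @slot airIntensity mean air-reference intensity used for thresholding.
#' @exportClass TracerSpread
setClass("TracerSpread",
  representation(extents = "numeric", voxelCount = "integer",
                 airIntensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@extents < 0)) msg <- c(msg, "extents must be >= 0")
    if ((object@voxelCount == 0L) != all(object@extents == 0))
      msg <- c(msg, "extent is 0 iff the cluster is empty")
    if (length(msg)) msg else TRUE
  })

#' VelocityEstimate: interstitial flow velocity from tracer-spread fold change
#'
#' @slot baselineU baseline flow speed (um/s).
#' @slot foldRange numeric(2) dimensionless fold range, low <= high.
#' @slot uRange numeric(2) \code{baselineU * foldRange} (um/s).
#' @exportClass VelocityEstimate
setClass("VelocityEstimate",
  representation(baselineU = "numeric", foldRange = "numeric", uRange = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@foldRange[1] > object@foldRange[2]) msg <- c(msg, "fold low > high")
    if (!isTRUE(all.equal(object@uRange, object@baselineU * object@foldRange)))
      msg <- c(msg, "uRange must equal baselineU * foldRange")
    if (length(msg)) msg else TRUE
  })

#' ShearStressEstimate: Darcy permeability and shear-stress envelope
#'
#' @slot kpRange numeric(2) Darcy permeability range attained (m^2).
#' @slot tauRange numeric(2) shear-stress envelope \code{c(min, max)} (Pa).
#' @slot minCorner,maxCorner named numeric vectors of the input-corner values
#'   attaining each extreme.
#' @slot config list of input ranges used (provenance record).
#' @exportClass ShearStressEstimate
setClass("ShearStressEstimate",
  representation(kpRange = "numeric", tauRange = "numeric",
                 minCorner = "numeric", maxCorner = "numeric", config = "list"),
  validity = function(object) {
    msg <- character()
    if (any(object@kpRange <= 0)) msg <- c(msg, "kp must be > 0")
    if (any(object@tauRange <= 0)) msg <- c(msg, "tau must be > 0")
    if (object@tauRange[1] > object@tauRange[2]) msg <- c(msg, "tau min > max")
    if (length(msg)) msg else TRUE
  })

#' NerveSignal: raw multifibre nerve recording with beat annotations
#'
#' @slot samples numeric vector of raw amplitudes (a.u.).
#' @slot rate sampling frequency in Hz (>= 1000; recordings are digitised
#'   at 3 kHz by default).
#' @slot beatTimes heartbeat times in seconds, strictly increasing.
#' @slot background post-euthanasia integrated level (a.u.), subtracted as
#'   noise floor downstream.
#' @exportClass NerveSignal
setClass("NerveSignal",
  representation(samples = "numeric", rate = "numeric", beatTimes = "numeric",
                 background = "numeric"),
  prototype(background = 0),
  validity = function(object) {
    msg <- character()
    if (object@rate <= 0) msg <- c(msg, "rate must be positive")
    if (any(diff(object@beatTimes) <= 0))
      msg <- c(msg, "beat times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Construct a NerveSignal
#' @param samples,rate,beatTimes,background see \linkS4class{NerveSignal}.
#' @return A \linkS4class{NerveSignal}.
#' @export
NerveSignal <- function(samples, rate, beatTimes = numeric(), background = 0) {
  new("NerveSignal", samples = as.numeric(samples), rate = as.numeric(rate),
      beatTimes = as.numeric(beatTimes), background = as.numeric(background))
}

#' PoreVolumeSpec: parameters of the synthetic interstitial-channel volume
#'
#' Describes a volume of straight tube-like bright channels with log-normal
#' cross-sectional areas and a preferred orientation, embedded in noisy
#' background; the simulated counterpart of a multiphoton fluorescence stack
#' of brain interstitial space.
#'
#' @slot shape integer(3) voxel counts per axis.
#' @slot spacing numeric(3) um per voxel.
#' @slot nChannels number of channels to place.
#' @slot logMu,logSigma log-normal parameters of cross-sectional area
#'   (log of um^2).
#' @slot orientationAxis unit vector of the preferred direction.
#' @slot orientationJitter s.d. (radians) of angular deviation from the axis.
#' @slot aspectRatio major/minor aspect of the elliptical cross-section.
#' @slot fgIntensity,bgIntensity,noiseSd intensities (a.u.).
#' @slot seed integer RNG seed.
#' @exportClass PoreVolumeSpec
setClass("PoreVolumeSpec",
  representation(shape = "integer", spacing = "numeric", nChannels = "integer",
                 logMu = "numeric", logSigma = "numeric",
                 orientationAxis = "numeric", orientationJitter = "numeric",
                 aspectRatio = "numeric", fgIntensity = "numeric",
                 bgIntensity = "numeric", noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@shape < 1L)) msg <- c(msg, "shape must be positive")
    if (object@logSigma <= 0) msg <- c(msg, "logSigma must be > 0")
    if (object@orientationJitter < 0 || object@orientationJitter >= pi / 2)
      msg <- c(msg, "orientationJitter must be in [0, pi/2)")
    if (object@fgIntensity <= object@bgIntensity)
      msg <- c(msg, "fgIntensity must exceed bgIntensity")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@aspectRatio < 1) msg <- c(msg, "aspectRatio must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' BeatSeriesSpec: parameters of the synthetic beat-by-beat series
#'
#' LF (~0.1 Hz) and HF (~0.25 Hz) sinusoidal modulation of RRI plus LF
#' modulation of SBP, with ectopic (halved/doubled RRI) and pressure-dropout
#' artifacts at seeded random beats.
#'
#' @slot duration recording length (s).
#' @slot meanRri mean interbeat interval (s).
#' @slot lfFreq,hfFreq modulation frequencies (Hz); LF must lie in
#'   [0.04, 0.15], HF in [0.15, 0.4].
#' @slot lfAmpRri,hfAmpRri RRI modulation amplitudes (s).
#' @slot meanSbp,meanDbp mean pressures (mm Hg), SBP > DBP.
#' @slot lfAmpSbp SBP modulation amplitude (mm Hg).
#' @slot ectopicRate,dropoutRate artifact fractions in [0, 1].
#' @slot seed integer RNG seed.
#' @exportClass BeatSeriesSpec
setClass("BeatSeriesSpec",
  representation(duration = "numeric", meanRri = "numeric",
                 lfFreq = "numeric", hfFreq = "numeric",
                 lfAmpRri = "numeric", hfAmpRri = "numeric",
                 meanSbp = "numeric", meanDbp = "numeric", lfAmpSbp = "numeric",
                 ectopicRate = "numeric", dropoutRate = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@lfFreq < 0.04 || object@lfFreq > 0.15)
      msg <- c(msg, "lfFreq must be in [0.04, 0.15] Hz")
    if (object@hfFreq < 0.15 || object@hfFreq > 0.4)
      msg <- c(msg, "hfFreq must be in [0.15, 0.4] Hz")
    if (object@meanSbp <= object@meanDbp) msg <- c(msg, "meanSbp must exceed meanDbp")
    if (object@ectopicRate < 0 || object@ectopicRate > 1 ||
        object@dropoutRate < 0 || object@dropoutRate > 1)
      msg <- c(msg, "artifact rates must be in [0, 1]")
    if (object@duration <= 0 || object@meanRri <= 0)
      msg <- c(msg, "duration and meanRri must be positive")
    if (length(msg)) msg else TRUE
  })
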