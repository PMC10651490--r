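#' @rdname Volume3D
#' @param object,x a \linkS4class{Volume3D} (or other object as documented).
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname Volume3D
#' @export
setMethod("intensities", "Volume3D", function(object) object@intensities)

#' @rdname Volume3D
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname Volume3D
#' @export
setMethod("spacing", "Volume3D", function(object) object@spacing)

#' @rdname ClusterSet-class
#' @export
setMethod("spacing", "ClusterSet", function(object) object@spacing)

#' @rdname Volume3D
#' @export
setMethod("dim", "Volume3D", function(x) dim(x@intensities))

setMethod("show", "Volume3D", function(object) {
  d <- dim(object)
  cat("Volume3D:", paste(d, collapse = " x "), "voxels\n")
  cat("  spacing:", paste(signif(object@spacing, 4), collapse = " x "),
      "per voxel (", paste(object@axes, collapse = ", "), ")\n")
  cat("  intensity range: [", signif(min(object@intensities), 4), ", ",
      signif(max(object@intensities), 4), "]\n", sep = "")
})

#' Number of clusters in a ClusterSet
#' @param object a \linkS4class{ClusterSet}.
#' @return integer count.
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname nClusters
#' @export
setMethod("nClusters", "ClusterSet", function(object) length(object@clusters))

#' Cluster sizes (voxel counts)
#' @param object a \linkS4class{ClusterSet}.
#' @return named integer vector of voxel counts, one per cluster.
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))

#' @rdname clusterSizes
#' @export
setMethod("clusterSizes", "ClusterSet", function(object) {
  sizes <- vapply(object@clusters, function(cl) cl$size, integer(1))
  names(sizes) <- vapply(object@clusters, function(cl) as.character(cl$id), character(1))
  sizes
})

#' Label array of a ClusterSet
#' @param object a \linkS4class{ClusterSet}.
#' @return 3D integer array; 0 marks background.
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))

#' @rdname labelArray
#' @export
setMethod("labelArray", "ClusterSet", function(object) object@labels)

#' List of per-cluster records
#' @param object a \linkS4class{ClusterSet}.
#' @return list of records with id, voxels, intensities, size.
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname clusters
#' @export
setMethod("clusters", "ClusterSet", function(object) object@clusters)

setMethod("show", "ClusterSet", function(object) {
  n <- nClusters(object)
  cat("ClusterSet:", n, "cluster(s) in a",
      paste(dim(object@labels), collapse = " x "), "grid\n")
  if (n > 0) {
    s <- clusterSizes(object)
    cat("  sizes: min", min(s), "/ median", stats::median(s), "/ max", max(s), "voxels\n")
  }
})

setMethod("show", "PoreSizeDistribution", function(object) {
  cat("PoreSizeDistribution (log-normal, n =", object@n, ")\n")
  cat("  logMu =", signif(object@logMu, 4), " logSigma =", signif(object@logSigma, 4), "\n")
  cat("  mode =", signif(object@mode, 4),
      " FWHM = [", signif(object@fwhmLow, 4), ",", signif(object@fwhmHigh, 4), "]\n")
})

setMethod("show", "BeatSeries", function(object) {
  cat("BeatSeries:", length(object@time), "beats over",
      signif(diff(range(object@time)), 5), "s\n")
  cat("  SBP mean", signif(mean(object@sbp, na.rm = TRUE), 4), "mm Hg; RRI mean",
      signif(mean(object@rri, na.rm = TRUE), 4), "s;",
      sum(!object@bpValid | is.na(object@sbp)), "invalid-BP beat(s)\n")
})

#' Number of beats in a BeatSeries
#' @param x a \linkS4class{BeatSeries}.
#' @export
setMethod("length", "BeatSeries", function(x) length(x@time))

#' Convert a BeatSeries to a data.frame
#'
#' Columns follow the interchange CSV schema: beat_time_s, sbp_mmhg,
#' dbp_mmhg, rri_s, bp_valid.
#' @param x a \linkS4class{BeatSeries}.
#' @param ... ignored.
#' @return data.frame with one row per beat.
#' @export
setMethod("as.data.frame", "BeatSeries", function(x, ...) {
  data.frame(beat_time_s = x@time, sbp_mmhg = x@sbp, dbp_mmhg = x@dbp,
             rri_s = x@rri, bp_valid = x@bpValid)
})

setMethod("show", "SpectralSummary", function(object) {
  cat("SpectralSummary [", object@signal, "] over ", object@segmentLength, " s\n", sep = "")
  cat("  LF [", paste(object@lfBand, collapse = "-"), " Hz] = ",
      signif(object@lfPower, 4), "  HF [", paste(object@hfBand, collapse = "-"),
      " Hz] = ", signif(object@hfPower, 4), "\n", sep = "")
  if (is.finite(object@lfHfRatio))
    cat("  LF/HF =", signif(object@lfHfRatio, 4), "\n")
})

setMethod("show", "CleaningReport", function(object) {
  cat("CleaningReport:", nrow(object@removed), "of", object@nInput,
      "interval(s) removed (", signif(100 * object@removalFraction, 3), "% )\n")
  if (nrow(object@removed)) {
    tab <- table(object@removed$reason)
    for (r in names(tab)) cat("  ", r, ":", tab[[r]], "\n")
  }
})

setMethod("show", "TracerSpread", function(object) {
  cat("TracerSpread:", object@voxelCount, "voxels; extents (x,y,z) = (",
      paste(signif(object@extents, 4), collapse = ", "), ")\n")
  cat("  air reference:", signif(object@airIntensity, 5), "a.u.\n")
})

setMethod("show", "VelocityEstimate", function(object) {
  cat("VelocityEstimate: u = [", paste(signif(object@uRange, 4), collapse = ", "),
      "] um/s (baseline ", object@baselineU, " x fold [",
      paste(signif(object@foldRange, 4), collapse = ", "), "])\n", sep = "")
})

setMethod("show", "ShearStressEstimate", function(object) {
  cat("ShearStressEstimate\n")
  cat("  tau = [", signif(object@tauRange[1], 3), ",", signif(object@tauRange[2], 3), "] Pa\n")
  cat("  Kp  = [", signif(object@kpRange[1], 3), ",", signif(object@kpRange[2], 3), "] m^2\n")
})

setMethod("show", "NerveSignal", function(object) {
  cat("NerveSignal:", length(object@samples), "samples at", object@rate, "Hz (",
      signif(length(object@samples) / object@rate, 4), "s ),",
      length(object@beatTimes), "annotated beat(s)\n")
})

#' Shear-stress envelope accessor
#' @param object a \linkS4class{ShearStressEstimate}.
#' @return numeric(2) \code{c(min, max)} in Pa.
#' @export
setGeneric("tauRange", function(object) standardGeneric("tauRange"))

#' @rdname tauRange
#' @export
setMethod("tauRange", "ShearStressEstimate", function(object) object@tauRange)

#' Darcy-permeability range accessor
#' @param object a \linkS4class{ShearStressEstimate}.
#' @return numeric(2) in m^2.
#' @export
setGeneric("kpRange", function(object) standardGeneric("kpRange"))

#' @rdname kpRange
#' @export
setMethod("kpRange", "ShearStressEstimate", function(object) object@kpRange)

#' Per-axis extents of a TracerSpread
#' @param object a \linkS4class{TracerSpread}.
#' @return named numeric(3).
#' @export
setGeneric("extents", function(object) standardGeneric("extents"))

#' @rdname extents
#' @export
setMethod("extents", "TracerSpread", function(object) object@extents)
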