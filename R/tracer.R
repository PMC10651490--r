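# Tracer (contrast-agent) spread quantification and flow-velocity estimation.

#' Segment a tracer cluster against an air reference
#'
#' The threshold is \code{ratio} times the mean intensity over the air ROI;
#' voxels at or above the threshold (inclusive: a voxel at exactly 1.02 x the
#' air mean belongs to the cluster) form the foreground, connected components
#' are labelled, and the largest component is returned as the tracer cluster
#' (a single bolus; smaller super-threshold speckle is suppressed).
#'
#' @param vol a \linkS4class{Volume3D} CT-like volume.
#' @param airRoi 2 x 3 matrix of inclusive index bounds (rows from/to) of an
#'   air region, disjoint from the expected tracer region.
#' @param ratio threshold multiple of the air mean (default 1.02).
#' @param connectivity component connectivity, 26 (default) or 6.
#' @return A \linkS4class{ClusterSet} with at most one cluster; empty (with a
#'   warning) when nothing exceeds the threshold. The air mean is attached as
#'   attribute \code{airIntensity} and the threshold as \code{threshold}.
#' @export
segmentTracer <- function(vol, airRoi, ratio = 1.02, connectivity = 26) {
  stopifnot(is(vol, "Volume3D"), is.matrix(airRoi), nrow(airRoi) == 2, ncol(airRoi) == 3)
  x <- intensities(vol)
  air <- x[airRoi[1, 1]:airRoi[2, 1], airRoi[1, 2]:airRoi[2, 2],
           airRoi[1, 3]:airRoi[2, 3]]
  airMean <- mean(air)
  thr <- ratio * airMean
  fg <- x >= thr
  if (!any(fg)) {
    warning("no voxel reaches ", ratio, " x the air mean; empty tracer cluster")
    cs <- new("ClusterSet", labels = array(0L, dim(x)), clusters = list(),
              spacing = spacing(vol))
  } else {
    lab <- labelComponents(fg, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keepId <- which.max(sizes)
    lab[lab != keepId] <- 0L
    lab[lab == keepId] <- 1L
    cs <- clusterSetFromLabels(lab, x, spacing(vol))
  }
  attr(cs, "airIntensity") <- airMean
  attr(cs, "threshold") <- thr
  cs
}

#' Axis-aligned spread of a tracer cluster
#'
#' The extent along an axis is \code{(max index - min index + 1) * spacing},
#' i.e. the length of the cluster's bounding box on that axis; 0 for an empty
#' cluster.
#'
#' @param clusterSet a \linkS4class{ClusterSet} from \code{\link{segmentTracer}}.
#' @param axis axis index 1--3, or NULL (default) for all three.
#' @return numeric extent(s) in the volume's spatial units, named x/y/z when
#'   all axes are returned.
#' @export
axisSpread <- function(clusterSet, axis = NULL) {
  stopifnot(is(clusterSet, "ClusterSet"))
  one <- function(ax) {
    if (nClusters(clusterSet) == 0L) return(0)
    idx <- unlist(lapply(clusterSet@clusters, function(cl) cl$voxels[, ax]))
    (max(idx) - min(idx) + 1) * clusterSet@spacing[ax]
  }
  if (is.null(axis)) {
    out <- vapply(1:3, one, numeric(1))
    names(out) <- c("x", "y", "z")
    out
  } else one(as.integer(axis))
}

#' Summarise a segmented tracer cluster as a TracerSpread
#'
#' @param clusterSet output of \code{\link{segmentTracer}}.
#' @return A \linkS4class{TracerSpread} with per-axis extents, voxel count
#'   and the air reference intensity.
#' @export
tracerSpread <- function(clusterSet) {
  air <- attr(clusterSet, "airIntensity")
  new("TracerSpread", extents = axisSpread(clusterSet),
      voxelCount = as.integer(sum(clusterSizes(clusterSet))),
      airIntensity = if (is.null(air)) NA_real_ else air)
}

#' Per-axis fold change of tracer spread between two scans
#'
#' Elementwise post/pre extent ratio, quantifying how much an intervention
#' between two serial scans enhanced the tracer spread along each axis.
#'
#' @param pre,post \linkS4class{TracerSpread} objects from the first and
#'   second scan.
#' @return named numeric(3) fold change per axis.
#' @export
spreadFoldChange <- function(pre, post) {
  stopifnot(is(pre, "TracerSpread"), is(post, "TracerSpread"))
  if (any(extents(pre) <= 0))
    stop("pre-scan extents must be positive to form a fold change")
  extents(post) / extents(pre)
}

#' Interstitial flow velocity from a spread fold range
#'
#' Scales a baseline interstitial flow speed by the observed enhancement
#' range. Head-motion-enhanced spread of two to three times the sedentary
#' baseline of 0.2 um/s gives the working estimate u = 0.4--0.6 um/s.
#'
#' @param baselineU baseline flow speed (um/s); 0.2 um/s is the reported
#'   sedentary-brain value.
#' @param foldRange numeric(2) c(low, high) dimensionless enhancement.
#' @return A \linkS4class{VelocityEstimate}.
#' @examples
#' estimateFlowVelocity(0.2, c(2, 3))  # u = [0.4, 0.6] um/s
#' @export
estimateFlowVelocity <- function(baselineU = 0.2, foldRange = c(2, 3)) {
  stopifnot(baselineU > 0, length(foldRange) == 2, foldRange[1] > 0,
            foldRange[1] <= foldRange[2])
  new("VelocityEstimate", baselineU = baselineU,
      foldRange = as.numeric(foldRange),
      uRange = baselineU * as.numeric(foldRange))
}
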