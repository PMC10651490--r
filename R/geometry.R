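# Interstitial-space geometry: preprocessing, cluster extraction, ellipse
# fitting, pore-size statistics and centroidal-line orientation.

# Linear interpolation of `arr` along its first axis at fractional 1-based
# indices `f` (clamped to the valid range).
interpFirstAxis <- function(arr, f) {
  n <- dim(arr)[1]
  f <- pmin(pmax(f, 1), n)
  i0 <- pmin(floor(f), n - ifelse(n > 1, 1, 0))
  if (n == 1) i0 <- rep(1, length(f))
  i1 <- pmin(i0 + 1, n)
  w <- f - i0
  arr0 <- arr[i0, , , drop = FALSE]
  arr1 <- arr[i1, , , drop = FALSE]
  arr0 * (1 - w) + arr1 * w   # recycling runs along axis 1
}

# Edge-aware separable box filter along the first axis (window `w`, odd);
# sums are divided by the in-volume window size so constants are preserved.
boxFirstAxis <- function(arr, w) {
  d <- dim(arr)
  h <- (w - 1L) %/% 2L
  m <- matrix(arr, d[1], d[2] * d[3])
  cs <- apply(m, 2, cumsum)
  if (d[1] == 1L) cs <- matrix(cs, 1L)
  cs0 <- rbind(0, cs)
  i <- seq_len(d[1])
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, d[1])
  out <- (cs0[hi + 1L, , drop = FALSE] - cs0[lo, , drop = FALSE]) / (hi - lo + 1L)
  array(out, d)
}

#' Resample a volume to an isotropic grid and smooth it
#'
#' Resamples by trilinear interpolation to \code{targetVoxel} spacing on every
#' axis (the new axis length is \code{round(extent / targetVoxel)}), then
#' applies a uniform box filter of the given odd width. The imaging analysis
#' works at 0.2072 um isotropic voxels smoothed over 5 voxels (about 1 um).
#'
#' @param vol a \linkS4class{Volume3D}.
#' @param targetVoxel target isotropic voxel size (same units as spacing).
#' @param smoothWidthVoxels odd box-filter width in voxels (1 = no smoothing).
#' @return A resampled, smoothed \linkS4class{Volume3D} with isotropic spacing.
#' @examples
#' v <- Volume3D(array(1, c(20, 20, 20)), spacing = rep(1.036, 3))
#' dim(preprocessVolume(v, 0.2072, 5))  # 100 x 100 x 100
#' @export
preprocessVolume <- function(vol, targetVoxel = 0.2072, smoothWidthVoxels = 5L) {
  stopifnot(is(vol, "Volume3D"), targetVoxel > 0,
            smoothWidthVoxels >= 1, smoothWidthVoxels %% 2 == 1)
  d <- dim(vol)
  extent <- d * spacing(vol)
  newN <- round(extent / targetVoxel)
  if (any(newN < 1))
    stop("targetVoxel exceeds the volume extent on at least one axis")
  arr <- intensities(vol)
  for (ax in 1:3) {
    if (!(newN[ax] == d[ax] && isTRUE(all.equal(spacing(vol)[ax], targetVoxel)))) {
      coords <- (seq_len(newN[ax]) - 0.5) * targetVoxel
      f <- coords / spacing(vol)[ax] + 0.5
      arr <- withAxisFirst(arr, ax, function(a) interpFirstAxis(a, f))
    }
  }
  if (smoothWidthVoxels > 1L)
    for (ax in 1:3)
      arr <- withAxisFirst(arr, ax, function(a) boxFirstAxis(a, smoothWidthVoxels))
  Volume3D(arr, spacing = rep(targetVoxel, 3), axes = vol@axes)
}

#' Extract interstitial-space clusters from a fluorescence volume
#'
#' Implements the top-quantile extraction rule: (1) voxels strictly above the
#' \code{1 - topFraction} sample quantile of intensity form the foreground
#' (the interstitial space occupies about 20\% of brain tissue, hence the
#' default top 20\%); (2) connected components are labelled (26-connectivity
#' by default); (3) any component larger than \code{hugeSize} voxels has its
#' lowest-intensity \code{trimFraction} of voxels removed (exactly
#' \code{ceiling(trimFraction * size)}, ties broken by voxel index order) and
#' components are re-labelled; (4) components smaller than \code{minSize}
#' voxels are deleted.
#'
#' An all-constant volume yields an empty foreground (strict inequality) and
#' an empty ClusterSet, not an error.
#'
#' @param vol a \linkS4class{Volume3D}.
#' @param topFraction fraction of voxels extracted as foreground (0, 1).
#' @param hugeSize component size (voxels) above which trimming applies.
#' @param trimFraction fraction of a huge component's lowest-intensity voxels
#'   to remove.
#' @param minSize minimum surviving component size in voxels; components with
#'   fewer than \code{minSize} voxels are deleted.
#' @param connectivity 26 (default) or 6.
#' @return A \linkS4class{ClusterSet}.
#' @export
extractInterstitialClusters <- function(vol, topFraction = 0.20,
                                        hugeSize = 5000L, trimFraction = 0.50,
                                        minSize = 50L, connectivity = 26) {
  stopifnot(is(vol, "Volume3D"), topFraction > 0, topFraction < 1)
  x <- intensities(vol)
  thr <- stats::quantile(x, 1 - topFraction, names = FALSE, type = 7)
  fg <- x > thr
  if (!any(fg))
    return(new("ClusterSet", labels = array(0L, dim(x)), clusters = list(),
               spacing = spacing(vol)))
  lab <- labelComponents(fg, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  for (id in which(sizes > hugeSize)) {
    lin <- which(lab == id)
    nDrop <- ceiling(trimFraction * length(lin))
    ord <- order(x[lin], lin)      # lowest intensity first, ties by index
    fg[lin[ord[seq_len(nDrop)]]] <- FALSE
  }
  lab <- labelComponents(fg, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minSize)
  lab[!(lab %in% keep)] <- 0L
  # compact ids in first-occurrence order
  if (length(keep)) {
    remap <- integer(max(lab))
    remap[sort(unique(lab[lab > 0L]))] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  clusterSetFromLabels(lab, x, spacing(vol))
}

#' Fit second-moment ellipses to cluster footprints in a plane
#'
#' Selects the analysis slice along the stack axis (by default the slice with
#' the highest mean intensity of the supplied volume, the conventional choice
#' for a fluorescence stack), takes each cluster's in-plane footprint there,
#' and returns the second-central-moment (covariance) ellipse: axis lengths
#' are \code{4 * sqrt(eigenvalue)} and the major-axis angle lies in
#' \code{[-pi/2, pi/2)} measured from the first in-plane axis. A uniform
#' voxel-extent term (spacing^2 / 12) is added to the diagonal moments so
#' one-voxel-wide footprints have a finite minor axis. Footprints with fewer
#' than \code{minVoxels} voxels are skipped with a recorded reason.
#'
#' @param clusterSet a \linkS4class{ClusterSet}.
#' @param vol the \linkS4class{Volume3D} the clusters came from (used for
#'   slice selection); may be NULL when \code{slice} is given.
#' @param stackAxis axis index treated as the stack direction (default 3).
#' @param slice optional explicit slice index overriding the selection rule.
#' @param minVoxels minimum footprint size to fit (default 3).
#' @return data.frame with columns clusterId, centroid1, centroid2 (physical,
#'   in-plane), major, minor (physical lengths), angle (radians), nVoxels.
#'   Attribute \code{skipped} lists skipped clusters and reasons; attributes
#'   \code{planeAxes}, \code{stackAxis}, \code{slice} record the geometry.
#' @export
fitClusterEllipses <- function(clusterSet, vol = NULL, stackAxis = 3L,
                               slice = NULL, minVoxels = 3L) {
  stopifnot(is(clusterSet, "ClusterSet"))
  planeAxes <- setdiff(1:3, stackAxis)
  if (is.null(slice)) {
    if (is.null(vol))
      stop("either `vol` (for the max-mean-fluorescence rule) or `slice` is required")
    sliceMeans <- apply(intensities(vol), stackAxis, mean)
    slice <- which.max(sliceMeans)
  }
  sp <- clusterSet@spacing[planeAxes]
  rows <- list(); skipped <- list()
  for (cl in clusterSet@clusters) {
    inPlane <- cl$voxels[cl$voxels[, stackAxis] == slice, , drop = FALSE]
    if (nrow(inPlane) < minVoxels) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        clusterId = cl$id, nVoxels = nrow(inPlane),
        reason = sprintf("footprint of %d voxel(s) < %d in slice %d",
                         nrow(inPlane), minVoxels, slice))
      next
    }
    p <- sweep(inPlane[, planeAxes, drop = FALSE] - 0.5, 2, sp, `*`)
    ctr <- colMeans(p)
    pc <- sweep(p, 2, ctr)
    mu20 <- mean(pc[, 1]^2) + sp[1]^2 / 12
    mu02 <- mean(pc[, 2]^2) + sp[2]^2 / 12
    mu11 <- mean(pc[, 1] * pc[, 2])
    tr <- mu20 + mu02
    disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    lam1 <- tr / 2 + disc
    lam2 <- tr / 2 - disc
    ang <- if (mu11 == 0 && mu20 == mu02) 0 else 0.5 * atan2(2 * mu11, mu20 - mu02)
    if (ang >= pi / 2) ang <- ang - pi
    if (ang < -pi / 2) ang <- ang + pi
    rows[[length(rows) + 1L]] <- data.frame(
      clusterId = cl$id, centroid1 = ctr[1], centroid2 = ctr[2],
      major = 4 * sqrt(lam1), minor = 4 * sqrt(max(lam2, 0)),
      angle = ang, nVoxels = nrow(inPlane))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clusterId = integer(0), centroid1 = numeric(0),
               centroid2 = numeric(0), major = numeric(0), minor = numeric(0),
               angle = numeric(0), nVoxels = integer(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "planeAxes") <- planeAxes
  attr(out, "stackAxis") <- stackAxis
  attr(out, "slice") <- slice
  out
}

#' Per-cluster cross-sectional areas from in-plane footprints
#'
#' For each cluster, counts footprint voxels on every slice along the stack
#' axis where the cluster is present and converts counts to physical areas
#' with the in-plane voxel area. The default per-cluster summary (mean over
#' slices) gives one cross-sectional area per channel.
#'
#' @param clusterSet a \linkS4class{ClusterSet}.
#' @param stackAxis stack axis index (slices are taken perpendicular to it).
#' @param perSlice if TRUE return every (cluster, slice) footprint area.
#' @return numeric vector of areas (per cluster, or per cluster-slice).
#' @export
clusterCrossSections <- function(clusterSet, stackAxis = 3L, perSlice = FALSE) {
  planeAxes <- setdiff(1:3, stackAxis)
  va <- prod(clusterSet@spacing[planeAxes])
  res <- lapply(clusterSet@clusters, function(cl) {
    counts <- table(cl$voxels[, stackAxis])
    as.numeric(counts) * va
  })
  if (perSlice) unlist(res) else vapply(res, mean, numeric(1))
}

#' Fit a log-normal pore-size distribution with mode and FWHM
#'
#' Maximum-likelihood log-normal fit to cross-sectional areas (closed form:
#' mean and s.d. of log areas, ML variant with divisor n). The mode is
#' \code{exp(mu - sigma^2)}; the full width at half maximum of the fitted
#' density has the closed form \code{mode * exp(+/- sigma * sqrt(2 log 2))}.
#'
#' @param areas positive cross-sectional areas, or voxel counts when
#'   \code{voxelArea} is supplied.
#' @param voxelArea multiplier converting counts to areas (default 1).
#' @return A \linkS4class{PoreSizeDistribution}.
#' @examples
#' set.seed(1)
#' estimateCrossSectionDistribution(rlnorm(1000, -3, 0.8))
#' @export
estimateCrossSectionDistribution <- function(areas, voxelArea = 1) {
  areas <- as.numeric(areas) * voxelArea
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("all areas must be positive and finite")
  n <- length(areas)
  if (n < 10L) stop("at least 10 areas are required, got ", n)
  la <- log(areas)
  mu <- mean(la)
  sig <- sqrt(mean((la - mu)^2))
  if (sig < 1e-10)
    stop("degenerate fit: all areas are (numerically) equal")
  half <- sig * sqrt(2 * log(2))
  mode <- exp(mu - sig^2)
  new("PoreSizeDistribution", logMu = mu, logSigma = sig, mode = mode,
      fwhmLow = mode * exp(-half), fwhmHigh = mode * exp(half), n = n)
}

# 4-parameter sigmoid used for the centroidal-line transverse fit.
sigmoidFun <- function(y, c, d, y0, s) c + d / (1 + exp(-(y - y0) / s))

#' Centroidal line of a binary brain mask
#'
#' Computes the unweighted centre of mass of every non-empty slice along the
#' parameter axis and fits the two transverse centroid coordinates against
#' the parameter coordinate: the first transverse axis by linear least
#' squares, the second by a 4-parameter sigmoid
#' \code{c + d / (1 + exp(-(y - y0)/s))} (Levenberg--Marquardt). When the
#' sigmoid fit does not converge the second axis falls back to a linear fit
#' and the result is flagged. With the default parameter axis y, x(y) is
#' linear and z(y) sigmoidal, matching the dorsal-ventral bend of the lower
#' brainstem along its longest (rostral--caudal) diameter.
#'
#' @param mask a \linkS4class{Volume3D} whose non-zero voxels form the mask.
#' @param parameterAxis axis name ("x", "y", "z") or index; default "y".
#' @return A \linkS4class{CenterLine}.
#' @export
computeCentroidalLine <- function(mask, parameterAxis = "y") {
  stopifnot(is(mask, "Volume3D"))
  ax <- if (is.character(parameterAxis))
    match(parameterAxis, mask@axes) else as.integer(parameterAxis)
  if (is.na(ax) || !(ax %in% 1:3)) stop("invalid parameter axis")
  tAxes <- setdiff(1:3, ax)
  m <- intensities(mask) != 0
  d <- dim(m)
  sp <- spacing(mask)
  slices <- which(apply(m, ax, any))
  if (length(slices) < 4L)
    stop("mask must be non-empty in at least 4 slices along the parameter axis")
  mp <- aperm(m, c(ax, tAxes))
  cent <- t(vapply(slices, function(j) {
    sub <- arrayInd(which(mp[j, , ]), d[tAxes])
    c(mean((sub[, 1] - 0.5) * sp[tAxes[1]]),
      mean((sub[, 2] - 0.5) * sp[tAxes[2]]))
  }, numeric(2)))
  y <- (slices - 0.5) * sp[ax]
  linFit <- stats::lm.fit(cbind(1, y), cent[, 1])
  fitted1 <- linFit$fitted.values
  t2 <- cent[, 2]
  sigPars <- rep(NA_real_, 4)
  fallback <- FALSE
  fbCoef <- c(NA_real_, NA_real_)
  start <- list(c = min(t2), d = max(t2) - min(t2),
                y0 = stats::median(y), s = diff(range(y)) / 10)
  fit2 <- tryCatch({
    f <- minpack.lm::nlsLM(t2 ~ sigmoidFun(y, c, d, y0, s), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    sigPars <- stats::coef(f)[c("c", "d", "y0", "s")]
    as.numeric(stats::fitted(f))
  }, error = function(e) NULL)
  if (is.null(fit2)) {
    fallback <- TRUE
    lf <- stats::lm.fit(cbind(1, y), t2)
    fbCoef <- lf$coefficients
    fit2 <- lf$fitted.values
    message("sigmoid fit did not converge; falling back to a linear fit")
  }
  fitted <- cbind(fitted1, fit2)
  new("CenterLine", parameterAxis = as.integer(ax), param = y,
      centroids = cent, fitted = fitted, residuals = cent - fitted,
      sigmoidPars = as.numeric(sigPars),
      linearCoef = as.numeric(linFit$coefficients),
      fallbackCoef = as.numeric(fbCoef), linearFallback = fallback)
}

# Unit tangent of a CenterLine at parameter coordinate `at`, as a 3-vector
# in original axis order.
lineTangent <- function(line, at) {
  slope1 <- line@linearCoef[2]
  slope2 <- if (line@linearFallback) {
    line@fallbackCoef[2]
  } else {
    p <- line@sigmoidPars
    e <- exp(-(at - p[3]) / p[4])
    p[2] / p[4] * e / (1 + e)^2
  }
  tAxes <- setdiff(1:3, line@parameterAxis)
  v <- numeric(3)
  v[line@parameterAxis] <- 1
  v[tAxes[1]] <- slope1
  v[tAxes[2]] <- slope2
  v / sqrt(sum(v^2))
}

#' Orientation of cluster major axes relative to the centroidal line
#'
#' For every fitted ellipse, computes the acute angle between its major axis
#' and the centroidal-line direction projected into the ellipse plane, and
#' summarises the angles with axial circular statistics (doubled-angle
#' resultant). Elongation ratios (major/minor) are reported alongside.
#'
#' @param ellipses data.frame from \code{\link{fitClusterEllipses}} (its
#'   \code{planeAxes} attribute identifies the plane).
#' @param line a \linkS4class{CenterLine}, or a numeric(2) in-plane direction
#'   vector, or a single in-plane angle in radians.
#' @return list with \code{angles} (acute, [0, pi/2]), \code{signedAngles}
#'   ((-pi/2, pi/2]), \code{circularMean}, \code{resultantLength},
#'   \code{circularSd} (radians), and \code{elongation}.
#' @export
orientationSummary <- function(ellipses, line) {
  if (nrow(ellipses) < 1L) stop("at least one ellipse is required")
  planeAxes <- attr(ellipses, "planeAxes")
  if (is(line, "CenterLine")) {
    stackAxis <- attr(ellipses, "stackAxis")
    sliceCoord <- if (!is.null(attr(ellipses, "slice")))
      stats::median(line@param) else stats::median(line@param)
    tang <- lineTangent(line, sliceCoord)
    v <- tang[planeAxes]
    if (sqrt(sum(v^2)) < 1e-8)
      stop("centroidal line is perpendicular to the ellipse plane")
    refAngle <- atan2(v[2], v[1])
  } else if (length(line) == 2L) {
    refAngle <- atan2(line[2], line[1])
  } else {
    refAngle <- as.numeric(line)
  }
  delta <- (ellipses$angle - refAngle) %% pi
  signed <- ifelse(delta > pi / 2, delta - pi, delta)
  acute <- abs(signed)
  z <- exp(2i * signed)
  R <- Mod(mean(z))
  circMean <- Arg(mean(z)) / 2
  circSd <- if (R > 0) sqrt(-2 * log(R)) / 2 else Inf
  list(angles = acute, signedAngles = signed, circularMean = circMean,
       resultantLength = R, circularSd = circSd,
       elongation = ellipses$major / pmax(ellipses$minor, .Machine$double.eps))
}
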