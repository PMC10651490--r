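# File interchange: volumes as multi-page TIFF or NIfTI-1, beat series and
# cuff logs as CSV, fits as JSON.

#' Read a 3D volume from TIFF or NIfTI
#'
#' TIFF stacks are read page-by-page into the (x, y, z) array convention
#' used throughout; NIfTI files carry their voxel spacing in the header,
#' for TIFF it must be supplied.
#'
#' @param path file ending in .tif/.tiff or .nii (.nii.gz).
#' @param spacing numeric(3) voxel size, required for TIFF.
#' @return A \linkS4class{Volume3D}.
#' @export
readVolume <- function(path, spacing = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.null(spacing)) stop("spacing must be supplied for TIFF input")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
    Volume3D(arr, spacing = spacing)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    if (is.null(spacing)) spacing <- sp
    Volume3D(array(as.numeric(img), dim(img)[1:3]), spacing = spacing)
  } else stop("unsupported volume format: ", path)
}

#' Write a 3D volume to TIFF or NIfTI
#'
#' TIFF output is a 32-bit float multi-page stack (one page per z slice);
#' NIfTI output records the voxel spacing in the header.
#'
#' @param vol a \linkS4class{Volume3D}.
#' @param path destination ending in .tif/.tiff or .nii/.nii.gz.
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume3D"))
  arr <- intensities(vol)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]))
    # 32-bit float pages; the [0,1]-range warning does not apply to floats
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing(vol)
    RNifti::writeNifti(img, path)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' Read a beat series from its interchange CSV
#'
#' Expected columns: beat_time_s, sbp_mmhg, dbp_mmhg, rri_s, bp_valid.
#'
#' @param path CSV file path.
#' @return A \linkS4class{BeatSeries}.
#' @export
readBeatSeries <- function(path) {
  d <- utils::read.csv(path)
  need <- c("beat_time_s", "sbp_mmhg", "dbp_mmhg", "rri_s", "bp_valid")
  if (!all(need %in% names(d)))
    stop("beat CSV must have columns ", paste(need, collapse = ", "))
  BeatSeries(d$beat_time_s, d$sbp_mmhg, d$dbp_mmhg, d$rri_s,
             as.logical(d$bp_valid))
}

#' Write a beat series to its interchange CSV
#' @param series a \linkS4class{BeatSeries}.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
writeBeatSeries <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write a pore-size distribution fit as JSON
#' @param fit a \linkS4class{PoreSizeDistribution}.
#' @param path destination JSON path.
#' @return the path, invisibly.
#' @export
writeDistributionFit <- function(fit, path) {
  jsonlite::write_json(list(logMu = fit@logMu, logSigma = fit@logSigma,
                            mode = fit@mode, fwhmLow = fit@fwhmLow,
                            fwhmHigh = fit@fwhmHigh, n = fit@n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
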