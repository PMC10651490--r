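# Human-study computations: MAP, cuff-log aggregation, RRI artifact
# rejection, segment validity rules and Hanning-windowed band power.

#' Mean arterial pressure
#'
#' \code{MAP = DBP + (SBP - DBP) / 3}, the standard cuff formula.
#'
#' @param sbp,dbp systolic and diastolic pressure (mm Hg), vectorised.
#' @return MAP in mm Hg.
#' @examples
#' computeMAP(120, 80)  # 93.33
#' @export
computeMAP <- function(sbp, dbp) {
  if (any(dbp <= 0) || any(sbp < dbp))
    stop("require sbp >= dbp > 0")
  dbp + (sbp - dbp) / 3
}

#' Value of the day from a same-morning measurement triplet
#'
#' The mean of exactly three consecutive morning measurements defines the
#' value of the day.
#'
#' @param x numeric vector of exactly 3 measurements.
#' @return their arithmetic mean.
#' @export
valueOfDay <- function(x) {
  if (length(x) != 3L || any(!is.finite(x)))
    stop("a value of the day requires exactly 3 finite measurements")
  mean(x)
}

#' Value of the week from daily values
#'
#' The mean of all values of the day recorded in a week, defined only when
#' at least 3 days were recorded; otherwise an explicit undefined result
#' (NA with attribute \code{undefined = TRUE}), not an error.
#'
#' @param days numeric vector of values of the day for one week.
#' @return mean, or NA flagged undefined when fewer than 3 days.
#' @export
valueOfWeek <- function(days) {
  days <- days[is.finite(days)]
  if (length(days) < 3L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  mean(days)
}

#' Per-day summaries of a cuff-measurement log
#'
#' @param log data.frame with columns date, slot (1--3), sbp, dbp, hr; each
#'   date must carry exactly 3 rows. Malformed rows raise an error naming the
#'   offending date.
#' @return data.frame with one row per date: sbp, dbp, hr and map (means of
#'   the triplet).
#' @export
cuffDailyValues <- function(log) {
  need <- c("date", "slot", "sbp", "dbp", "hr")
  if (!all(need %in% names(log)))
    stop("cuff log must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(log, log$date), function(d) {
    if (nrow(d) != 3L)
      stop("date ", d$date[1], " has ", nrow(d), " measurement(s), expected 3")
    if (any(!is.finite(d$sbp)) || any(!is.finite(d$dbp)) || any(!is.finite(d$hr)))
      stop("non-finite measurement on date ", d$date[1])
    data.frame(date = d$date[1], sbp = valueOfDay(d$sbp), dbp = valueOfDay(d$dbp),
               hr = valueOfDay(d$hr),
               map = computeMAP(valueOfDay(d$sbp), valueOfDay(d$dbp)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-pass RRI artifact rejection
#'
#' Pass 1 removes intervals below \code{absRange[1]} or above
#' \code{absRange[2]} seconds as erroneous. Pass 2 scans forward over the
#' survivors: an interval outside \code{relRange} times the mean of the 10
#' immediately preceding retained intervals is removed as unreliable; the
#' first 10 retained intervals are exempt (insufficient history). The order
#' of the passes matters and is fixed: absolute first, then relative.
#'
#' @param rri numeric vector of interbeat intervals (s).
#' @param absRange hard limits in seconds (default 0.5--1.5).
#' @param relRange multiples of the running 10-interval mean (default
#'   0.6--1.4).
#' @param history number of preceding retained intervals to average.
#' @return list with \code{cleaned} (retained values), \code{keptIdx}
#'   (their original indices) and \code{report}
#'   (\linkS4class{CleaningReport} itemising every removal).
#' @export
cleanRRI <- function(rri, absRange = c(0.5, 1.5), relRange = c(0.6, 1.4),
                     history = 10L) {
  if (length(rri) == 0L) stop("empty RRI series")
  removed <- data.frame(index = integer(0), value = numeric(0),
                        reason = character(0))
  bad1 <- which(rri < absRange[1] | rri > absRange[2])
  if (length(bad1))
    removed <- rbind(removed, data.frame(index = bad1, value = rri[bad1],
                                         reason = "absolute"))
  survIdx <- setdiff(seq_along(rri), bad1)
  retained <- numeric(0)
  keptIdx <- integer(0)
  for (i in survIdx) {
    v <- rri[i]
    if (length(retained) >= history) {
      m <- mean(retained[(length(retained) - history + 1L):length(retained)])
      if (v < relRange[1] * m || v > relRange[2] * m) {
        removed <- rbind(removed, data.frame(index = i, value = v,
                                             reason = "relative"))
        next
      }
    }
    retained <- c(retained, v)
    keptIdx <- c(keptIdx, i)
  }
  removed <- removed[order(removed$index), , drop = FALSE]
  rownames(removed) <- NULL
  rep <- new("CleaningReport", nInput = length(rri), removed = removed,
             removalFraction = nrow(removed) / length(rri))
  list(cleaned = retained, keptIdx = keptIdx, report = rep)
}

#' Validity verdict for the last recording window
#'
#' A beat's blood-pressure measurement is a failure when the pressure is
#' missing, flagged invalid, or SBP is below 50 mm Hg (SBP = 50 passes).
#' The blood-pressure modality fails when summed failed-beat time exceeds
#' \code{bpFailMax} of the window; the RRI modality fails when the two-pass
#' cleaning removes more than \code{rriRemovedMax} of the window's intervals.
#' Both rules are evaluated on the last \code{window} seconds.
#'
#' @param series a \linkS4class{BeatSeries} covering at least \code{window} s.
#' @param window evaluation window in seconds (default 300, the last 5 min).
#' @param bpFailMax maximum tolerated failure-time fraction (default 0.04).
#' @param rriRemovedMax maximum tolerated RRI removal fraction (default 0.10).
#' @param sbpFailBelow SBP failure threshold in mm Hg (default 50).
#' @return list with logical \code{bpValid}, \code{rriValid}, the measured
#'   \code{bpFailFraction} and \code{rriRemovedFraction}, and the RRI
#'   \code{report}.
#' @export
validateSegment <- function(series, window = 300, bpFailMax = 0.04,
                            rriRemovedMax = 0.10, sbpFailBelow = 50) {
  stopifnot(is(series, "BeatSeries"))
  tEnd <- max(series@time)
  if (tEnd - min(series@time) < window)
    stop("series must cover at least ", window, " seconds")
  sel <- series@time > tEnd - window
  failed <- !series@bpValid[sel] | is.na(series@sbp[sel]) |
    series@sbp[sel] < sbpFailBelow
  bpFailFraction <- sum(series@rri[sel][failed]) / window
  cl <- cleanRRI(series@rri[sel])
  list(bpValid = bpFailFraction <= bpFailMax,
       rriValid = cl$report@removalFraction <= rriRemovedMax,
       bpFailFraction = bpFailFraction,
       rriRemovedFraction = cl$report@removalFraction,
       report = cl$report)
}

#' Band power of a beat-indexed signal
#'
#' The beat series is interpolated (cubic spline) to a uniform grid at
#' \code{resampleHz} over the central \code{analysisWindow} seconds of the
#' last \code{lastWindow} seconds, demeaned, Hanning-windowed with power
#' compensation (division by the window's mean square), and the one-sided
#' periodogram is summed over \code{band}. Frequencies are assigned to a band
#' by \code{lower <= f < upper}, so adjacent bands sharing an edge never
#' double-count a bin. For a noiseless sinusoid of amplitude a inside the
#' band the result is a^2/2 up to windowing tolerance.
#'
#' @param time beat times (s).
#' @param values per-beat signal values; NA values (missing beats) are
#'   dropped and bridged by the interpolation.
#' @param band numeric(2) frequency band in Hz.
#' @param analysisWindow analysed segment length (s), default 256.
#' @param resampleHz uniform resampling rate (Hz), default 4 (the
#'   conventional tachogram rate, comfortably above twice the 0.4 Hz band
#'   edge).
#' @param lastWindow recording tail the segment is centred in (s).
#' @return band power in (input units)^2.
#' @export
bandPower <- function(time, values, band, analysisWindow = 256,
                      resampleHz = 4, lastWindow = 300) {
  keep <- is.finite(values)
  time <- time[keep]; values <- values[keep]
  tEnd <- max(time)
  segStart <- tEnd - lastWindow + (lastWindow - analysisWindow) / 2
  segEnd <- segStart + analysisWindow
  nSeg <- sum(time >= segStart & time <= segEnd)
  if (nSeg / analysisWindow < 2 * band[2])
    stop("too few beats in the analysis window to resolve ", band[2], " Hz")
  N <- round(analysisWindow * resampleHz)
  grid <- segStart + (seq_len(N) - 1) / resampleHz
  x <- stats::spline(time, values, xout = grid, method = "fmm")$y
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1) / (N - 1))
  X <- stats::fft(x * w)
  k <- seq_len(floor(N / 2))           # positive frequencies
  f <- k * resampleHz / N
  p <- 2 * Mod(X[k + 1])^2 / (N^2 * mean(w^2))
  sum(p[f >= band[1] & f < band[2]])
}

#' Spectral summary of a beat series (LF of SBP, LF/HF of RRI)
#'
#' Computes the low-frequency power of SBP variability (vascular sympathetic
#' index) and the LF and HF powers of RRI variability (sympatho-vagal
#' balance via their ratio) on the central 256 s of the last 5 min. SBP uses
#' valid-pressure beats only; RRI is cleaned with \code{\link{cleanRRI}}
#' before interpolation, which bridges the removed beats.
#'
#' @param series a \linkS4class{BeatSeries}.
#' @param lfBand,hfBand band edges in Hz.
#' @param analysisWindow,resampleHz,lastWindow see \code{\link{bandPower}}.
#' @return list with elements \code{sbp} and \code{rri}, each a
#'   \linkS4class{SpectralSummary}.
#' @export
spectralSummary <- function(series, lfBand = c(0.04, 0.15),
                            hfBand = c(0.15, 0.4), analysisWindow = 256,
                            resampleHz = 4, lastWindow = 300) {
  stopifnot(is(series, "BeatSeries"))
  okBp <- series@bpValid & is.finite(series@sbp)
  sbpLf <- bandPower(series@time[okBp], series@sbp[okBp], lfBand,
                     analysisWindow, resampleHz, lastWindow)
  sbpHf <- bandPower(series@time[okBp], series@sbp[okBp], hfBand,
                     analysisWindow, resampleHz, lastWindow)
  cl <- cleanRRI(series@rri)
  tKept <- series@time[cl$keptIdx]
  rriLf <- bandPower(tKept, cl$cleaned, lfBand, analysisWindow, resampleHz,
                     lastWindow)
  rriHf <- bandPower(tKept, cl$cleaned, hfBand, analysisWindow, resampleHz,
                     lastWindow)
  mk <- function(sig, lf, hf) new("SpectralSummary", signal = sig,
    lfPower = lf, hfPower = hf,
    lfHfRatio = if (hf > 0) lf / hf else NA_real_,
    lfBand = lfBand, hfBand = hfBand, segmentLength = analysisWindow)
  list(sbp = mk("sbp", sbpLf, sbpHf), rri = mk("rri", rriLf, rriHf))
}

#' Scale begin/end values to the mean of the begin period
#'
#' Implements the begin-mean normalisation used for group summaries: every
#' value is divided by the mean of the begin-period values, so the begin
#' group averages 1 by construction.
#'
#' @param begin,end numeric vectors of per-participant period means.
#' @return list with scaled \code{begin} and \code{end} and the
#'   \code{baselineMean} used.
#' @examples
#' normalizeToBaseline(c(2, 4), c(1.5, 3))
#' @export
normalizeToBaseline <- function(begin, end) {
  m <- mean(begin, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("begin-period mean must be positive to serve as the baseline")
  list(begin = begin / m, end = end / m, baselineMean = m)
}

#' Per-participant period mean over repeated sessions
#'
#' A participant's period value is the mean of their valid sessions, defined
#' only when at least \code{minSessions} are valid (the documented exception
#' of a single 3-session case is expressed by lowering \code{minSessions}).
#'
#' @param x numeric vector of per-session values (NA = invalid session).
#' @param minSessions minimum valid sessions required (default 4).
#' @return mean, or NA flagged with attribute \code{flagged = TRUE}.
#' @export
summarizeSessions <- function(x, minSessions = 4L) {
  v <- x[is.finite(x)]
  if (length(v) < minSessions) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  mean(v)
}
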