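# Rectified-integrated processing of multifibre sympathetic/baroreceptor
# nerve recordings.

#' First-order leaky integration (RC smoothing)
#'
#' Discrete first-order exponential smoother
#' \code{y_t = alpha * x_t + (1 - alpha) * y_{t-1}} with
#' \code{alpha = dt / (tau + dt)}, the digital equivalent of the hardware
#' RC "integrate and smooth" stage. A constant input settles to 95\% of its
#' value within about three time constants.
#'
#' @param x numeric input samples.
#' @param rate sampling rate (Hz).
#' @param tauMs time constant in milliseconds (default 3).
#' @return smoothed numeric vector (initial state 0).
#' @export
leakyIntegrate <- function(x, rate, tauMs = 3) {
  dt <- 1 / rate
  alpha <- dt / (tauMs / 1000 + dt)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive"))
}

#' Rectify and integrate a raw nerve signal
#'
#' The processing chain applied to multifibre nerve activity: DC offset
#' removal (mean subtraction), band-pass filtering (the 50--10,000 Hz
#' acquisition band; an upper edge above Nyquist is clipped to 0.45 x the
#' sampling rate, with a message), full-wave rectification, and first-order
#' leaky integration with a 3 ms time constant. The band-pass is a 2nd-order
#' Butterworth run forward--backward (zero-phase, 4th-order magnitude).
#'
#' @param signal a \linkS4class{NerveSignal}.
#' @param band numeric(2) pass band in Hz.
#' @param tauMs smoothing time constant (ms).
#' @return A \linkS4class{NerveSignal} whose samples are the integrated
#'   trace (beat annotations and background carried over).
#' @export
integrateNerveSignal <- function(signal, band = c(50, 10000), tauMs = 3) {
  stopifnot(is(signal, "NerveSignal"))
  rate <- signal@rate
  if (rate < 2 * band[1])
    stop("sampling rate ", rate, " Hz cannot support a ", band[1],
         " Hz lower band edge")
  nyq <- rate / 2
  hi <- band[2]
  if (hi >= nyq) {
    hi <- 0.45 * rate
    message("upper band edge clipped to ", hi, " Hz (0.45 x sampling rate)")
  }
  x <- signal@samples - mean(signal@samples)
  bf <- signal::butter(2, c(band[1], hi) / nyq, type = "pass")
  x <- signal::filtfilt(bf, x)
  y <- leakyIntegrate(abs(x), rate, tauMs)
  new("NerveSignal", samples = y, rate = rate, beatTimes = signal@beatTimes,
      background = signal@background)
}

#' Per-heartbeat relative nerve activity (% of pre-event baseline)
#'
#' Averages the integrated trace within each beat interval, subtracts the
#' background level (the integrated value recorded post mortem), and scales
#' by the mean of the \code{baselineBeats} beats immediately preceding the
#' event marker so the baseline is 100\%.
#'
#' @param integrated a \linkS4class{NerveSignal} from
#'   \code{\link{integrateNerveSignal}} (its \code{background} slot is used
#'   unless \code{background} is given).
#' @param eventTime event marker (s); the baseline window ends here.
#' @param background noise-floor level to subtract (a.u.); defaults to the
#'   signal's background slot.
#' @param baselineBeats number of pre-event beats forming the baseline.
#' @return data.frame with beat index, beat start time, raw per-beat mean
#'   (after background subtraction) and \code{relative} (%).
#' @export
beatAverageRelative <- function(integrated, eventTime,
                                background = NULL, baselineBeats = 10L) {
  stopifnot(is(integrated, "NerveSignal"))
  bt <- integrated@beatTimes
  if (length(bt) < 2L) stop("at least 2 annotated beats are required")
  if (is.null(background)) background <- integrated@background
  nSamp <- length(integrated@samples)
  tt <- (seq_len(nSamp) - 1) / integrated@rate
  edges <- c(bt, max(tt) + 1 / integrated@rate)
  beatMean <- vapply(seq_along(bt), function(b) {
    sel <- tt >= edges[b] & tt < edges[b + 1]
    mean(integrated@samples[sel]) - background
  }, numeric(1))
  pre <- which(bt < eventTime)
  if (length(pre) < baselineBeats)
    stop("need at least ", baselineBeats, " beats before the event marker")
  baseIdx <- pre[(length(pre) - baselineBeats + 1L):length(pre)]
  base <- mean(beatMean[baseIdx])
  if (base <= 0)
    stop("baseline not above the background level; ",
         "signal is indistinguishable from noise")
  data.frame(beat = seq_along(bt), time = bt, mean = beatMean,
             relative = 100 * beatMean / base)
}
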