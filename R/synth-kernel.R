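#' Convolve a drive series with a calcium indicator kernel
#'
#' Convolves a per-frame drive with a causal single-exponential kernel of
#' unit peak, `k(t) = exp(-t / decayS)`, emulating slow-indicator (GCaMP7s
#' style) fluorescence dynamics. Implemented as an exact first-order
#' recursive filter, equivalent to convolution with the untruncated kernel:
#' `y[t] = drive[t] + exp(-1 / (decayS * frameRate)) * y[t - 1]`.
#'
#' @param drive numeric vector, per-frame drive (e.g. spiking intensity).
#' @param decayS kernel decay constant in seconds; must be > 0.
#' @param frameRate sampling rate in Hz; must be > 0.
#' @return numeric vector of the same length as `drive`.
#' @examples
#' tr <- calciumConvolve(c(0, 1, rep(0, 8)), decayS = 1.5, frameRate = 20)
#' tr[2]            # 1 at the impulse
#' tr[3] / tr[2]    # decays by exp(-1/30) per frame
#' @export
calciumConvolve <- function(drive, decayS, frameRate = 20) {
  .stopIfNot(is.numeric(decayS) && length(decayS) == 1L && decayS > 0,
             "configuration error: 'decayS' must be a single positive number")
  .stopIfNot(is.numeric(frameRate) && length(frameRate) == 1L && frameRate > 0,
             "configuration error: 'frameRate' must be a single positive number")
  a <- exp(-1 / (decayS * frameRate))
  as.numeric(stats::filter(drive, a, method = "recursive"))
}

# Scale factor turning a unit 2 s boxcar drive (convolved with the kernel)
# into a response whose MEAN over the odor window is 1. Together with the
# smoothing noise factor this makes `responseAmplitude` a post-pipeline
# z-unit (see synthConfig).
.odorTemplateScale <- function(config, odorFrames = 2 * config@frameRate) {
  ref <- calciumConvolve(rep(1, odorFrames), config@kernelDecayS,
                         config@frameRate)
  1 / mean(ref)
}

# sd of a 5-frame centered moving average of unit white noise; the default
# smoothing of the preprocessing stage. Used to express injected amplitudes
# in post-smoothing z-units.
.smoothNoiseFactor <- function(window = 5) 1 / sqrt(window)

# Raw-unit amplitude for an injected response of `responseAmplitude`
# post-pipeline z-units.
.rawAmplitude <- function(config) {
  nsd <- if (config@noiseSd > 0) config@noiseSd else 1
  config@responseAmplitude * nsd * .smoothNoiseFactor()
}

# Slow baseline drift: low-pass-filtered white noise with sd ~ driftSd.
.baselineDrift <- function(n, driftSd) {
  if (driftSd <= 0) return(numeric(n))
  w <- 401L  # ~20 s at 20 Hz
  .movingAverage(stats::rnorm(n, 0, driftSd * sqrt(w)), w)
}
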