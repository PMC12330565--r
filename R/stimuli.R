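# Stimulus construction and level calibration.

#' Measure the sound pressure level of a waveform
#'
#' \code{20 * log10(RMS / Pref)} with Pref = 20 uPa.
#'
#' @param w a \linkS4class{Waveform}.
#' @return level in dB SPL.
#' @export
measureLevel <- function(w) {
  r <- rmsOf(w@samples)
  if (r == 0) stop("level of an all-zero waveform is undefined")
  20 * log10(r / PREF_PA)
}

#' Scale a waveform to a target sound pressure level
#'
#' Rescales the samples so the RMS equals \code{Pref * 10^(target/20)}
#' (Pref = 20 uPa); the waveform shape is unchanged.
#'
#' @param w a \linkS4class{Waveform} with nonzero RMS.
#' @param targetDb target level in dB SPL.
#' @return calibrated \linkS4class{Waveform}.
#' @examples
#' w <- setLevel(makeTone(1000, 0.1), 60)
#' measureLevel(w)  # 60
#' @export
setLevel <- function(w, targetDb) {
  r <- rmsOf(w@samples)
  if (r == 0) stop("cannot set the level of an all-zero waveform")
  Waveform(w@samples * (PREF_PA * 10^(targetDb / 20) / r), w@fs, targetDb)
}

raisedCosineRamps <- function(n, rampN) {
  g <- rep(1, n)
  if (rampN > 0) {
    t <- seq_len(rampN) / rampN
    on <- sin(pi * t / 2)^2          # squared-cosine (raised-cosine) ramp
    g[seq_len(rampN)] <- on
    g[(n - rampN + 1):n] <- rev(on)
  }
  g
}

#' Pure tone generator
#'
#' @param freq frequency (Hz), below Nyquist.
#' @param dur duration (s).
#' @param fs sample rate (Hz).
#' @param levelDb level (dB SPL).
#' @param rampSec optional raised-cosine on/off ramp length (s).
#' @param phase starting phase (rad).
#' @return calibrated \linkS4class{Waveform}.
#' @export
makeTone <- function(freq, dur, fs = 20000, levelDb = 60, rampSec = 0,
                     phase = 0) {
  if (freq >= fs / 2) stop("tone frequency must be below Nyquist")
  n <- round(dur * fs)
  x <- sin(2 * pi * freq * (0:(n - 1)) / fs + phase)
  x <- x * raisedCosineRamps(n, round(rampSec * fs))
  setLevel(Waveform(x, fs), levelDb)
}

# Brick-wall bandpass in the frequency domain (exact band limitation).
brickwallBandpass <- function(x, fs, fLo, fHi) {
  n <- length(x)
  f <- fftFoldedFreqs(n, fs)
  H <- as.numeric(f >= fLo & f <= fHi)
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Bandlimited Gaussian noise burst
#'
#' Gaussian noise band-limited to \code{band} with squared-cosine on/off
#' ramps; reproducible for a given seed.
#'
#' @param band two-element frequency band (Hz), within (0, fs/2).
#' @param dur duration (s).
#' @param rampSec ramp length (s); \code{2*rampSec} must not exceed dur.
#' @param fs sample rate (Hz).
#' @param levelDb level (dB SPL).
#' @param seed integer seed.
#' @return calibrated \linkS4class{Waveform}.
#' @export
makeNoiseBurst <- function(band = c(300, 10000), dur = 0.1, rampSec = 1e-3,
                           fs = 20000, levelDb = 60, seed = 1) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] <= fs / 2)
  if (2 * rampSec > dur) stop("ramps longer than the burst")
  n <- round(dur * fs)
  x <- withSeed(seed, stats::rnorm(n))
  x <- brickwallBandpass(x, fs, band[1], band[2])
  x <- x * raisedCosineRamps(n, round(rampSec * fs))
  # refilter after gating so ramp spectral leakage stays out of band
  x <- brickwallBandpass(x, fs, band[1], band[2])
  setLevel(Waveform(x, fs), levelDb)
}

#' Amplitude-modulated narrowband noise
#'
#' Narrowband Gaussian noise (bandwidth \code{bw} centered on \code{center})
#' multiplied by \code{(1 + depth * sin(2 pi modRate t))}, normalized so the
#' modulator has unit RMS gain, then calibrated.
#'
#' @param center center frequency (Hz).
#' @param bw bandwidth (Hz), less than \code{center}.
#' @param modRate modulation rate (Hz).
#' @param depth modulation depth in [0, 1].
#' @param dur duration (s).
#' @param fs sample rate (Hz).
#' @param levelDb level (dB SPL).
#' @param seed integer seed.
#' @param rampSec on/off ramp (s).
#' @return calibrated \linkS4class{Waveform}.
#' @export
makeAmNarrowbandNoise <- function(center, bw = 80, modRate = 40, depth = 1,
                                  dur = 0.5, fs = 20000, levelDb = 60,
                                  seed = 1, rampSec = 1e-3) {
  stopifnot(bw < center, depth >= 0, depth <= 1)
  n <- round(dur * fs)
  x <- withSeed(seed, stats::rnorm(n))
  x <- brickwallBandpass(x, fs, center - bw / 2, center + bw / 2)
  t <- (0:(n - 1)) / fs
  mod <- (1 + depth * sin(2 * pi * modRate * t)) / sqrt(1 + depth^2 / 2)
  x <- x * mod * raisedCosineRamps(n, round(rampSec * fs))
  setLevel(Waveform(x, fs), levelDb)
}

#' Impose interaural time and level differences on a stereo pair
#'
#' Applies a whole-waveform delay of \code{itdUs} microseconds to the right
#' channel (positive ITD: right lags) and raises the left channel level by
#' \code{ildDb} dB (positive ILD: left louder). The delay affects envelope
#' and fine structure alike; fractional-sample delays are realized by an
#' exact band-limited frequency-domain phase shift.
#'
#' @param left,right \linkS4class{Waveform}s with equal fs and length.
#' @param itdUs interaural time difference (microseconds).
#' @param ildDb interaural level difference (dB).
#' @return list with elements \code{left} and \code{right}.
#' @export
imposeItdIld <- function(left, right, itdUs = 0, ildDb = 0) {
  stopifnot(left@fs == right@fs,
            length(left@samples) == length(right@samples))
  fs <- left@fs
  d <- itdUs * 1e-6 * fs                   # delay in samples (right channel)
  r <- right@samples
  l <- left@samples
  if (d != 0) {
    if (d > 0) r <- fractionalDelay(r, d) else l <- fractionalDelay(l, -d)
  }
  if (ildDb != 0) l <- l * 10^(ildDb / 20)
  list(left = Waveform(l, fs), right = Waveform(r, fs))
}

#' Harmonic "speech-like" complex with amplitude modulation
#'
#' A stand-in for running speech: a harmonic complex on a fundamental
#' \code{f0} with 1/n amplitude rolloff and random phases, multiplied by a
#' slow sinusoidal envelope (syllable-rate AM).
#'
#' @param f0 fundamental (Hz).
#' @param nHarmonics number of harmonics.
#' @param amRate envelope modulation rate (Hz).
#' @param amDepth envelope modulation depth in [0, 1].
#' @param dur duration (s).
#' @param fs sample rate (Hz).
#' @param levelDb level (dB SPL).
#' @param seed integer seed (harmonic phases).
#' @return calibrated \linkS4class{Waveform}.
#' @export
makeHarmonicComplex <- function(f0 = 150, nHarmonics = 20, amRate = 5,
                                amDepth = 0.8, dur = 0.5, fs = 20000,
                                levelDb = 60, seed = 1) {
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  ph <- withSeed(seed, stats::runif(nHarmonics, 0, 2 * pi))
  x <- numeric(n)
  for (h in seq_len(nHarmonics)) {
    f <- h * f0
    if (f >= fs / 2) break
    x <- x + sin(2 * pi * f * t + ph[h]) / h
  }
  x <- x * (1 + amDepth * sin(2 * pi * amRate * t)) /
    sqrt(1 + amDepth^2 / 2)
  setLevel(Waveform(x, fs), levelDb)
}

#' Mix a signal with noise at a prescribed signal-to-noise ratio
#'
#' The noise is rescaled so that the signal-to-noise RMS ratio equals
#' \code{snrDb}; the mixture is then recalibrated to the signal's level.
#'
#' @param sig,noise \linkS4class{Waveform}s with equal fs and length.
#' @param snrDb target SNR (dB); \code{Inf} returns the clean signal.
#' @return calibrated \linkS4class{Waveform}.
#' @export
mixAtSnr <- function(sig, noise, snrDb) {
  if (is.infinite(snrDb) && snrDb > 0) return(sig)
  stopifnot(sig@fs == noise@fs,
            length(sig@samples) == length(noise@samples))
  g <- rmsOf(sig@samples) / rmsOf(noise@samples) / 10^(snrDb / 20)
  lvl <- if (is.na(sig@levelDb)) measureLevel(sig) else sig@levelDb
  setLevel(Waveform(sig@samples + g * noise@samples, sig@fs), lvl)
}
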