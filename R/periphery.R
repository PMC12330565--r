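# Acoustic-hearing auditory nerve model.

#' Rounded-exponential cochlear filterbank
#'
#' Applies \code{cfg@nChannels} zero-phase roex filters (unity gain at CF,
#' ERB-spaced center frequencies) to a waveform by frequency-domain
#' multiplication.
#'
#' @param w a \linkS4class{Waveform} with fs at least 2*fmax.
#' @param cfg a \linkS4class{CochleaConfig}.
#' @return N x T matrix of subband signals (attribute \code{cfs} holds the
#'   center frequencies).
#' @export
roexFilterbank <- function(w, cfg = CochleaConfig()) {
  # CFs may approach or exceed the Nyquist frequency (the default bank ends
  # at 12 kHz on 20 kHz audio); those filters are truncated at Nyquist by
  # construction of the folded frequency grid.
  if (length(w@samples) < 2) stop("stimulus too short to filter")
  cfs <- erbSpace(cfg@fmin, cfg@fmax, cfg@nChannels)
  f <- fftFoldedFreqs(length(w@samples), w@fs)
  resp <- t(vapply(cfs, roexResponse, numeric(length(f)), freqs = f))
  sub <- applyFilterbank(w@samples, resp)
  attr(sub, "cfs") <- cfs
  sub
}

#' Half-wave rectification, lowpass filtering and downsampling
#'
#' Half-wave rectifies each subband, lowpass filters with a linear-phase FIR
#' designed with a 50 ms Kaiser window (the upper limit of nerve phase
#' locking for the acoustic model: 3 kHz), clamps filter undershoot at 0 and
#' decimates to \code{nerveFs}.
#'
#' @param subbands N x T matrix at the audio sample rate.
#' @param cutoffHz lowpass cutoff (Hz), below fs/2.
#' @param fs audio sample rate (Hz); must be an integer multiple of
#'   \code{nerveFs}.
#' @param nerveFs output sample rate (Hz).
#' @return N x (T * nerveFs / fs) nonnegative matrix.
#' @export
rectifyLowpass <- function(subbands, cutoffHz = 3000, fs = 20000,
                           nerveFs = 10000) {
  stopifnot(cutoffHz < fs / 2, fs %% nerveFs == 0)
  h <- firKaiserLowpass(cutoffHz, fs)
  y <- filterRowsSame(pmax(subbands, 0), h)
  y <- pmax(y, 0)
  dec <- fs / nerveFs
  y[, seq(1, ncol(y), by = dec), drop = FALSE]
}

#' Sigmoidal rate-level function
#'
#' \code{Rspont + (Rmax - Rspont) / (1 + exp(-k (x - x0)))} with
#' \code{k = 7.32 / D} and \code{x0 = T + D/2}.
#'
#' @param x input level(s) in dB SPL (any numeric shape).
#' @param fiber a \linkS4class{FiberType}.
#' @return firing rate(s) in spikes/s, same shape as \code{x}.
#' @examples
#' rateLevel(10, FiberType(70, 250, 0, 20))  # sigmoid midpoint: 160
#' @export
rateLevel <- function(x, fiber) {
  k <- 7.32 / fiber@dynamicRangeDb
  x0 <- fiber@thresholdDb + fiber@dynamicRangeDb / 2
  fiber@rSpont + (fiber@rMax - fiber@rSpont) / (1 + exp(-k * (x - x0)))
}

#' Sample spike counts from instantaneous firing rates
#'
#' Pools the fibers of each type within a channel as a binomial process with
#' \code{n} fibers and per-bin success probability \code{p = rate / fs},
#' approximated by \code{Normal(np, np(1-p))}; draws are rounded to the
#' nearest integer (half to even) and clamped to \code{[0, n]}. Each
#' channel-by-type combination uses an independent substream derived from
#' \code{seed}, so a given seed yields a deterministic spike tensor.
#'
#' @param rateArr N x T x C array of firing rates (spikes/s).
#' @param nPerType integer vector (length C) of fibers per channel and type.
#' @param fs nerve sample rate (Hz); rates must not exceed fs.
#' @param seed integer seed.
#' @return N x T x C integer array of spike counts.
#' @export
sampleSpikes <- function(rateArr, nPerType, fs, seed = 1) {
  d <- dim(rateArr)
  stopifnot(length(d) == 3L, length(nPerType) == d[3])
  if (max(rateArr) > fs) stop("rates exceed the sampling rate (p > 1)")
  out <- array(0L, d)
  for (ci in seq_len(d[3])) {
    n <- nPerType[ci]
    if (n <= 0) next
    for (ch in seq_len(d[1])) {
      p <- rateArr[ch, , ci] / fs
      np <- n * p
      sd <- sqrt(pmax(np * (1 - p), 0))
      z <- withSeed(deriveSeed(seed, (ci - 1) * d[1] + ch),
                    stats::rnorm(d[2]))
      out[ch, , ci] <- as.integer(pmin(pmax(round(np + sd * z), 0), n))
    }
  }
  out
}

# Fibers per channel for each type, honoring any degeneration cap.
fibersPerType <- function(cfg, fibers) {
  perChannel <- cfg@nFibersTotal / cfg@nChannels
  fr <- vapply(fibers, function(f) f@populationFraction, numeric(1))
  as.integer(round(fr * perChannel))
}

#' Acoustic auditory nerve response (nervegram)
#'
#' Full acoustic pipeline: roex filterbank, half-wave rectification and
#' 3 kHz lowpass, downsampling to the nerve rate, per-sample conversion of
#' subband amplitude to dB SPL (floored at -30 dB SPL), three sigmoidal
#' rate-level functions, and Normal-approximation spike sampling.
#'
#' @param w calibrated \linkS4class{Waveform} (levelDb set).
#' @param cfg a \linkS4class{CochleaConfig}.
#' @param fibers list of \linkS4class{FiberType}s (default population).
#' @param seed integer seed for spike sampling.
#' @param sampleSpikeTrains if FALSE, skip spike sampling (rates only).
#' @return a \linkS4class{Nervegram} of shape N x T x C.
#' @export
acousticNervegram <- function(w, cfg = CochleaConfig(),
                              fibers = defaultFiberTypes(), seed = 1,
                              sampleSpikeTrains = TRUE) {
  if (is.na(w@levelDb))
    stop("waveform must be calibrated in dB SPL (use setLevel)")
  sub <- roexFilterbank(w, cfg)
  cfs <- attr(sub, "cfs")
  env <- rectifyLowpass(sub, cfg@lowpassCutoff, w@fs, cfg@nerveFs)
  xdb <- ampToDbSpl(env)
  d <- c(nrow(env), ncol(env), length(fibers))
  rateArr <- array(0, d)
  for (ci in seq_along(fibers)) rateArr[, , ci] <- rateLevel(xdb, fibers[[ci]])
  nPerType <- fibersPerType(cfg, fibers)
  spk <- if (sampleSpikeTrains)
    sampleSpikes(rateArr, nPerType, cfg@nerveFs, seed)
  else array(integer(0), c(0, 0, 0))
  new("Nervegram", rates = rateArr, spikes = spk, channelCfs = cfs,
      fs = cfg@nerveFs,
      meta = list(mode = "acoustic", seed = seed, nPerType = nPerType,
                  configHash = configHash(cfg)))
}
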