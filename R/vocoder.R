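# Noise vocoder.

#' Vocoder configuration
#'
#' @slot nAnalysisFilters number of narrow analysis filters (320).
#' @slot fmin,fmax analysis range (Hz; 20--10000).
#' @slot nBands number of vocoder channels (must divide nAnalysisFilters).
#' @export
setClass("VocoderConfig",
  representation(nAnalysisFilters = "integer", fmin = "numeric",
                 fmax = "numeric", nBands = "integer"),
  prototype(nAnalysisFilters = 320L, fmin = 20, fmax = 10000, nBands = 16L))

setValidity("VocoderConfig", function(object) {
  if (object@nAnalysisFilters %% object@nBands != 0)
    return("nBands must divide nAnalysisFilters")
  if (object@fmin <= 0 || object@fmax <= object@fmin)
    return("need 0 < fmin < fmax")
  TRUE
})

#' @rdname VocoderConfig-class
#' @param nAnalysisFilters,fmin,fmax,nBands see slots.
#' @export
VocoderConfig <- function(nAnalysisFilters = 320L, fmin = 20, fmax = 10000,
                          nBands = 16L) {
  new("VocoderConfig", nAnalysisFilters = as.integer(nAnalysisFilters),
      fmin = fmin, fmax = fmax, nBands = as.integer(nBands))
}

# Band transfer functions: adjacent groups of narrow analysis filters summed.
vocoderBandResponses <- function(cfg, freqs) {
  narrow <- halfCosineFilterbank(cfg@nAnalysisFilters, cfg@fmin, cfg@fmax,
                                 freqs)
  g <- cfg@nAnalysisFilters / cfg@nBands
  groups <- rep(seq_len(cfg@nBands), each = g)
  rowsum(narrow, groups)
}

#' Noise vocoder
#'
#' Replaces subband fine structure with noise while preserving subband
#' envelopes: the signal is analyzed with a bank of 320 zero-phase
#' squared-cosine filters (20 Hz--10 kHz, ERB-spaced, 50\% overlap, perfectly
#' tiling), adjacent subbands are summed into \code{nBands} channels, their
#' Hilbert envelopes are imposed on matched Gaussian noise subbands (each
#' noise subband first divided by its own envelope), the products are
#' refiltered with the summed transfer functions and summed.
#'
#' @param w input \linkS4class{Waveform}; fs must be at least 2*fmax.
#' @param cfg a \linkS4class{VocoderConfig}.
#' @param seed integer seed for the noise carrier.
#' @return vocoded \linkS4class{Waveform} at the input level.
#' @export
noiseVocode <- function(w, cfg = VocoderConfig(), seed = 1) {
  stopifnot(w@fs >= 2 * cfg@fmax)
  x <- w@samples
  n <- length(x)
  f <- fftFoldedFreqs(n, w@fs)
  bands <- vocoderBandResponses(cfg, f)

  sigSub <- applyFilterbank(x, bands)
  sigEnv <- hilbertEnvelopeRows(sigSub)

  noise <- withSeed(seed, stats::rnorm(n))
  noiseSub <- applyFilterbank(noise, bands)
  noiseEnv <- hilbertEnvelopeRows(noiseSub)
  floorEnv <- 1e-8 * max(noiseEnv)
  carrier <- noiseSub / pmax(noiseEnv, floorEnv) * sigEnv

  out <- colSums(applyFilterbank2(carrier, bands))
  lvl <- w@levelDb
  wv <- Waveform(out, w@fs)
  if (!is.na(lvl) && rmsOf(out) > 0) wv <- setLevel(wv, lvl)
  wv
}

# Refilter each row of a matrix with the corresponding transfer function.
applyFilterbank2 <- function(m, responses) {
  n <- ncol(m)
  X <- stats::mvfft(t(m)) * t(responses)
  t(Re(stats::mvfft(X, inverse = TRUE)) / n)
}
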