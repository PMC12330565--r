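# Electrode-nerve interface: spatial spread, temporal impulse response,
# electrical rate-level and spike generation.

#' Spatial spread of the electrical field
#'
#' Sums, at each nerve position and time sample, the exponentially decaying
#' field \code{I_e(t) * V0 * exp(-|x - x_e| / lambda)} contributed by every
#' electrode (superposition in linear current).
#'
#' @param eg an \linkS4class{Electrodogram}.
#' @param sm a \linkS4class{SpreadModel} with matching electrode count.
#' @return nNerve x T matrix of summed field (linear current units).
#' @export
spatialSpread <- function(eg, sm = SpreadModel()) {
  if (length(sm@electrodePositionsMm) != nrow(eg@current))
    stop("electrode count of spread model and electrodogram differ")
  V <- sm@V0 * exp(-abs(outer(sm@nervePositionsMm,
                              sm@electrodePositionsMm, "-")) / sm@lambdaMm)
  V %*% eg@current
}

#' Nerve temporal impulse response
#'
#' 10 ms kernel: weighted sum of an excitatory Gaussian (mean 0.6 ms,
#' sd 0.6 ms, weight 1.0) and a refractory Gaussian (mean 2.2 ms, sd 0.33 ms,
#' weight 0.1), rescaled to a peak value of 1. The printed refractory weight
#' is positive (additive); \code{negateRefractory = TRUE} gives the
#' suppressive variant.
#'
#' @param fs sample rate (Hz); 10 kHz or higher recommended.
#' @param negateRefractory flip the sign of the refractory component.
#' @return numeric kernel of length \code{0.01 * fs}.
#' @export
nerveKernel <- function(fs = 10000, negateRefractory = FALSE) {
  t <- (seq_len(round(0.01 * fs)) - 1) / fs
  wR <- if (negateRefractory) -0.1 else 0.1
  k <- exp(-(t - 0.6e-3)^2 / (2 * 0.6e-3^2)) +
    wR * exp(-(t - 2.2e-3)^2 / (2 * 0.33e-3^2))
  k / max(k)
}

#' Electrical rate-level parameters as a FiberType sigmoid
#' @noRd
electricalRateLevel <- function(xDb, efp) {
  k <- 7.32 / efp@dynamicRangeDb
  x0 <- efp@thresholdDb + efp@dynamicRangeDb / 2
  efp@rSpont + (efp@rMax - efp@rSpont) / (1 + exp(-k * (xDb - x0)))
}

# Firing-rate matrix (nNerve x T) for an electrodogram; shared by the
# nervegram builder and the variance-maximization fit.
ciRateMatrix <- function(eg, sm, efp, kernel = NULL) {
  field <- spatialSpread(eg, sm)
  if (is.null(kernel)) kernel <- nerveKernel(eg@fs)
  drive <- convolveRowsCausal(field, kernel)
  xDb <- milliampToDb(drive)
  electricalRateLevel(xDb, efp)
}

#' CI-stimulated auditory nerve response (nervegram)
#'
#' Convolves the spatially spread electrical field at each nerve position
#' with the nerve impulse response, converts the drive to dB re 1 mA
#' (floored at -100 dB), applies the electrical rate-level sigmoid (shared
#' by all three fiber-type channels) and samples spikes exactly as in the
#' acoustic model.
#'
#' @param eg an \linkS4class{Electrodogram}.
#' @param sm a \linkS4class{SpreadModel}.
#' @param efp an \linkS4class{ElectricalFiberParams}.
#' @param cfg a \linkS4class{CochleaConfig} (fiber counts, nerve rate).
#' @param fibers fiber population (population fractions only).
#' @param kernel optional precomputed \code{\link{nerveKernel}}.
#' @param seed integer seed for spike sampling.
#' @param sampleSpikeTrains if FALSE, skip spike sampling.
#' @return a \linkS4class{Nervegram} of shape nNerve x T x 3.
#' @export
ciNervegram <- function(eg, sm = SpreadModel(nElectrodes = nrow(eg@current)),
                        efp = ElectricalFiberParams(), cfg = CochleaConfig(),
                        fibers = defaultFiberTypes(), kernel = NULL, seed = 1,
                        sampleSpikeTrains = TRUE) {
  r1 <- ciRateMatrix(eg, sm, efp, kernel)
  C <- length(fibers)
  rateArr <- array(0, c(nrow(r1), ncol(r1), C))
  for (ci in seq_len(C)) rateArr[, , ci] <- r1
  nPerType <- fibersPerType(cfg, fibers)
  spk <- if (sampleSpikeTrains) sampleSpikes(rateArr, nPerType, eg@fs, seed)
  else array(integer(0), c(0, 0, 0))
  new("Nervegram", rates = rateArr, spikes = spk,
      channelCfs = greenwoodCf(sm@nervePositionsMm, sm@cochleaLengthMm),
      fs = eg@fs,
      meta = list(mode = "electric", seed = seed, nPerType = nPerType,
                  configHash = configHash(list(sm, efp, cfg))))
}

# Greenwood place-frequency map (human), position measured from the apex.
greenwoodCf <- function(xMm, lengthMm = 35) {
  165.4 * (10^(2.1 * xMm / lengthMm) - 0.88)
}

#' Simulate peripheral neural degeneration
#'
#' Eliminates fibers at the spike sampling stage: the per-channel maximum
#' spike count becomes \code{round((1 - fraction) * nFibersPerChannel)},
#' applied uniformly across frequencies and fiber types.
#'
#' @param cfg a \linkS4class{CochleaConfig}.
#' @param fraction fraction of fibers lost, in [0, 1].
#' @return modified \linkS4class{CochleaConfig} with the reduced fiber count.
#' @examples
#' applyPeripheralDegeneration(CochleaConfig(), 0.9)@nFibersTotal / 50  # 64
#' @export
applyPeripheralDegeneration <- function(cfg, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  perChannel <- cfg@nFibersTotal / cfg@nChannels
  newCap <- round((1 - fraction) * perChannel)
  CochleaConfig(cfg@nChannels, cfg@fmin, cfg@fmax, cfg@lowpassCutoff,
                cfg@nerveFs, newCap * cfg@nChannels)
}
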