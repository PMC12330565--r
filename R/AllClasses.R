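#' @import methods
NULL

# ---------------------------------------------------------------------------
# Waveform
# ---------------------------------------------------------------------------

#' Waveform: a sampled acoustic pressure signal
#'
#' Container for a mono pressure waveform. Samples are in pressure units
#' scaled so that a calibrated waveform has
#' \code{20*log10(RMS / 20e-6) == levelDb} (dB SPL re 20 uPa).
#'
#' @slot samples numeric vector of pressure samples.
#' @slot fs sample rate in Hz.
#' @slot levelDb calibrated level in dB SPL, or \code{NA} if uncalibrated.
#' @export
setClass("Waveform",
  representation(samples = "numeric", fs = "numeric", levelDb = "numeric"),
  prototype(samples = numeric(0), fs = 20000, levelDb = NA_real_))

setValidity("Waveform", function(object) {
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    return("samples must be finite")
  if (length(object@levelDb) != 1L)
    return("levelDb must be length 1 (possibly NA)")
  if (!is.na(object@levelDb) && length(object@samples) > 0) {
    r <- rmsOf(object@samples)
    if (r > 0 && abs(20 * log10(r / PREF_PA) - object@levelDb) > 1e-6)
      return("levelDb inconsistent with sample RMS")
  }
  TRUE
})

#' Construct a Waveform
#'
#' @param samples numeric vector of pressure samples.
#' @param fs sample rate (Hz).
#' @param levelDb calibrated level (dB SPL) or \code{NA}.
#' @return A \linkS4class{Waveform}.
#' @export
Waveform <- function(samples, fs = 20000, levelDb = NA_real_) {
  new("Waveform", samples = as.numeric(samples), fs = as.numeric(fs),
      levelDb = as.numeric(levelDb))
}

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' Auditory nerve fiber type parameters
#'
#' Sigmoidal rate-level parameters for one fiber population. The sigmoid
#' slope is \code{k = 7.32 / D} and midpoint \code{x0 = T + D/2} where
#' \code{T} is the threshold (dB SPL) and \code{D} the dynamic range (dB).
#'
#' @slot rSpont spontaneous rate (spikes/s).
#' @slot rMax maximum rate (spikes/s).
#' @slot thresholdDb threshold (dB SPL).
#' @slot dynamicRangeDb dynamic range (dB).
#' @slot populationFraction fraction of the fiber population of this type.
#' @export
setClass("FiberType",
  representation(rSpont = "numeric", rMax = "numeric", thresholdDb = "numeric",
                 dynamicRangeDb = "numeric", populationFraction = "numeric"))

setValidity("FiberType", function(object) {
  if (object@rSpont < 0) return("rSpont must be >= 0")
  if (object@rMax <= object@rSpont) return("rMax must exceed rSpont")
  if (object@dynamicRangeDb <= 0) return("dynamic range must be positive")
  if (object@populationFraction < 0 || object@populationFraction > 1)
    return("populationFraction must be in [0,1]")
  TRUE
})

#' @rdname FiberType-class
#' @param rSpont,rMax,thresholdDb,dynamicRangeDb,populationFraction see slots.
#' @export
FiberType <- function(rSpont, rMax = 250, thresholdDb = 0,
                      dynamicRangeDb = 20, populationFraction = 1) {
  new("FiberType", rSpont = rSpont, rMax = rMax, thresholdDb = thresholdDb,
      dynamicRangeDb = dynamicRangeDb, populationFraction = populationFraction)
}

#' Default fiber population: high/medium/low spontaneous rate
#'
#' Three fiber types with spontaneous rates 70 / 4 / 0.1 spikes/s, thresholds
#' 0 / 12 / 28 dB SPL, dynamic ranges 20 / 40 / 80 dB, maximum rate
#' 250 spikes/s, population fractions 0.60 / 0.25 / 0.15.
#'
#' @return list of three \linkS4class{FiberType} objects.
#' @export
defaultFiberTypes <- function() {
  list(
    high   = FiberType(70,  250,  0, 20, 0.60),
    medium = FiberType(4,   250, 12, 40, 0.25),
    low    = FiberType(0.1, 250, 28, 80, 0.15))
}

#' Cochlear model configuration
#'
#' @slot nChannels number of frequency channels (default 50).
#' @slot fmin,fmax filterbank range (Hz; 60--12000).
#' @slot lowpassCutoff envelope/phase-locking lowpass cutoff (Hz; 3000).
#' @slot nerveFs nerve representation sample rate (Hz; 10000).
#' @slot nFibersTotal simulated fiber count across channels (32000).
#' @export
setClass("CochleaConfig",
  representation(nChannels = "integer", fmin = "numeric", fmax = "numeric",
                 lowpassCutoff = "numeric", nerveFs = "numeric",
                 nFibersTotal = "numeric"),
  prototype(nChannels = 50L, fmin = 60, fmax = 12000, lowpassCutoff = 3000,
            nerveFs = 10000, nFibersTotal = 32000))

setValidity("CochleaConfig", function(object) {
  if (object@nChannels < 2L) return("need at least 2 channels")
  if (object@fmin <= 0 || object@fmax <= object@fmin)
    return("need 0 < fmin < fmax")
  if (object@nFibersTotal < 0) return("nFibersTotal must be >= 0")
  if (object@nFibersTotal %% object@nChannels != 0)
    return("nFibersTotal must be divisible by nChannels")
  TRUE
})

#' @rdname CochleaConfig-class
#' @param nChannels,fmin,fmax,lowpassCutoff,nerveFs,nFibersTotal see slots.
#' @export
CochleaConfig <- function(nChannels = 50L, fmin = 60, fmax = 12000,
                          lowpassCutoff = 3000, nerveFs = 10000,
                          nFibersTotal = 32000) {
  new("CochleaConfig", nChannels = as.integer(nChannels), fmin = fmin,
      fmax = fmax, lowpassCutoff = lowpassCutoff, nerveFs = nerveFs,
      nFibersTotal = nFibersTotal)
}

#' Loudness growth function parameters
#'
#' Sigmoidal map from acoustic level p (dB SPL) to current level (dB re 1 mA):
#' \code{TL + (MCL - TL) / (1 + exp(-beta * (p - p0)))} with beta = 0.122 and
#' p0 = 40, so that the 10--70 dB SPL acoustic range maps to [TL, MCL].
#'
#' @slot TL threshold current level (dB re 1 mA).
#' @slot MCL maximum comfortable current level (dB re 1 mA).
#' @slot beta sigmoid slope (1/dB).
#' @slot p0 sigmoid midpoint (dB SPL).
#' @export
setClass("LoudnessGrowth",
  representation(TL = "numeric", MCL = "numeric", beta = "numeric",
                 p0 = "numeric"),
  prototype(TL = -20, MCL = 0, beta = 0.122, p0 = 40))

setValidity("LoudnessGrowth", function(object) {
  if (object@MCL <= object@TL) return("MCL must exceed TL")
  if (object@beta <= 0) return("beta must be positive")
  TRUE
})

#' @rdname LoudnessGrowth-class
#' @param TL,MCL,beta,p0 see slots.
#' @export
LoudnessGrowth <- function(TL = -20, MCL = 0, beta = 0.122, p0 = 40) {
  new("LoudnessGrowth", TL = TL, MCL = MCL, beta = beta, p0 = p0)
}

#' Sound coding strategy configuration
#'
#' @slot name one of "CIS", "ACE", "FSP", "HIRES120".
#' @slot nElectrodes electrode count M (16 default; 22 supported).
#' @slot fLow,fHigh analysis filter range (Hz; 150--10000).
#' @slot envCutoff envelope lowpass cutoff (Hz; 50).
#' @slot pulseRate per-electrode pulse rate (pps; 500 CIS, 800 ACE/FSP).
#' @slot interleaveOffset inter-electrode pulse offset (s; 200e-6).
#' @slot nMaxima ACE: electrodes active per frame (8).
#' @slot frameMs analysis frame length (ms; ACE/HiRes 2, FSP fine structure 1).
#' @slot nFineStructure FSP: number of apical fine-structure electrodes (3).
#' @slot independentJitter if TRUE each electrode draws its own start jitter.
#' @slot activeElectrodes integer indices of active electrodes (all if empty).
#' @export
setClass("StrategyConfig",
  representation(name = "character", nElectrodes = "integer",
                 fLow = "numeric", fHigh = "numeric", envCutoff = "numeric",
                 pulseRate = "numeric", interleaveOffset = "numeric",
                 nMaxima = "integer", frameMs = "numeric",
                 nFineStructure = "integer", independentJitter = "logical",
                 activeElectrodes = "integer"))

setValidity("StrategyConfig", function(object) {
  if (!object@name %in% c("CIS", "ACE", "FSP", "HIRES120"))
    return("unknown strategy name")
  if (object@nElectrodes < 2L) return("need at least 2 electrodes")
  if (object@pulseRate <= 0 || object@interleaveOffset < 0)
    return("rates and offsets must be positive")
  if (object@nMaxima > object@nElectrodes)
    return("nMaxima must not exceed nElectrodes")
  if (length(object@activeElectrodes) &&
      (min(object@activeElectrodes) < 1L ||
       max(object@activeElectrodes) > object@nElectrodes))
    return("activeElectrodes out of range")
  TRUE
})

#' @rdname StrategyConfig-class
#' @param name,nElectrodes,fLow,fHigh,envCutoff,pulseRate,interleaveOffset
#'   see slots.
#' @param nMaxima,frameMs,nFineStructure,independentJitter,activeElectrodes
#'   see slots.
#' @export
StrategyConfig <- function(name = "CIS", nElectrodes = 16L, fLow = 150,
                           fHigh = 10000, envCutoff = 50,
                           pulseRate = if (name == "CIS") 500 else 800,
                           interleaveOffset = 200e-6, nMaxima = 8L,
                           frameMs = if (name == "FSP") 1 else 2,
                           nFineStructure = 3L, independentJitter = FALSE,
                           activeElectrodes = integer(0)) {
  new("StrategyConfig", name = toupper(name),
      nElectrodes = as.integer(nElectrodes), fLow = fLow, fHigh = fHigh,
      envCutoff = envCutoff, pulseRate = pulseRate,
      interleaveOffset = interleaveOffset, nMaxima = as.integer(nMaxima),
      frameMs = frameMs, nFineStructure = as.integer(nFineStructure),
      independentJitter = independentJitter,
      activeElectrodes = as.integer(activeElectrodes))
}

#' Spatial spread model of electrical excitation
#'
#' Exponential decay of the electrical field along the (unwound) cochlea:
#' \code{V = V0 * exp(-|x_ANF - x_elec| / lambda)}. Electrodes are placed
#' equidistantly from 8.125 mm (apical) to 23.875 mm (basal) on a 35 mm
#' cochlea; nerve positions default to 50 uniform locations over the cochlea.
#'
#' @slot lambdaMm spread constant (mm): 6 monopolar, 2.35 bipolar,
#'   1.5 tripolar.
#' @slot V0 peak field (1).
#' @slot cochleaLengthMm cochlea length (35 mm).
#' @slot electrodePositionsMm electrode positions (mm, apex-referenced).
#' @slot nervePositionsMm nerve fiber channel positions (mm).
#' @export
setClass("SpreadModel",
  representation(lambdaMm = "numeric", V0 = "numeric",
                 cochleaLengthMm = "numeric",
                 electrodePositionsMm = "numeric",
                 nervePositionsMm = "numeric"))

setValidity("SpreadModel", function(object) {
  if (object@lambdaMm <= 0) return("lambda must be positive")
  pos <- c(object@electrodePositionsMm, object@nervePositionsMm)
  if (any(pos < 0 | pos > object@cochleaLengthMm))
    return("positions must lie within [0, cochleaLength]")
  TRUE
})

#' @rdname SpreadModel-class
#' @param lambdaMm,V0,cochleaLengthMm see slots.
#' @param nElectrodes electrode count used to place electrodes equidistantly
#'   from 8.125 to 23.875 mm.
#' @param nNerve number of nerve positions (uniform over the cochlea).
#' @param electrodePositionsMm,nervePositionsMm explicit overrides.
#' @export
SpreadModel <- function(lambdaMm = 6, V0 = 1, cochleaLengthMm = 35,
                        nElectrodes = 16L, nNerve = 50L,
                        electrodePositionsMm =
                          seq(8.125, 23.875, length.out = nElectrodes),
                        nervePositionsMm =
                          seq(0, cochleaLengthMm, length.out = nNerve)) {
  new("SpreadModel", lambdaMm = lambdaMm, V0 = V0,
      cochleaLengthMm = cochleaLengthMm,
      electrodePositionsMm = electrodePositionsMm,
      nervePositionsMm = nervePositionsMm)
}

#' Electrical rate-level parameters
#'
#' All fibers share one sigmoid under electrical stimulation: dynamic range
#' 15 dB, threshold -5 dB re 1 mA, spontaneous rate 0.1 spikes/s, maximum
#' 250 spikes/s (same sigmoid family as the acoustic rate-level function).
#'
#' @slot dynamicRangeDb,thresholdDb,rSpont,rMax see description.
#' @export
setClass("ElectricalFiberParams",
  representation(dynamicRangeDb = "numeric", thresholdDb = "numeric",
                 rSpont = "numeric", rMax = "numeric"),
  prototype(dynamicRangeDb = 15, thresholdDb = -5, rSpont = 0.1, rMax = 250))

setValidity("ElectricalFiberParams", function(object) {
  if (object@dynamicRangeDb <= 0) return("dynamic range must be positive")
  if (object@rMax <= object@rSpont) return("rMax must exceed rSpont")
  TRUE
})

#' @rdname ElectricalFiberParams-class
#' @param dynamicRangeDb,thresholdDb,rSpont,rMax see slots.
#' @export
ElectricalFiberParams <- function(dynamicRangeDb = 15, thresholdDb = -5,
                                  rSpont = 0.1, rMax = 250) {
  new("ElectricalFiberParams", dynamicRangeDb = dynamicRangeDb,
      thresholdDb = thresholdDb, rSpont = rSpont, rMax = rMax)
}

#' Grid of candidate current settings
#'
#' MCL candidates from -60 to +40 dB re 1 mA in 5 dB steps, with the
#' threshold level tied to the MCL as \code{TL = MCL - tlOffset} (20 dB).
#'
#' @slot mclMin,mclMax,stepDb,tlOffset see description.
#' @export
setClass("CurrentGrid",
  representation(mclMin = "numeric", mclMax = "numeric", stepDb = "numeric",
                 tlOffset = "numeric"),
  prototype(mclMin = -60, mclMax = 40, stepDb = 5, tlOffset = 20))

setValidity("CurrentGrid", function(object) {
  if (object@stepDb <= 0) return("step must be positive")
  if (object@mclMax < object@mclMin) return("empty grid")
  TRUE
})

#' @rdname CurrentGrid-class
#' @param mclMin,mclMax,stepDb,tlOffset see slots.
#' @export
CurrentGrid <- function(mclMin = -60, mclMax = 40, stepDb = 5,
                        tlOffset = 20) {
  new("CurrentGrid", mclMin = mclMin, mclMax = mclMax, stepDb = stepDb,
      tlOffset = tlOffset)
}

# ---------------------------------------------------------------------------
# Electrodogram / Nervegram
# ---------------------------------------------------------------------------

#' Electrodogram: per-electrode stimulation current over time
#'
#' The canonical store is linear current in mA (an M x T matrix; 0 means no
#' pulse). The dB re 1 mA view of nonzero pulse amplitudes is available via
#' \code{\link{currentDb}}. Electrode 1 is the most apical (lowest frequency).
#'
#' @slot current M x T matrix, linear mA.
#' @slot fs sample rate (Hz, 10000).
#' @slot positionsMm electrode positions along the cochlea (mm).
#' @slot strategy strategy name.
#' @slot loudness the \linkS4class{LoudnessGrowth} used.
#' @slot meta list: seed, config hash, pulse table.
#' @export
setClass("Electrodogram",
  representation(current = "matrix", fs = "numeric", positionsMm = "numeric",
                 strategy = "character", loudness = "LoudnessGrowth",
                 meta = "list"))

setValidity("Electrodogram", function(object) {
  if (any(!is.finite(object@current))) return("currents must be finite")
  if (any(object@current < 0)) return("linear currents must be nonnegative")
  if (length(object@positionsMm) != nrow(object@current))
    return("one position per electrode required")
  nz <- object@current[object@current > 0]
  if (length(nz)) {
    # steered (HiRes120) pulses split current below TL; only the MCL bound
    # is a hard invariant in the dB view
    if (max(20 * log10(nz)) > object@loudness@MCL + 1e-6)
      return("pulse amplitudes must not exceed MCL")
  }
  TRUE
})

#' Nervegram: firing rates and spike counts per channel/time/fiber type
#'
#' @slot rates N x T x C array of instantaneous firing rates (spikes/s).
#' @slot spikes N x T x C integer array of sampled spike counts.
#' @slot channelCfs characteristic frequency per channel (Hz).
#' @slot fs nerve sample rate (Hz).
#' @slot meta list: mode, seed, config hash, fiber counts.
#' @export
setClass("Nervegram",
  representation(rates = "array", spikes = "array", channelCfs = "numeric",
                 fs = "numeric", meta = "list"))

setValidity("Nervegram", function(object) {
  if (length(dim(object@rates)) != 3L) return("rates must be N x T x C")
  if (any(object@rates < 0)) return("rates must be nonnegative")
  if (length(object@spikes)) {
    if (!identical(dim(object@spikes), dim(object@rates)))
      return("spikes must match rates in shape")
    if (any(object@spikes < 0)) return("spike counts must be nonnegative")
    if (max(abs(object@spikes - round(object@spikes))) > 0)
      return("spike counts must be integers")
    n <- object@meta$nPerType
    if (!is.null(n)) {
      mx <- apply(object@spikes, 3, max)
      if (any(mx > n + 1e-9)) return("spike counts exceed fiber counts")
    }
  }
  if (length(object@channelCfs) != dim(object@rates)[1])
    return("one CF per channel required")
  TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.3f s), level %s dB SPL\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs,
              ifelse(is.na(object@levelDb), "NA",
                     sprintf("%.2f", object@levelDb))))
})

setMethod("show", "Electrodogram", function(object) {
  cat(sprintf(
    "Electrodogram [%s]: %d electrodes x %d samples @ %g Hz, %d pulses\n",
    object@strategy, nrow(object@current), ncol(object@current), object@fs,
    sum(object@current > 0)))
  cat(sprintf("  TL %.1f / MCL %.1f dB re 1 mA\n", object@loudness@TL,
              object@loudness@MCL))
})

setMethod("show", "Nervegram", function(object) {
  d <- dim(object@rates)
  cat(sprintf("Nervegram [%s]: %d channels x %d samples x %d fiber types @ %g Hz\n",
              ifelse(is.null(object@meta$mode), "?", object@meta$mode),
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  mean rate %.2f spikes/s, CFs %.0f-%.0f Hz\n",
              mean(object@rates), min(object@channelCfs),
              max(object@channelCfs)))
})
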