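# Psychophysical analysis procedures: psychometric readout, electrodogram
# ITD/ILD measurement, cue bias weights, localization utilities.

#' Intensity discrimination pedestal stimulus
#'
#' A 1000 ms tone pedestal. Label 1: 250 ms at the pedestal level, 500 ms at
#' pedestal + increment, 250 ms back at the pedestal. Label 0: constant
#' pedestal throughout (any increment is ignored).
#'
#' @param freq carrier frequency (Hz).
#' @param pedestalDb pedestal level I (dB SPL).
#' @param deltaDb intensity increment (dB), >= 0.
#' @param label 0 (constant) or 1 (incremented middle segment).
#' @param fs sample rate (Hz; 20000).
#' @param totalDur total duration (s; 1).
#' @return \linkS4class{Waveform} (levelDb left \code{NA}: the level varies
#'   over time by construction).
#' @export
makeIntensityStimulus <- function(freq, pedestalDb, deltaDb = 0, label = 1,
                                  fs = 20000, totalDur = 1) {
  stopifnot(label %in% c(0, 1), deltaDb >= 0, freq < fs / 2)
  n <- round(totalDur * fs)
  n1 <- round(0.25 * totalDur * fs)
  n2 <- round(0.75 * totalDur * fs)
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * freq * t)
  x <- x / rmsOf(x) * dbSplToAmp(pedestalDb)   # sine RMS -> pedestal level
  if (label == 1 && deltaDb > 0)
    x[(n1 + 1):n2] <- x[(n1 + 1):n2] * 10^(deltaDb / 20)
  Waveform(x, fs)
}

#' Psychometric threshold at a criterion accuracy
#'
#' Monotonizes the accuracy-vs-increment curve by isotonic regression, then
#' finds the smallest increment at which the curve crosses the criterion by
#' linear interpolation between adjacent grid points. A curve that starts
#' above the criterion yields the first grid point; one that never reaches
#' it yields \code{NA}.
#'
#' @param deltaGrid increasing increment grid (dB).
#' @param acc accuracies in [0, 1], one per grid point.
#' @param criterion threshold criterion (0.707).
#' @return threshold increment (dB), or \code{NA_real_} if undefined.
#' @examples
#' psychometricThreshold(c(1, 2), c(0.5, 0.9))  # 1.5175
#' @export
psychometricThreshold <- function(deltaGrid, acc, criterion = 0.707) {
  stopifnot(length(deltaGrid) >= 2, length(acc) == length(deltaGrid),
            !is.unsorted(deltaGrid))
  y <- stats::isoreg(deltaGrid, acc)$yf
  if (y[1] >= criterion) return(deltaGrid[1])
  ix <- which(y >= criterion)
  if (!length(ix)) return(NA_real_)
  i <- ix[1]
  deltaGrid[i - 1] + (criterion - y[i - 1]) / (y[i] - y[i - 1]) *
    (deltaGrid[i] - deltaGrid[i - 1])
}

#' Weber fraction and percent dynamic range
#'
#' Converts the pedestal I and threshold increment to linear current through
#' the loudness growth function, then reports the Weber fraction
#' \code{10 log10(dI / I)} (dB, in current) and the pedestal position within
#' the electrical dynamic range,
#' \code{\%DR = 100 (I - TL) / (MCL - TL)} in linear current.
#'
#' @param pedestalDb pedestal level I (dB SPL).
#' @param deltaDb threshold increment (dB SPL).
#' @param lg a \linkS4class{LoudnessGrowth}.
#' @return list with \code{weberDb} and \code{percentDR} (the latter is
#'   <= 0, flagged via attribute \code{"belowTL"}, when I maps at or below
#'   TL).
#' @export
weberAndPercentDR <- function(pedestalDb, deltaDb, lg) {
  stopifnot(is.finite(deltaDb))
  iCur <- dbToMilliamp(loudnessGrowth(pedestalDb, lg))
  dCur <- dbToMilliamp(loudnessGrowth(pedestalDb + deltaDb, lg)) - iCur
  tlCur <- dbToMilliamp(lg@TL)
  mclCur <- dbToMilliamp(lg@MCL)
  pdr <- 100 * (iCur - tlCur) / (mclCur - tlCur)
  out <- list(weberDb = 10 * log10(dCur / iCur), percentDR = pdr)
  if (pdr <= 0) attr(out, "belowTL") <- TRUE
  out
}

#' Interaural time difference of one electrode's signal
#'
#' Cross-correlates the left and right linear-current signals of one
#' electrode and returns the lag of maximum similarity within +-1 ms
#' (positive: right lags). Mode "envelope" first lowpass filters both
#' channels with a zero-phase 4th-order Butterworth at 60 Hz, isolating the
#' envelope ITD; mode "fine_structure" cross-correlates the pulse trains
#' directly.
#'
#' @param left,right matched \linkS4class{Electrodogram}s.
#' @param electrode electrode index.
#' @param mode "fine_structure" or "envelope".
#' @param maxLagUs analysis window (us; 1000).
#' @return measured ITD in microseconds, or \code{NA} if either channel is
#'   silent on that electrode.
#' @export
measureElectrodeItd <- function(left, right, electrode,
                                mode = c("fine_structure", "envelope"),
                                maxLagUs = 1000) {
  mode <- match.arg(mode)
  stopifnot(left@fs == right@fs,
            ncol(left@current) == ncol(right@current))
  x <- left@current[electrode, ]
  y <- right@current[electrode, ]
  if (all(x == 0) || all(y == 0)) return(NA_real_)
  if (mode == "envelope") {
    bf <- signal::butter(4, 60 / (left@fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
    y <- signal::filtfilt(bf, y)
  }
  maxLag <- round(maxLagUs * 1e-6 * left@fs)
  # exclude envelope-filter transients at the signal edges where possible
  margin <- if (mode == "envelope")
    min(round(0.1 * left@fs), (length(x) - 4 * maxLag) %/% 2) else 0L
  lag <- bestCrossCorrLag(x, y, maxLag, max(margin, 0L))
  lag / left@fs * 1e6
}

#' Interaural level difference of one electrode's signal
#'
#' \code{20 log10(RMS_left / RMS_right)} of the linear current on the
#' selected electrode (dB; positive: left louder).
#'
#' @inheritParams measureElectrodeItd
#' @return ILD in dB, or \code{NA} if either channel is silent.
#' @export
measureElectrodeIld <- function(left, right, electrode) {
  x <- left@current[electrode, ]
  y <- right@current[electrode, ]
  rl <- rmsOf(x); rr <- rmsOf(y)
  if (rl == 0 || rr == 0) return(NA_real_)
  20 * log10(rl / rr)
}

#' Fold azimuths into the frontal hemifield
#'
#' Maps any azimuth (degrees, counterclockwise, 0 = front) to its
#' front-back-folded equivalent in [-90, 90].
#'
#' @param azDeg azimuth(s) in degrees.
#' @return folded azimuth(s).
#' @export
foldFrontBack <- function(azDeg) {
  a <- ((azDeg + 180) %% 360) - 180
  ifelse(a > 90, 180 - a, ifelse(a < -90, -180 - a, a))
}

#' Spherical-head (Woodworth) azimuth-to-ITD map
#'
#' \code{ITD = (a / c) (theta + sin theta)} for a head radius \code{a} and
#' speed of sound \code{c}; azimuths are front-back folded first.
#'
#' @param azDeg azimuth(s) in degrees.
#' @param headRadiusM head radius (m; 0.0875).
#' @param soundSpeed speed of sound (m/s; 343).
#' @return ITD in microseconds.
#' @export
azimuthToItd <- function(azDeg, headRadiusM = 0.0875, soundSpeed = 343) {
  th <- foldFrontBack(azDeg) * pi / 180
  (headRadiusM / soundSpeed) * (th + sin(th)) * 1e6
}

#' Broadband azimuth-to-ILD approximation
#'
#' Sinusoidal broadband approximation \code{ILD = 10 sin(theta)} dB (folded
#' azimuth); stands in for an HRTF-derived lookup.
#'
#' @param azDeg azimuth(s) in degrees.
#' @param maxIldDb ILD at 90 degrees (dB).
#' @return ILD in dB.
#' @export
azimuthToIld <- function(azDeg, maxIldDb = 10) {
  maxIldDb * sin(foldFrontBack(azDeg) * pi / 180)
}

#' Cue bias weight (slope of response bias on imposed bias)
#'
#' Front-back folds true and response azimuths, converts both to cue units
#' with \code{cueMap}, forms the response bias (response cue minus true cue)
#' and returns the ordinary least squares slope of response bias on the
#' imposed bias.
#'
#' @param trueAz,respAz equal-length azimuth vectors (degrees).
#' @param imposed imposed cue bias per trial (cue units).
#' @param cueMap function mapping azimuth (deg) to cue units, e.g.
#'   \code{\link{azimuthToItd}} or \code{\link{azimuthToIld}}.
#' @return fitted slope (dimensionless cue weight).
#' @export
cueBiasWeight <- function(trueAz, respAz, imposed,
                          cueMap = azimuthToItd) {
  stopifnot(length(trueAz) == length(respAz),
            length(imposed) == length(trueAz))
  if (stats::var(imposed) == 0)
    stop("imposed bias is constant; slope undefined")
  bias <- cueMap(foldFrontBack(respAz)) - cueMap(foldFrontBack(trueAz))
  unname(stats::coef(stats::lm(bias ~ imposed))[2])
}

#' Enumerate the localization class grid
#'
#' Cartesian grid of azimuth (0--355 in steps of 5: 72 classes) by elevation
#' (0--60 in steps of 10: 7 classes), 504 classes by default.
#'
#' @param azStep,azMax azimuth step and maximum (degrees).
#' @param elStep,elMax elevation step and maximum (degrees).
#' @return data.frame with columns \code{azimuth}, \code{elevation}.
#' @export
enumerateLocations <- function(azStep = 5, azMax = 355, elStep = 10,
                               elMax = 60) {
  stopifnot(azMax %% azStep == 0, elMax %% elStep == 0)
  grid <- expand.grid(azimuth = seq(0, azMax, by = azStep),
                      elevation = seq(0, elMax, by = elStep))
  grid[order(grid$elevation, grid$azimuth), , drop = FALSE]
}

#' Snap a predicted azimuth to the experiment's speaker locations
#'
#' Returns the nearest experiment location; exact ties are resolved by an
#' equiprobable random draw.
#'
#' @param predAz predicted azimuth (degrees, scalar).
#' @param experimentLocs available speaker azimuths (degrees).
#' @param seed optional integer seed for tie resolution.
#' @return chosen location (degrees).
#' @export
snapToExperimentLocations <- function(predAz, experimentLocs, seed = NULL) {
  stopifnot(length(experimentLocs) >= 1)
  d <- abs(predAz - experimentLocs)
  near <- experimentLocs[d <= min(d) + 1e-9]
  if (length(near) == 1) return(near)
  withSeed(seed, sample(near, 1))
}

#' Word recognition experiment trial protocol
#'
#' One block of \code{nPerCond} trials per SNR-by-noise-type condition plus
#' \code{cleanMultiplier * nPerCond} clean-speech trials; with 3 SNRs, 5
#' noise types and 18 trials per condition this is the 306-trial, 16
#' condition protocol.
#'
#' @param snrs SNR levels (dB).
#' @param noiseTypes character vector of noise types.
#' @param nPerCond stimuli per condition (18).
#' @param cleanMultiplier clean-condition multiplier (2).
#' @return ordered data.frame with columns \code{condition},
#'   \code{noiseType}, \code{snrDb}, \code{trial}.
#' @export
buildWordProtocol <- function(snrs, noiseTypes, nPerCond = 18,
                              cleanMultiplier = 2) {
  rows <- list()
  cond <- 0L
  for (nt in noiseTypes) for (s in snrs) {
    cond <- cond + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, noiseType = nt, snrDb = s, trial = seq_len(nPerCond))
  }
  cond <- cond + 1L
  rows[[length(rows) + 1L]] <- data.frame(
    condition = cond, noiseType = "clean", snrDb = Inf,
    trial = seq_len(cleanMultiplier * nPerCond))
  do.call(rbind, rows)
}
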