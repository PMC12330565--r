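# Cochlear implant sound coding strategies.

ELEC_FS <- 10000   # electrodogram / nerve sample rate (Hz)

electrodePositionsFor <- function(M) seq(8.125, 23.875, length.out = M)

#' Loudness growth function
#'
#' Maps acoustic level (dB SPL) to current level (dB re 1 mA):
#' \code{TL + (MCL - TL) / (1 + exp(-beta (p - p0)))}.
#'
#' @param p acoustic level(s), dB SPL.
#' @param lg a \linkS4class{LoudnessGrowth}.
#' @return current level(s), dB re 1 mA.
#' @examples
#' lg <- LoudnessGrowth(TL = -20, MCL = 0)
#' loudnessGrowth(40, lg)  # midpoint: (TL + MCL) / 2
#' @export
loudnessGrowth <- function(p, lg) {
  lg@TL + (lg@MCL - lg@TL) / (1 + exp(-lg@beta * (p - lg@p0)))
}

# Shared front end: M half-cosine subbands, rectified + 50 Hz lowpass
# envelopes at the electrodogram rate, and the dB SPL envelope view.
ciAnalysis <- function(w, cfg) {
  if (is.na(w@levelDb))
    stop("waveform must be calibrated in dB SPL (use setLevel)")
  stopifnot(w@fs >= 2 * cfg@fHigh, w@fs %% ELEC_FS == 0)
  n <- length(w@samples)
  f <- fftFoldedFreqs(n, w@fs)
  resp <- halfCosineFilterbank(cfg@nElectrodes, cfg@fLow, cfg@fHigh, f)
  sub <- applyFilterbank(w@samples, resp)
  envLin <- rectifyLowpass(sub, cfg@envCutoff, w@fs, ELEC_FS)
  list(subbands = sub, envLin = envLin, envDb = ampToDbSpl(envLin),
       cfs = halfCosineCenters(cfg@nElectrodes, cfg@fLow, cfg@fHigh),
       audioFs = w@fs)
}

#' CI filterbank envelopes
#'
#' ERB-spaced half-cosine analysis filters (150 Hz--10 kHz), half-wave
#' rectification, 50 Hz lowpass (50 ms Kaiser-window FIR), downsampling to
#' 10 kHz and per-sample conversion to dB SPL.
#'
#' @param w calibrated \linkS4class{Waveform}.
#' @param cfg a \linkS4class{StrategyConfig}.
#' @return M x T matrix of envelopes in dB SPL (attribute \code{cfs} holds
#'   the filter center frequencies).
#' @export
ciFilterbankEnvelopes <- function(w, cfg = StrategyConfig()) {
  an <- ciAnalysis(w, cfg)
  out <- an$envDb
  attr(out, "cfs") <- an$cfs
  out
}

activeSet <- function(cfg) {
  if (length(cfg@activeElectrodes)) sort(unique(cfg@activeElectrodes))
  else seq_len(cfg@nElectrodes)
}

# Interleaved pulse-train sample indices per electrode on the 10 kHz grid.
# One shared jitter draw u ~ U[0, 1/rate] plus fixed (k-1)*offset stagger;
# with independentJitter each electrode draws its own u.
pulseIndices <- function(cfg, nSamples, seed, rate = cfg@pulseRate) {
  ipi <- 1 / rate
  act <- activeSet(cfg)
  u <- withSeed(seed, stats::runif(if (cfg@independentJitter)
    cfg@nElectrodes else 1L, 0, ipi))
  dur <- nSamples / ELEC_FS
  out <- vector("list", cfg@nElectrodes)
  for (k in act) {
    u0 <- if (cfg@independentJitter) u[k] else u[1]
    t0 <- u0 + (k - 1) * cfg@interleaveOffset
    tt <- seq(t0, dur, by = ipi)
    idx <- round(tt * ELEC_FS) + 1L
    out[[k]] <- idx[idx >= 1L & idx <= nSamples]
  }
  out
}

newElectrodogram <- function(current, strategy, lg, cfg, meta = list()) {
  meta$configHash <- configHash(list(cfg, lg))
  new("Electrodogram", current = current, fs = ELEC_FS,
      positionsMm = electrodePositionsFor(nrow(current)),
      strategy = strategy, loudness = lg, meta = meta)
}

#' Continuous interleaved sampling (CIS) encoder
#'
#' Monophasic pulse trains at \code{pulseRate} per electrode, temporally
#' interleaved with a fixed 200 us inter-electrode offset and a shared random
#' start jitter drawn from U[0, inter-pulse interval]. Each pulse amplitude
#' is the loudness-growth-compressed envelope at the pulse time.
#'
#' @param w calibrated \linkS4class{Waveform}.
#' @param cfg a \linkS4class{StrategyConfig} with name "CIS".
#' @param lg a \linkS4class{LoudnessGrowth}.
#' @param seed integer seed (jitter).
#' @return an \linkS4class{Electrodogram}.
#' @export
cisEncode <- function(w, cfg = StrategyConfig("CIS"), lg = LoudnessGrowth(),
                      seed = 1) {
  an <- ciAnalysis(w, cfg)
  encodeEnvelopePulses(an, cfg, lg, seed, "CIS")
}

encodeEnvelopePulses <- function(an, cfg, lg, seed, label,
                                 selected = NULL, frameLen = NULL) {
  Tn <- ncol(an$envDb)
  idxList <- pulseIndices(cfg, Tn, seed)
  if (!is.null(selected)) {    # ACE: keep only per-frame selected electrodes
    for (k in seq_len(cfg@nElectrodes)) {
      idx <- idxList[[k]]
      if (!length(idx)) next
      fr <- (idx - 1L) %/% frameLen + 1L
      idxList[[k]] <- idx[selected[k, fr]]
    }
  }
  envList <- lapply(seq_len(cfg@nElectrodes), function(k) {
    idx <- idxList[[k]]
    if (!length(idx)) return(numeric(0))
    an$envDb[k, idx]
  })
  wList <- lapply(envList, function(e) rep(1, length(e)))
  tab <- pulseTableFrom(idxList, envList, wList, lg)
  cur <- fillPulsesFromTable(cfg@nElectrodes, Tn, tab)
  newElectrodogram(cur, label, lg, cfg,
                   meta = list(seed = seed, pulses = tab))
}

# Pulse table: env_db is the pre-compression envelope level (dB SPL) and
# weight the steering weight; amplitude in mA for loudness growth `lg` is
# weight * 10^(loudnessGrowth(env_db, lg) / 20). Keeping env_db allows the
# current-fitting grid search to re-map amplitudes without re-analysis.
pulseTableFrom <- function(idxList, envList, wList, lg) {
  tab <- data.frame(
    electrode = rep(seq_along(idxList), vapply(idxList, length, integer(1))),
    index = unlist(idxList, use.names = FALSE),
    env_db = unlist(envList, use.names = FALSE),
    weight = unlist(wList, use.names = FALSE))
  tab$amp_mA <- tab$weight * dbToMilliamp(loudnessGrowth(tab$env_db, lg))
  tab
}

fillPulsesFromTable <- function(M, Tn, tab) {
  cur <- matrix(0, M, Tn)
  if (nrow(tab)) {
    lin <- (tab$index - 1) * M + tab$electrode
    agg <- rowsum(tab$amp_mA, lin)          # same-sample collisions add
    cur[as.numeric(rownames(agg))] <- agg
  }
  cur
}

# Rebuild an electrodogram from a pulse table under different current
# settings (used by the variance-maximization grid search).
remapPulses <- function(eg, lg) {
  tab <- eg@meta$pulses
  tab$amp_mA <- tab$weight * dbToMilliamp(loudnessGrowth(tab$env_db, lg))
  cur <- fillPulsesFromTable(nrow(eg@current), ncol(eg@current), tab)
  meta <- eg@meta; meta$pulses <- tab
  new("Electrodogram", current = cur, fs = eg@fs,
      positionsMm = eg@positionsMm, strategy = eg@strategy, loudness = lg,
      meta = meta)
}

#' Advanced combination encoder (ACE, N-of-M)
#'
#' CIS-style interleaved pulse trains at 800 pps, but in each non-overlapping
#' 2 ms frame only the \code{nMaxima} electrodes whose compressed envelopes
#' have the highest mean amplitude are stimulated; the remaining electrodes
#' are silent for that frame. Ties break toward the lower (more apical)
#' electrode index.
#'
#' @inheritParams cisEncode
#' @param cfg a \linkS4class{StrategyConfig} with name "ACE" (16 electrodes,
#'   8 maxima, 2 ms frames, 800 pps).
#' @return an \linkS4class{Electrodogram}.
#' @export
aceEncode <- function(w, cfg = StrategyConfig("ACE"), lg = LoudnessGrowth(),
                      seed = 1) {
  an <- ciAnalysis(w, cfg)
  Tn <- ncol(an$envDb)
  frameLen <- max(1L, round(cfg@frameMs * 1e-3 * ELEC_FS))
  nFrames <- (Tn - 1L) %/% frameLen + 1L
  fr <- (seq_len(Tn) - 1L) %/% frameLen + 1L
  # loudness growth is monotone, so ranking the dB envelope equals ranking
  # the compressed envelope
  frameMean <- t(apply(an$envDb, 1, function(r) rowsum(r, fr) / tabulate(fr)))
  selected <- matrix(FALSE, cfg@nElectrodes, nFrames)
  act <- activeSet(cfg)
  for (f in seq_len(nFrames)) {
    ord <- act[order(-frameMean[act, f], act)]
    selected[ord[seq_len(min(cfg@nMaxima, length(ord)))], f] <- TRUE
  }
  encodeEnvelopePulses(an, cfg, lg, seed, "ACE", selected, frameLen)
}

#' Fine structure processing (FSP) encoder
#'
#' The \code{nFineStructure} most apical electrodes fire one pulse per 1 ms
#' analysis frame at the time of the frame's maximum of the half-wave
#' rectified subband (no pulse when the frame is below the silence floor),
#' conveying temporal fine structure; the remaining basal electrodes are
#' driven as in CIS at 800 pps.
#'
#' @inheritParams cisEncode
#' @param cfg a \linkS4class{StrategyConfig} with name "FSP".
#' @return an \linkS4class{Electrodogram}.
#' @export
fspEncode <- function(w, cfg = StrategyConfig("FSP"), lg = LoudnessGrowth(),
                      seed = 1) {
  an <- ciAnalysis(w, cfg)
  Tn <- ncol(an$envDb)
  act <- activeSet(cfg)
  apical <- act[act <= cfg@nFineStructure]
  fsA <- an$audioFs
  frameA <- max(1L, round(cfg@frameMs * 1e-3 * fsA))
  floorAmp <- dbSplToAmp(DB_SPL_FLOOR)
  idxList <- pulseIndices(cfg, Tn, seed)       # basal CIS grid
  for (k in apical) idxList[[k]] <- integer(0)
  for (k in apical) {
    hw <- pmax(an$subbands[k, ], 0)
    n <- length(hw)
    # local temporal maxima of the rectified subband (carrier peaks)
    isMax <- c(FALSE, hw[2:(n - 1)] >= hw[1:(n - 2)] &
                 hw[2:(n - 1)] > hw[3:n], FALSE) & hw > floorAmp
    cand <- which(isMax)
    nF <- (n - 1L) %/% frameA + 1L
    idx <- integer(0)
    for (f in seq_len(nF)) {
      a <- (f - 1L) * frameA + 1L
      b <- min(f * frameA, n)
      inFrame <- cand[cand >= a & cand <= b]
      if (!length(inFrame)) next          # at most one pulse per 1 ms frame
      best <- inFrame[which.max(hw[inFrame])]
      i10 <- round((best - 1L) / fsA * ELEC_FS) + 1L
      if (i10 >= 1L && i10 <= Tn) idx <- c(idx, i10)
    }
    idxList[[k]] <- unique(idx)
  }
  envList <- lapply(seq_len(cfg@nElectrodes), function(k) {
    idx <- idxList[[k]]
    if (!length(idx)) return(numeric(0))
    an$envDb[k, idx]
  })
  wList <- lapply(envList, function(e) rep(1, length(e)))
  tab <- pulseTableFrom(idxList, envList, wList, lg)
  cur <- fillPulsesFromTable(cfg@nElectrodes, Tn, tab)
  newElectrodogram(cur, "FSP", lg, cfg, meta = list(seed = seed, pulses = tab))
}

#' Simplified HiRes120 current-steering encoder
#'
#' Adjacent electrode pairs (15 pairs for 16 electrodes) emit synchronized
#' pulse pairs once per 2 ms analysis frame. For each pair and frame the
#' spectral peak within the pair's passband is estimated (zero-padded FFT
#' argmax of the summed subband) and mapped to a steering coefficient
#' \code{alpha} in \{0, 1/8, ..., 7/8\}; the two pulse amplitudes are
#' \code{(1-alpha) A} and \code{alpha A} in linear current, where \code{A}
#' is the loudness-growth-compressed pair envelope (carrier-synthesis peak:
#' the pair envelope modulated at the spectral peak frequency). 15 pairs x 8
#' steps give 120 virtual stimulation sites. This is a deliberately
#' simplified re-implementation of the commercial strategy, with automatic
#' gain control and noise reduction disabled.
#'
#' @inheritParams cisEncode
#' @param cfg a \linkS4class{StrategyConfig} with name "HIRES120".
#' @return an \linkS4class{Electrodogram}.
#' @export
hires120Encode <- function(w, cfg = StrategyConfig("HIRES120"),
                           lg = LoudnessGrowth(), seed = 1) {
  an <- ciAnalysis(w, cfg)
  M <- cfg@nElectrodes
  Tn <- ncol(an$envDb)
  fsA <- an$audioFs
  nPairs <- M - 1L
  pairSub <- an$subbands[seq_len(nPairs), , drop = FALSE] +
    an$subbands[2:M, , drop = FALSE]
  pairEnv <- rectifyLowpass(pairSub, cfg@envCutoff, fsA, ELEC_FS)
  frameA <- max(1L, round(cfg@frameMs * 1e-3 * fsA))
  frame10 <- max(1L, round(cfg@frameMs * 1e-3 * ELEC_FS))
  nF <- (ncol(pairSub) - 1L) %/% frameA + 1L
  nfft <- 1024L
  u <- withSeed(seed, stats::runif(1, 0, cfg@frameMs * 1e-3))
  jit10 <- round(u * ELEC_FS)
  cfs <- an$cfs
  floorAmp <- dbSplToAmp(DB_SPL_FLOOR)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(frameA) / (frameA + 1))
  idxList <- rep(list(integer(0)), M)
  envList <- rep(list(numeric(0)), M)
  wList <- rep(list(numeric(0)), M)
  for (m in seq_len(nPairs)) {
    stagger <- round((m - 1) * frame10 / nPairs)
    for (f in seq_len(nF)) {
      aA <- (f - 1L) * frameA + 1L
      bA <- min(f * frameA, ncol(pairSub))
      seg <- pairSub[m, aA:bA]
      if (max(abs(seg)) <= floorAmp) next
      segw <- seg * win[seq_along(seg)]
      sp <- Mod(stats::fft(c(segw, numeric(nfft - length(segw)))))
      fgrid <- (0:(nfft / 2)) * fsA / nfft
      inb <- which(fgrid >= cfs[m] & fgrid <= cfs[m + 1])
      if (!length(inb)) next
      fpk <- fgrid[inb[which.max(sp[inb])]]
      q <- (fpk - cfs[m]) / (cfs[m + 1] - cfs[m])
      alpha <- min(floor(pmin(pmax(q, 0), 1) * 8 + 0.5), 7) / 8
      i10 <- (f - 1L) * frame10 + 1L + stagger + jit10
      if (i10 < 1L || i10 > Tn) next
      frIdx <- ((f - 1L) * frame10 + 1L):min(f * frame10, Tn)
      tfr <- (frIdx - 1) / ELEC_FS
      carrier <- pairEnv[m, frIdx] * pmax(0, sin(2 * pi * fpk * tfr))
      A <- max(carrier)
      if (A <= floorAmp) next
      Adb <- ampToDbSpl(A)
      if (alpha < 1) {
        idxList[[m]] <- c(idxList[[m]], i10)
        envList[[m]] <- c(envList[[m]], Adb)
        wList[[m]] <- c(wList[[m]], 1 - alpha)
      }
      if (alpha > 0) {
        idxList[[m + 1L]] <- c(idxList[[m + 1L]], i10)
        envList[[m + 1L]] <- c(envList[[m + 1L]], Adb)
        wList[[m + 1L]] <- c(wList[[m + 1L]], alpha)
      }
    }
  }
  tab <- pulseTableFrom(idxList, envList, wList, lg)
  cur <- fillPulsesFromTable(M, Tn, tab)
  newElectrodogram(cur, "HIRES120", lg, cfg,
                   meta = list(seed = seed, nSteeringSites = nPairs * 8L,
                               pulses = tab))
}

#' Encode with any strategy by name
#'
#' @inheritParams cisEncode
#' @param cfg a \linkS4class{StrategyConfig}; its \code{name} selects the
#'   encoder.
#' @return an \linkS4class{Electrodogram}.
#' @export
encodeStrategy <- function(w, cfg, lg = LoudnessGrowth(), seed = 1) {
  switch(cfg@name,
         CIS = cisEncode(w, cfg, lg, seed),
         ACE = aceEncode(w, cfg, lg, seed),
         FSP = fspEncode(w, cfg, lg, seed),
         HIRES120 = hires120Encode(w, cfg, lg, seed),
         stop("unknown strategy: ", cfg@name))
}
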