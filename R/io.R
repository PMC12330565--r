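# File round-trips: WAV audio, nervegram/electrodogram containers, pulse
# tables.

AUDIO_FS <- 20000   # internal audio sample rate (Hz)

#' Read a WAV file as a Waveform
#'
#' Minimal RIFF/WAVE reader supporting PCM 16/24-bit and IEEE float32 mono
#' or stereo files. Multichannel audio is either averaged to mono or a
#' single channel is selected; audio is resampled to the internal 20 kHz
#' rate unless \code{resample = FALSE}.
#'
#' @param path input file.
#' @param channel "mix", or a channel number.
#' @param resample resample to 20 kHz (default TRUE).
#' @return a \linkS4class{Waveform} (uncalibrated; samples in [-1, 1]).
#' @export
readWave <- function(path, channel = "mix", resample = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1, 2, endian = "little",
                              signed = FALSE),
        nChannels = readBin(con, "integer", 1, 2, endian = "little"),
        fs = readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 4, endian = "little"))  # byteRate
      invisible(readBin(con, "integer", 1, 2, endian = "little"))  # align
      fmt$bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV file: ", path)
  x <- decodeWavData(dat, fmt)
  if (fmt$nChannels > 1) {
    m <- matrix(x, nrow = fmt$nChannels)
    x <- if (identical(channel, "mix")) colMeans(m)
    else m[as.integer(channel), ]
  }
  fs <- fmt$fs
  if (resample && fs != AUDIO_FS) {
    r <- ratApprox(AUDIO_FS / fs)
    x <- as.numeric(signal::resample(x, r[1], r[2]))
    fs <- AUDIO_FS
  }
  Waveform(x, fs)
}

decodeWavData <- function(dat, fmt) {
  if (fmt$audioFormat == 3 && fmt$bits == 32) {
    readBin(dat, "double", length(dat) / 4, 4, endian = "little")
  } else if (fmt$audioFormat == 1 && fmt$bits == 16) {
    readBin(dat, "integer", length(dat) / 2, 2, endian = "little",
            signed = TRUE) / 32768
  } else if (fmt$audioFormat == 1 && fmt$bits == 24) {
    n <- length(dat) / 3
    b <- as.integer(dat)
    v <- b[seq(1, by = 3, length.out = n)] +
      256 * b[seq(2, by = 3, length.out = n)] +
      65536 * b[seq(3, by = 3, length.out = n)]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else stop("unsupported WAV encoding (PCM16/24 or float32 only)")
}

ratApprox <- function(x, maxDen = 1000) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(maxDen)) {
    p <- round(x * q)
    e <- abs(x - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), q) }
    if (err == 0) break
  }
  best
}

#' Write a Waveform to a WAV file
#'
#' @param w a \linkS4class{Waveform}.
#' @param path output file.
#' @param bits 16 or 24 (PCM) or 32 (IEEE float).
#' @param normalize rescale peaks to 0.999 before integer quantization
#'   (PCM only; keeps calibrated float files exact).
#' @return \code{path}, invisibly.
#' @export
writeWave <- function(w, path, bits = 16, normalize = TRUE) {
  x <- w@samples
  if (bits != 32 && normalize && max(abs(x)) > 0)
    x <- x / max(abs(x)) * 0.999
  con <- file(path, "wb")
  on.exit(close(con))
  bytes <- bits / 8
  dataSize <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (bits == 32) 3L else 1L, 1L), con, 2, endian = "little")
  writeBin(as.integer(w@fs), con, 4, endian = "little")
  writeBin(as.integer(w@fs * bytes), con, 4, endian = "little")
  writeBin(c(as.integer(bytes), as.integer(bits)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4, endian = "little")
  if (bits == 32) {
    writeBin(x, con, 4, endian = "little")
  } else if (bits == 16) {
    writeBin(as.integer(pmax(pmin(round(x * 32767), 32767), -32768)),
             con, 2, endian = "little")
  } else if (bits == 24) {
    v <- as.integer(pmax(pmin(round(x * 8388607), 8388607), -8388608))
    v <- ifelse(v < 0, v + 16777216L, v)
    raw3 <- as.raw(rbind(v %% 256L, (v %/% 256L) %% 256L, v %/% 65536L))
    writeBin(raw3, con)
  } else stop("bits must be 16, 24 or 32")
  invisible(path)
}

#' Nervegram and electrodogram round-trips
#'
#' Serializes the container arrays with their sample rate, channel metadata
#' and config hash; \code{readNervegram}/\code{readElectrodogram} restore
#' identical objects.
#'
#' @param ng a \linkS4class{Nervegram}.
#' @param path output file.
#' @return \code{path} (writers, invisibly); the restored object (readers).
#' @export
writeNervegram <- function(ng, path) {
  saveRDS(list(rates = ng@rates, spikes = ng@spikes,
               channelCfs = ng@channelCfs, fs = ng@fs, meta = ng@meta),
          path)
  invisible(path)
}

#' @rdname writeNervegram
#' @export
readNervegram <- function(path) {
  l <- readRDS(path)
  new("Nervegram", rates = l$rates, spikes = l$spikes,
      channelCfs = l$channelCfs, fs = l$fs, meta = l$meta)
}

#' @rdname writeNervegram
#' @param eg an \linkS4class{Electrodogram}.
#' @export
writeElectrodogram <- function(eg, path) {
  saveRDS(list(current = eg@current, fs = eg@fs,
               positionsMm = eg@positionsMm, strategy = eg@strategy,
               loudness = c(TL = eg@loudness@TL, MCL = eg@loudness@MCL,
                            beta = eg@loudness@beta, p0 = eg@loudness@p0),
               meta = eg@meta),
          path)
  invisible(path)
}

#' @rdname writeNervegram
#' @export
readElectrodogram <- function(path) {
  l <- readRDS(path)
  new("Electrodogram", current = l$current, fs = l$fs,
      positionsMm = l$positionsMm, strategy = l$strategy,
      loudness = LoudnessGrowth(l$loudness["TL"], l$loudness["MCL"],
                                l$loudness["beta"], l$loudness["p0"]),
      meta = l$meta)
}

#' Pulse table of an electrodogram
#'
#' @param eg an \linkS4class{Electrodogram}.
#' @return data.frame with columns \code{electrode}, \code{time_us},
#'   \code{amplitude_db_re_1ma}.
#' @export
pulseTable <- function(eg) {
  tab <- eg@meta$pulses
  data.frame(electrode = tab$electrode,
             time_us = (tab$index - 1) / eg@fs * 1e6,
             amplitude_db_re_1ma = 20 * log10(tab$amp_mA))
}

#' @rdname pulseTable
#' @param path output CSV file.
#' @export
writePulseTable <- function(eg, path) {
  utils::write.csv(pulseTable(eg), path, row.names = FALSE)
  invisible(path)
}

#' Spread profile export
#'
#' Relative field of a single active electrode as a function of nerve
#' position, for CSV export.
#'
#' @param sm a \linkS4class{SpreadModel}.
#' @param electrode electrode index.
#' @return data.frame with columns \code{position_mm},
#'   \code{relative_field}.
#' @export
spreadProfile <- function(sm, electrode = 1) {
  x <- sm@nervePositionsMm
  data.frame(position_mm = x,
             relative_field = sm@V0 *
               exp(-abs(x - sm@electrodePositionsMm[electrode]) /
                     sm@lambdaMm))
}
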