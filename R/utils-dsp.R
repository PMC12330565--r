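# Shared DSP and numeric helpers (internal).

PREF_PA <- 20e-6             # reference pressure, 20 uPa
DB_SPL_FLOOR <- -30          # floor for amplitude -> dB SPL conversion
DB_CURRENT_FLOOR <- -100     # floor for field -> dB re 1 mA conversion

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded package internals do not
#' disturb the caller's RNG stream. A \code{NULL} seed runs the expression
#' against the current stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derivation; keeps results within 32-bit range.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435.0 + 97.0 * as.double(k)) %% 2147483629)
}

#' Glasberg-Moore ERB-number scale
#' @noRd
erbNumber <- function(f) 21.4 * log10(0.00437 * f + 1)

erbInverse <- function(e) (10^(e / 21.4) - 1) / 0.00437

# Equivalent rectangular bandwidth (Hz) at frequency f (Hz).
erbBandwidth <- function(f) 24.7 * (0.00437 * f + 1)

# Frequencies of the length-n DFT grid folded onto [0, fs/2]; evaluating a
# real, symmetric transfer function at these points yields a zero-phase filter.
fftFoldedFreqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

# Apply a bank of zero-phase filters (rows of `responses`, sampled on the
# folded DFT grid of length(x)) to a signal by frequency-domain multiplication.
applyFilterbank <- function(x, responses) {
  n <- length(x)
  stopifnot(ncol(responses) == n)
  X <- stats::fft(x)
  Y <- t(responses) * X                      # n x nFilters
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  t(out)                                     # nFilters x n
}

# Linear-phase FIR lowpass (Kaiser window), returns coefficients with odd
# length so the group delay is an integer number of samples.
firKaiserLowpass <- function(cutoffHz, fs, lengthSec = 0.05, beta = 8.6) {
  L <- round(lengthSec * fs)
  if (L %% 2 == 0) L <- L + 1
  h <- signal::fir1(L - 1, cutoffHz / (fs / 2), type = "low",
                    window = signal::kaiser(L, beta))
  as.numeric(h)
}

# FFT-based "same" convolution of each row with a linear-phase FIR; the
# group delay (len-1)/2 is removed so output is time-aligned with input.
filterRowsSame <- function(m, h) {
  n <- ncol(m)
  L <- length(h)
  delay <- (L - 1) / 2
  nf <- stats::nextn(n + L - 1, c(2, 3, 5))   # keep FFT lengths smooth
  H <- stats::fft(c(h, numeric(nf - L)))
  X <- stats::mvfft(t(cbind(m, matrix(0, nrow(m), nf - n))))
  Y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nf
  t(Y)[, (delay + 1):(delay + n), drop = FALSE]
}

# Causal convolution of each row with a kernel; output truncated to ncol(m).
convolveRowsCausal <- function(m, k) {
  n <- ncol(m)
  L <- length(k)
  nf <- stats::nextn(n + L - 1, c(2, 3, 5))
  K <- stats::fft(c(k, numeric(nf - L)))
  X <- stats::mvfft(t(cbind(m, matrix(0, nrow(m), nf - n))))
  Y <- Re(stats::mvfft(X * K, inverse = TRUE)) / nf
  t(Y)[, seq_len(n), drop = FALSE]
}

# Magnitude of the analytic signal (Hilbert envelope) of each row.
hilbertEnvelopeRows <- function(m) {
  n <- ncol(m)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(t(m)) * w
  Mod(t(stats::mvfft(X, inverse = TRUE)) / n)
}

# Delay a signal by a (possibly fractional) number of samples using a
# frequency-domain phase shift; the signal is zero-padded so the shift is a
# true delay rather than a rotation.
fractionalDelay <- function(x, delaySamples) {
  n <- length(x)
  pad <- ceiling(abs(delaySamples)) + 8
  nf <- n + 2 * pad
  xf <- c(numeric(pad), x, numeric(pad))
  X <- stats::fft(xf)
  k <- c(0:(floor(nf / 2)), -(ceiling(nf / 2) - 1):-1)
  if (nf %% 2 == 0) k[nf / 2 + 1] <- nf / 2   # Nyquist bin kept real below
  ph <- exp(-2i * pi * k * delaySamples / nf)
  if (nf %% 2 == 0) ph[nf / 2 + 1] <- cos(2 * pi * (nf / 2) * delaySamples / nf)
  y <- Re(stats::fft(X * ph, inverse = TRUE)) / nf
  y[(pad + 1):(pad + n)]
}

# Lag (in samples) maximizing the unbiased cross-correlation of the
# demeaned signals, |lag| <= maxLag. Demeaning and overlap normalization
# keep broad, DC-heavy correlation functions (lowpassed envelopes) from
# being biased toward zero lag. Positive lag means y lags x.
# Shifting only y over a fixed interior window keeps the estimator exact
# for a pure delay; the margin additionally excludes filter onset/offset
# transients, which otherwise bias the very flat correlation functions of
# lowpassed envelopes.
bestCrossCorrLag <- function(x, y, maxLag, margin = 0L) {
  n <- length(x)
  stopifnot(length(y) == n, 2 * (maxLag + margin) < n)
  x <- x - mean(x); y <- y - mean(y)
  w <- (maxLag + margin + 1L):(n - maxLag - margin)
  lags <- -maxLag:maxLag
  nx <- sqrt(sum(x[w]^2))
  cc <- vapply(lags, function(k) {
    yy <- y[w + k]
    d <- nx * sqrt(sum(yy^2))
    if (d == 0) return(-Inf)
    sum(x[w] * yy) / d           # normalized: a pure shift scores exactly 1
  }, numeric(1))
  best <- which(cc >= max(cc) - 1e-12)
  lags[best[which.min(abs(lags[best]))]]   # ties resolve to the smaller lag
}

ampToDbSpl <- function(a, floorDb = DB_SPL_FLOOR) {
  floorAmp <- PREF_PA * 10^(floorDb / 20)
  20 * log10(pmax(a, floorAmp) / PREF_PA)
}

dbSplToAmp <- function(db) PREF_PA * 10^(db / 20)

# Current level conversions (amplitude convention, dB re 1 mA).
dbToMilliamp <- function(db) 10^(db / 20)

milliampToDb <- function(ma, floorDb = DB_CURRENT_FLOOR) {
  20 * log10(pmax(ma, 10^(floorDb / 20)))
}

rmsOf <- function(x) sqrt(mean(x^2))

# Small deterministic FNV-1a style hash of an R object, for config stamping.
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
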