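# Filterbank construction on the ERB scale.

#' ERB-spaced center frequencies
#'
#' Places \code{n} frequencies uniformly on the Glasberg--Moore ERB-number
#' scale between \code{fmin} and \code{fmax} (both included).
#'
#' @param fmin,fmax frequency range (Hz), 0 < fmin < fmax.
#' @param n number of frequencies (>= 2).
#' @return numeric vector of length \code{n}, strictly increasing.
#' @examples
#' erbSpace(60, 12000, 50)
#' @export
erbSpace <- function(fmin, fmax, n) {
  stopifnot(fmin > 0, fmax > fmin, n >= 2)
  e <- seq(erbNumber(fmin), erbNumber(fmax), length.out = n)
  f <- erbInverse(e)
  f[1] <- fmin; f[n] <- fmax
  f
}

#' Squared-cosine (half-cosine) filterbank transfer functions
#'
#' Builds \code{n} zero-phase bandpass transfer functions whose squared-cosine
#' lobes sit on the ERB-number axis with 50\% overlap, so that adjacent
#' transfer functions sum to 1 and the bank perfectly tiles
#' \code{[fmin, fmax]}. The first and last filters are clamped to 1 below and
#' above their centers so tiling holds to the band edges.
#'
#' @param n number of filters.
#' @param fmin,fmax band edges (Hz).
#' @param freqs frequencies (Hz) at which to sample the transfer functions.
#' @return \code{n x length(freqs)} matrix of filter gains in [0, 1].
#' @export
halfCosineFilterbank <- function(n, fmin, fmax, freqs) {
  stopifnot(n >= 1, fmin > 0, fmax > fmin)
  eLo <- erbNumber(fmin); eHi <- erbNumber(fmax)
  e <- erbNumber(pmax(freqs, 1e-9))
  if (n == 1L) {
    resp <- matrix(0, 1, length(freqs))
    resp[1, e >= eLo & e <= eHi] <- 1
    return(resp)
  }
  s <- (eHi - eLo) / (n - 1)
  centers <- eLo + (seq_len(n) - 1) * s
  resp <- matrix(0, n, length(freqs))
  for (k in seq_len(n)) {
    d <- e - centers[k]
    inl <- abs(d) < s
    resp[k, inl] <- cos(pi * d[inl] / (2 * s))^2
    if (k == 1L) resp[k, d <= 0 & e >= 0] <- 1
    if (k == n)  resp[k, d >= 0] <- 1
  }
  resp[, e < 0 | freqs <= 0] <- 0
  resp
}

#' @rdname halfCosineFilterbank
#' @details \code{halfCosineCenters} returns the center frequencies (Hz) of
#'   the bank.
#' @export
halfCosineCenters <- function(n, fmin, fmax) erbSpace(fmin, fmax, n)

#' Rounded-exponential (roex) filter transfer functions
#'
#' Symmetric roex(p) magnitude response \code{(1 + p g) exp(-p g)} with
#' \code{g = |f - cf| / cf} and \code{p = 4 cf / ERB(cf)}; unity gain at the
#' center frequency.
#'
#' @param cf center frequency (Hz).
#' @param freqs frequencies (Hz) at which to sample the response.
#' @return numeric vector of gains.
#' @export
roexResponse <- function(cf, freqs) {
  p <- 4 * cf / erbBandwidth(cf)
  g <- abs(freqs - cf) / cf
  (1 + p * g) * exp(-p * g)
}
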