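# Deterministic synthetic fixture generation (WAV file sets).

#' Generate the synthetic fixture WAV set
#'
#' Writes a deterministic set of test stimuli: pure tones, a 300 Hz--10 kHz
#' noise burst, amplitude-modulated narrowband noises centered at each CI
#' electrode filter frequency, and AM harmonic complexes ("speech-like")
#' clean and mixed with noise at SNRs from -24 to +18 dB in 3 dB steps.
#' The same seed yields byte-identical files.
#'
#' @param outDir writable output directory.
#' @param seed integer seed.
#' @param fs sample rate (Hz).
#' @return data.frame manifest (file, kind, parameter).
#' @export
makeFixtures <- function(outDir, seed = 1, fs = 20000) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  man <- list()
  add <- function(w, name, kind, par) {
    writeWave(w, file.path(outDir, name))
    man[[length(man) + 1L]] <<- data.frame(file = name, kind = kind,
                                           parameter = par)
  }
  for (f in c(500, 1000, 2000))
    add(makeTone(f, 0.5, fs, 60, rampSec = 5e-3),
        sprintf("tone_%dhz.wav", f), "tone", f)
  add(makeNoiseBurst(c(300, 10000), 0.1, 1e-3, fs, 60, seed = seed),
      "noise_burst_300_10000.wav", "noise_burst", NA)
  cfs <- halfCosineCenters(16, 150, 10000)
  for (k in seq_along(cfs))
    add(makeAmNarrowbandNoise(cfs[k], bw = 80, modRate = 40, depth = 1,
                              dur = 0.5, fs = fs, levelDb = 60,
                              seed = deriveSeed(seed, k)),
        sprintf("am_nbn_e%02d.wav", k), "am_narrowband_noise", cfs[k])
  snrs <- seq(-24, 18, by = 3)
  clean <- makeHarmonicComplex(dur = 0.5, fs = fs, levelDb = 60,
                               seed = deriveSeed(seed, 100))
  add(clean, "harmonic_clean.wav", "harmonic_complex", Inf)
  for (s in snrs) {
    noise <- withSeed(deriveSeed(seed, 200 + s),
                      Waveform(stats::rnorm(length(clean@samples)), fs))
    add(mixAtSnr(clean, setLevel(noise, 60), s),
        sprintf("harmonic_snr_%+03d.wav", s), "harmonic_in_noise", s)
  }
  do.call(rbind, man)
}
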