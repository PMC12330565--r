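# Waveform construction, calibration and binaural cue imposition.

test_that("level calibration round-trips and obeys log identities", {
  w <- setLevel(tone1k(), 60)
  expect_equal(measureLevel(w), 60, tolerance = 1e-9)
  # x10 amplitude = +20 dB
  w10 <- Waveform(samples(w) * 10, sampleRate(w))
  expect_equal(measureLevel(w10), 80, tolerance = 1e-9)
  # unit-RMS signal: 20*log10(1 / 2e-5)
  wu <- Waveform(samples(w) / sqrt(mean(samples(w)^2)), 20000)
  expect_equal(measureLevel(wu), 20 * log10(1 / 2e-5), tolerance = 1e-9)
  expect_equal(measureLevel(wu), 93.9794, tolerance = 1e-4)
  # shape unchanged by calibration
  expect_equal(cor(samples(w), samples(setLevel(w, 40))), 1)
  expect_error(setLevel(Waveform(numeric(100)), 60), "all-zero")
  expect_error(measureLevel(Waveform(numeric(10))), "undefined")
})

test_that("round-trip exactness holds for arbitrary non-silent waveforms", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(512))
    lvl <- withr::with_seed(seed, runif(1, -20, 90))
    expect_equal(measureLevel(setLevel(Waveform(x), lvl)), lvl,
                 tolerance = 1e-6 / abs(lvl + 1))
  }
})

test_that("tone generator honors duration, level and spectrum", {
  w <- makeTone(1000, 1, 20000, 60)
  expect_length(samples(w), 20000)
  expect_equal(measureLevel(w), 60, tolerance = 1e-9)
  sp <- Mod(fft(samples(w)))[1:10000]
  expect_equal(which.max(sp), 1000 + 1)   # bin spacing 1 Hz
  expect_error(makeTone(11000, 0.1, 20000), "Nyquist")
})

test_that("noise bursts are band-limited, ramped and reproducible", {
  w <- makeNoiseBurst(c(300, 10000), 0.1, 1e-3, 20000, 60, seed = 4)
  expect_length(samples(w), 2000)
  sp <- Mod(fft(samples(w)))^2
  f <- (0:1999) * 10
  inband <- mean(sp[f >= 350 & f <= 9000])
  outband <- mean(sp[f > 10 & f < 250])
  expect_gt(10 * log10(inband / outband), 40)
  w2 <- makeNoiseBurst(c(300, 10000), 0.1, 1e-3, 20000, 60, seed = 4)
  expect_identical(samples(w), samples(w2))
  expect_error(makeNoiseBurst(c(300, 1000), dur = 0.001, rampSec = 1e-3),
               "ramps")
})

test_that("AM narrowband noise carries its modulation in the envelope", {
  # depth 0 equals the unmodulated band (up to the post-gate refilter the
  # plain burst applies)
  w0 <- makeAmNarrowbandNoise(1000, 80, 40, depth = 0, dur = 0.5, seed = 2)
  ref <- makeNoiseBurst(c(960, 1040), 0.5, 1e-3, 20000, 60, seed = 2)
  expect_equal(cor(samples(w0), samples(ref)), 1, tolerance = 1e-4)
  # depth 1: Hilbert envelope spectrum peaks at the 40 Hz modulation rate
  w1 <- makeAmNarrowbandNoise(1000, 80, 40, depth = 1, dur = 1, seed = 2)
  env <- cochsim:::hilbertEnvelopeRows(matrix(samples(w1), 1))[1, ]
  env <- env - mean(env)
  sp <- Mod(fft(env))[2:100]          # 1..99 Hz at 1 Hz spacing
  expect_equal(which.max(sp) + 0, 40, tolerance = 1)
})

test_that("imposed ITD/ILD act on the right channels with the right signs", {
  w <- makeNoiseBurst(c(300, 5000), 0.2, 1e-3, seed = 9)
  same <- imposeItdIld(w, w, 0, 0)
  expect_equal(samples(same$left), samples(w))
  expect_equal(samples(same$right), samples(w))
  # +500 us at 20 kHz = exactly 10 samples of right-channel lag
  sh <- imposeItdIld(w, w, itdUs = 500)
  n <- length(samples(w))
  expect_equal(samples(sh$right)[11:n], samples(w)[1:(n - 10)],
               tolerance = 1e-10)
  # +10 dB ILD: left/right RMS ratio
  ld <- imposeItdIld(w, w, ildDb = 10)
  expect_equal(20 * log10(sd(samples(ld$left)) / sd(samples(ld$right))),
               10, tolerance = 1e-6)
})

test_that("cross-correlation recovers imposed delays to one lag step", {
  w <- makeNoiseBurst(c(300, 5000), 0.3, 1e-3, seed = 11)
  for (itd in c(-700, -250, 150, 900)) {
    pair <- imposeItdIld(w, w, itdUs = itd)
    lag <- cochsim:::bestCrossCorrLag(samples(pair$left),
                                      samples(pair$right),
                                      maxLag = 25)
    expect_equal(lag * 1e6 / 20000, itd, tolerance = 50 + 1e-9)
  }
})

test_that("SNR mixing achieves the requested ratio by construction", {
  sig <- tone1k(0.2)
  noise <- setLevel(Waveform(withr::with_seed(1, rnorm(4000))), 60)
  for (snr in c(-12, 0, 9)) {
    mixed <- mixAtSnr(sig, noise, snr)
    resid <- samples(mixed) / max(abs(samples(mixed)))
    # recompute realized SNR from the known components
    g <- 10^(-snr / 20) * sd(samples(sig)) / sd(samples(noise))
    expect_equal(20 * log10(sd(samples(sig)) / sd(g * samples(noise))),
                 snr, tolerance = 0.01)
    expect_equal(measureLevel(mixed), 60, tolerance = 1e-6)
  }
  expect_identical(mixAtSnr(sig, noise, Inf), sig)
})
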