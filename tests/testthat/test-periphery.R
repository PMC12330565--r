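# Acoustic auditory nerve model.

test_that("ERB spacing is uniform with exact endpoints", {
  expect_equal(erbSpace(100, 8000, 2), c(100, 8000))
  cfs <- erbSpace(60, 12000, 50)
  expect_length(cfs, 50)
  expect_true(all(diff(cfs) > 0))
  expect_equal(cfs[1], 60)
  expect_equal(cfs[50], 12000)
  e <- 21.4 * log10(0.00437 * cfs + 1)
  expect_lt(max(abs(diff(e) - diff(e)[1])), 1e-9)
})

test_that("roex filterbank peaks at CF and passes silence through", {
  cfs <- erbSpace(60, 12000, 50)
  cfg <- CochleaConfig()
  for (k in c(10, 25, 40)) {
    w <- setLevel(makeTone(cfs[k], 0.2), 60)
    sub <- roexFilterbank(w, cfg)
    expect_equal(nrow(sub), 50)
    expect_equal(which.max(apply(sub, 1, function(r) mean(r^2))), k)
  }
  zero <- roexFilterbank(Waveform(numeric(1000), 20000), cfg)
  expect_true(all(abs(zero) < 1e-12))
  expect_error(roexFilterbank(Waveform(1, 20000), cfg), "short")
})

test_that("rectify-lowpass keeps slow structure, removes fine structure", {
  cfg <- CochleaConfig()
  # 100 Hz content survives the 3 kHz lowpass
  w <- setLevel(makeTone(100, 0.5), 60)
  env <- rectifyLowpass(matrix(samples(w), 1), 3000, 20000, 10000)
  expect_equal(ncol(env), 5000)
  expect_true(all(env >= 0))
  i <- 1001:4000
  sp <- Mod(fft(env[1, i] - mean(env[1, i])))
  fgrid <- (seq_along(i) - 1) / length(i) * 10000
  expect_lt(abs(fgrid[which.max(sp[fgrid < 5000])] - 100), 5)
  # a 5 kHz carrier leaves only a near-constant envelope
  w5 <- setLevel(makeTone(5000, 0.5), 60)
  env5 <- rectifyLowpass(matrix(samples(w5), 1), 3000, 20000, 10000)
  x <- env5[1, i]
  expect_lt(sd(x) / mean(x), 0.05)
})

test_that("rate-level sigmoid reproduces printed parameter identities", {
  high <- FiberType(70, 250, 0, 20, 0.60)
  expect_equal(rateLevel(10, high), 160)             # midpoint
  expect_equal(rateLevel(-300, high), 70, tolerance = 1e-6)  # Rspont
  expect_equal(rateLevel(300, high), 250, tolerance = 1e-6)  # Rmax
  low <- FiberType(0.1, 250, 28, 80, 0.15)
  expect_equal(7.32 / low@dynamicRangeDb, 0.0915)
  # monotone nondecreasing for every type
  x <- seq(-20, 120, by = 0.5)
  for (f in defaultFiberTypes()) expect_true(all(diff(rateLevel(x, f)) >= 0))
})

test_that("spike sampler respects bounds and matches the binomial oracle", {
  fs <- 10000
  expect_error(sampleSpikes(array(20000, c(1, 10, 1)), 10L, fs), "exceed")
  zero <- sampleSpikes(array(0, c(2, 50, 3)), c(384L, 160L, 96L), fs, 1)
  expect_true(all(zero == 0))
  cfg <- CochleaConfig()
  expect_equal(sum(cochsim:::fibersPerType(cfg, defaultFiberTypes())), 640)
  # Normal approximation vs exact binomial, n = 640. For np >= 6 the
  # approximation matches to Monte-Carlo error; at np = 0.64 the rounding
  # and zero-clamp of the Normal draw give a known positive mean bias.
  n <- 640L
  for (p in c(0.01, 0.02)) {
    draws <- 20000L
    approx <- sampleSpikes(array(p * fs, c(1, draws, 1)), n, fs,
                           seed = round(1e4 * p))
    exact <- withr::with_seed(42, rbinom(draws, n, p))
    seMean <- sqrt(n * p * (1 - p) / draws)
    expect_lt(abs(mean(approx) - n * p), 4 * seMean)
    expect_lt(abs(var(as.numeric(approx)) / (n * p * (1 - p)) - 1), 0.05)
    expect_lt(abs(mean(exact) - mean(approx)), 5 * seMean)
  }
  low <- sampleSpikes(array(0.001 * fs, c(1, 20000L, 1)), n, fs, seed = 8)
  expect_gt(mean(low), 0.64)          # clamping bias is positive ...
  expect_lt(mean(low), 0.64 * 1.2)    # ... and bounded (~13%)
  # determinism
  r <- array(runif(300, 0, 200), c(10, 10, 3))
  expect_identical(sampleSpikes(r, c(384L, 160L, 96L), fs, 7),
                   sampleSpikes(r, c(384L, 160L, 96L), fs, 7))
})

test_that("acoustic nervegram has the documented shape and rate behavior", {
  cfg <- CochleaConfig()
  w <- setLevel(makeTone(1000, 0.5), 60)
  ng <- acousticNervegram(w, cfg, seed = 1)
  expect_equal(dim(rates(ng)), c(50, 5000, 3))
  expect_equal(dim(spikes(ng)), c(50, 5000, 3))
  expect_true(all(spikes(ng) >= 0))
  for (ci in 1:3)
    expect_lte(max(spikes(ng)[, , ci]), ng@meta$nPerType[ci])
  # silence-level input: mean rates near the spontaneous rates
  ng0 <- acousticNervegram(setLevel(makeTone(1000, 0.3), -30), cfg, seed = 1,
                           sampleSpikeTrains = FALSE)
  spont <- vapply(defaultFiberTypes(), function(f) f@rSpont, numeric(1))
  expect_equal(unname(apply(rates(ng0), 3, mean)), unname(spont),
               tolerance = 0.1)
  # louder tone within the dynamic range drives higher rates
  ng40 <- acousticNervegram(setLevel(makeTone(1000, 0.3), 40), cfg,
                            sampleSpikeTrains = FALSE)
  ng52 <- acousticNervegram(setLevel(makeTone(1000, 0.3), 52), cfg,
                            sampleSpikeTrains = FALSE)
  expect_gt(mean(rates(ng52)[, , 2]), mean(rates(ng40)[, , 2]))
  # channel tuning: mid-level tone at CF_k maximizes channel k
  cfs <- erbSpace(60, 12000, 50)
  ngt <- acousticNervegram(setLevel(makeTone(cfs[20], 0.3), 55), cfg,
                           sampleSpikeTrains = FALSE)
  expect_equal(which.max(apply(rates(ngt)[, , 1], 1, mean)), 20)
  uncal <- Waveform(sin(2 * pi * (1:2000) / 20), 20000)
  expect_error(acousticNervegram(uncal), "calibrated")
})

test_that("peripheral degeneration rescales the per-channel fiber cap", {
  cfg <- CochleaConfig()
  expect_equal(applyPeripheralDegeneration(cfg, 0.9)@nFibersTotal / 50, 64)
  expect_equal(applyPeripheralDegeneration(cfg, 0)@nFibersTotal / 50, 640)
  d1 <- applyPeripheralDegeneration(cfg, 1)
  expect_equal(d1@nFibersTotal, 0)
  r <- array(100, c(2, 20, 3))
  spk <- sampleSpikes(r, cochsim:::fibersPerType(d1, defaultFiberTypes()),
                      10000, 1)
  expect_true(all(spk == 0))
})
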