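# Psychometric readout, cue measurement and localization utilities.

test_that("intensity stimuli follow the three-segment level plan", {
  w0 <- makeIntensityStimulus(1000, 55, 6, label = 0)
  expect_length(samples(w0), 20000)
  seg <- function(w, a, b) 20 * log10(sqrt(mean(samples(w)[a:b]^2)) / 2e-5)
  expect_equal(seg(w0, 1, 5000), 55, tolerance = 0.01)
  expect_equal(seg(w0, 5001, 15000), 55, tolerance = 0.01)
  w1 <- makeIntensityStimulus(1000, 55, 6, label = 1)
  expect_equal(seg(w1, 1, 5000), 55, tolerance = 0.01)
  expect_equal(seg(w1, 5001, 15000), 61, tolerance = 0.01)
  expect_equal(seg(w1, 15001, 20000), 55, tolerance = 0.01)
})

test_that("psychometric threshold interpolates at the criterion", {
  expect_equal(psychometricThreshold(c(1, 2), c(0.5, 0.9), 0.707), 1.5175)
  # never reaches criterion: undefined
  expect_true(is.na(psychometricThreshold(c(1, 2, 3), c(0.5, 0.55, 0.6))))
  # starts above criterion: first grid point
  expect_equal(psychometricThreshold(c(0.5, 1), c(0.8, 0.9)), 0.5)
  # non-monotone curves are isotonized before interpolation
  thr <- psychometricThreshold(c(1, 2, 3, 4), c(0.5, 0.75, 0.65, 0.9))
  expect_true(is.finite(thr) && thr > 1 && thr < 4)
})

test_that("Weber fraction and %DR satisfy their endpoint identities", {
  lg <- LG0
  # I mapping to TL: %DR = 0 (acoustic level far below the mapped range)
  out <- weberAndPercentDR(-200, 1, lg)
  expect_equal(out$percentDR, 0, tolerance = 1e-4)
  # I mapping to MCL: %DR = 100
  out2 <- weberAndPercentDR(500, 1, lg)
  expect_equal(out2$percentDR, 100, tolerance = 1e-4)
  # Weber = 0 dB when the current increment equals the pedestal current:
  # construct deltaDb so that I(current) doubles exactly
  iCur <- cochsim:::dbToMilliamp(loudnessGrowth(40, lg))
  # find delta where current(40 + delta) = 2 * current(40)
  f <- function(d) cochsim:::dbToMilliamp(loudnessGrowth(40 + d, lg)) -
    2 * iCur
  d <- uniroot(f, c(0.1, 60))$root
  expect_equal(weberAndPercentDR(40, d, lg)$weberDb, 0, tolerance = 1e-6)
  # midpoint: p0 = 40 dB SPL sits mid-range in dB but not at 50 %DR in
  # linear current; sanity: %DR strictly increasing in pedestal
  pdr <- vapply(c(20, 40, 60, 80), function(p)
    weberAndPercentDR(p, 1, lg)$percentDR, numeric(1))
  expect_true(all(diff(pdr) > 0))
})

test_that("electrode ITD measurement recovers pure delays exactly", {
  pair <- binauralAmNoise(ELEC_CFS[3], itdUs = 0, dur = 0.4)
  eg <- cisEncode(pair$left, StrategyConfig("CIS"), LG0, seed = 2)
  # identical channels: 0 us in both modes
  expect_equal(measureElectrodeItd(eg, eg, 3, "fine_structure"), 0)
  expect_equal(measureElectrodeItd(eg, eg, 3, "envelope"), 0)
  # a pure 300 us shift of the electrode signal is recovered exactly
  shifted <- eg
  k <- 3L
  cur <- currentMatrix(eg)
  sh <- round(300e-6 * 10000)
  cur2 <- cur
  cur2[k, ] <- c(numeric(sh), cur[k, seq_len(ncol(cur) - sh)])
  shifted@current <- cur2
  expect_equal(measureElectrodeItd(eg, shifted, k, "fine_structure"), 300)
  expect_equal(measureElectrodeItd(eg, shifted, k, "envelope"), 300)
  # silent electrode: undefined
  silent <- eg; silent@current[5, ] <- 0
  expect_true(is.na(measureElectrodeItd(eg, silent, 5, "envelope")))
})

test_that("electrode ILD equals the RMS current ratio in dB", {
  pair <- binauralAmNoise(ELEC_CFS[5], dur = 0.3)
  eg <- cisEncode(pair$left, StrategyConfig("CIS"), LG0, seed = 2)
  expect_equal(measureElectrodeIld(eg, eg, 5), 0)
  double <- eg; double@current <- eg@current / 2
  expect_equal(measureElectrodeIld(eg, double, 5), 20 * log10(2))
  expect_equal(20 * log10(2), 6.0206, tolerance = 1e-4)
  silent <- eg; silent@current[5, ] <- 0
  expect_true(is.na(measureElectrodeIld(eg, silent, 5)))
  # imposed acoustic ILD drives the electrode ILD monotonically
  m <- vapply(c(-10, -5, 0, 5, 10), function(ild) {
    p <- binauralAmNoise(ELEC_CFS[5], ildDb = ild, dur = 0.3)
    measureElectrodeIld(cisEncode(p$left, StrategyConfig("CIS"), LG0, 2),
                        cisEncode(p$right, StrategyConfig("CIS"), LG0, 2),
                        5)
  }, numeric(1))
  expect_true(all(diff(m) > 0))
  expect_equal(m[3], 0, tolerance = 0.2)
})

test_that("cue bias weight equals the closed-form OLS slope", {
  # responses shifted by exactly the imposed cue: slope 1
  trueAz <- c(-40, -20, 0, 20, 40)
  imp <- c(-200, -100, 0, 100, 200)
  respAz <- vapply(seq_along(trueAz), function(i) {
    target <- azimuthToItd(trueAz[i]) + imp[i]
    grid <- seq(-90, 90, by = 0.01)
    grid[which.min(abs(azimuthToItd(grid) - target))]
  }, numeric(1))
  expect_equal(cueBiasWeight(trueAz, respAz, imp), 1, tolerance = 0.02)
  # responses ignoring the cue: slope 0
  expect_equal(cueBiasWeight(trueAz, trueAz, imp), 0)
  # hand-checkable synthetic set against the normal-equations oracle
  imposed <- c(-600, -300, 300, 600)
  biases <- c(-580, -310, 295, 605)
  resp2 <- vapply(seq_along(imposed), function(i) {
    grid <- seq(-90, 90, by = 0.001)
    grid[which.min(abs(azimuthToItd(grid) - biases[i]))]
  }, numeric(1))
  got <- cueBiasWeight(rep(0, 4), resp2, imposed)
  oracle <- olsSlopeOracle(imposed, azimuthToItd(resp2))
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_equal(oracle, olsSlopeOracle(imposed, biases), tolerance = 5e-3)
  expect_equal(olsSlopeOracle(imposed, biases), 892500 / 900000)
  expect_error(cueBiasWeight(trueAz, respAz, rep(5, 5)), "constant")
})

test_that("front-back folding and azimuth cue maps behave", {
  expect_equal(foldFrontBack(c(0, 45, 90, 135, 180, 225, 355)),
               c(0, 45, 90, 45, 0, -45, -5))
  expect_equal(azimuthToItd(0), 0)
  expect_gt(azimuthToItd(90), 600)      # ~655 us for a 8.75 cm head
  expect_equal(azimuthToItd(30), -azimuthToItd(-30))
  expect_equal(azimuthToIld(90), 10)
  expect_equal(azimuthToIld(-90), -10)
})

test_that("localization grid enumerates 504 azimuth-elevation classes", {
  g <- enumerateLocations()
  expect_equal(nrow(g), 504)
  expect_equal(length(unique(g$azimuth)), 72)
  expect_equal(length(unique(g$elevation)), 7)
  g2 <- enumerateLocations(elStep = 10, elMax = 0)
  expect_equal(nrow(g2), 72)
  expect_equal(nrow(enumerateLocations(azStep = 360, azMax = 0,
                                       elMax = 0)), 1)
})

test_that("snapping picks the nearest location and splits exact ties", {
  locs <- c(-70, -50, -30, -10, 10, 30, 50, 70)
  expect_equal(snapToExperimentLocations(12, locs), 10)
  expect_equal(snapToExperimentLocations(-70, locs), -70)
  draws <- vapply(seq_len(10000), function(i)
    snapToExperimentLocations(20, locs, seed = i), numeric(1))
  expect_true(all(draws %in% c(10, 30)))
  expect_equal(mean(draws == 10), 0.5, tolerance = 0.02)
})

test_that("word protocol enumerates the 306-trial, 16-condition design", {
  tr <- buildWordProtocol(snrs = c(-9, -3, 3),
                          noiseTypes = paste0("noise", 1:5))
  expect_equal(nrow(tr), 306)
  expect_equal(length(unique(tr$condition)), 16)
  expect_equal(sum(tr$noiseType == "clean"), 36)
  clean <- buildWordProtocol(snrs = numeric(0), noiseTypes = character(0))
  expect_true(all(clean$noiseType == "clean"))
})
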