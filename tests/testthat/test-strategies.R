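# Sound coding strategies and the loudness growth function.

test_that("loudness growth hits its midpoint and asymptotes", {
  lg <- LG0
  expect_equal(loudnessGrowth(40, lg), (lg@TL + lg@MCL) / 2)
  expect_equal(loudnessGrowth(1e4, lg), lg@MCL, tolerance = 1e-9)
  expect_equal(loudnessGrowth(-1e4, lg), lg@TL, tolerance = 1e-9)
  # p = 70 dB SPL: TL + (MCL-TL) / (1 + exp(-0.122 * 30))
  frac <- 1 / (1 + exp(-0.122 * 30))
  expect_equal(loudnessGrowth(70, lg), lg@TL + frac * (lg@MCL - lg@TL))
  expect_equal(frac, 0.9749, tolerance = 1e-4)
})

test_that("CI filterbank envelopes select the right electrode", {
  cfg <- StrategyConfig("CIS")
  env <- ciFilterbankEnvelopes(setLevel(makeTone(ELEC_CFS[7], 0.3), 60), cfg)
  expect_equal(nrow(env), 16)
  expect_equal(which.max(rowMeans(env)), 7)
  # silence sits at the dB floor
  env0 <- ciFilterbankEnvelopes(
    Waveform(numeric(4000), 20000, levelDb = NA_real_) |>
      (\(w) { w@levelDb <- 0; w })(), cfg)
  expect_true(all(env0 <= -30 + 1e-9))
  # scaling contract: x c in amplitude shifts dB envelopes by 20 log10 c
  w <- setLevel(tone1k(), 55)
  e1 <- ciFilterbankEnvelopes(w, cfg)
  w2 <- Waveform(samples(w) * 2, 20000, levelDb = w@levelDb + 20 * log10(2))
  e2 <- ciFilterbankEnvelopes(w2, cfg)
  keep <- e1 > -29 & e2 > -29    # away from the floor
  expect_equal(e2[keep] - e1[keep], rep(20 * log10(2), sum(keep)),
               tolerance = 1e-9)
})

test_that("CIS pulse trains interleave, jitter deterministically and code level", {
  w <- setLevel(tone1k(1), 60)
  eg <- cisEncode(w, StrategyConfig("CIS"), LG0, seed = 5)
  expect_equal(dim(currentMatrix(eg)), c(16, 10000))
  counts <- tabulate(eg@meta$pulses$electrode, 16)
  expect_true(all(abs(counts - 500) <= 1))         # 500 pps x 1 s
  expect_identical(currentMatrix(cisEncode(w, StrategyConfig("CIS"), LG0,
                                           seed = 5)),
                   currentMatrix(eg))
  expect_false(identical(currentMatrix(cisEncode(w, StrategyConfig("CIS"),
                                                 LG0, seed = 6)),
                         currentMatrix(eg)))
  # M * offset <= 1/rate: no two electrodes share a sample
  cfg10 <- StrategyConfig("CIS", nElectrodes = 10L)
  eg10 <- cisEncode(w, cfg10, LG0, seed = 5)
  expect_lte(max(colSums(currentMatrix(eg10) > 0)), 1)
  # all pulse amplitudes within [TL, MCL] in the dB view
  dbv <- currentDb(eg)
  expect_gte(min(dbv, na.rm = TRUE), LG0@TL - 1e-9)
  expect_lte(max(dbv, na.rm = TRUE), LG0@MCL + 1e-9)
  # silence maps to the loudness-growth lower asymptote (TL)
  ws <- Waveform(numeric(10000), 20000); ws@levelDb <- 0
  egs <- cisEncode(ws, StrategyConfig("CIS"), LG0, seed = 5)
  expect_equal(max(abs(currentDb(egs) - LG0@TL), na.rm = TRUE), 0,
               tolerance = 0.005)
})

test_that("ACE selects the n strongest bands per frame", {
  w <- setLevel(makeTone(ELEC_CFS[5], 0.5), 60)
  eg <- aceEncode(w, StrategyConfig("ACE"), LG0, seed = 2)
  cur <- currentMatrix(eg)
  fr <- (seq_len(ncol(cur)) - 1) %/% 20 + 1
  active <- vapply(split(seq_len(ncol(cur)), fr), function(ix)
    sum(rowSums(cur[, ix, drop = FALSE] > 0) > 0), numeric(1))
  expect_true(all(active <= 8))
  expect_equal(max(active), 8)
  # the tone's electrode is always among the selected set
  tonePulses <- vapply(split(seq_len(ncol(cur)), fr), function(ix)
    any(cur[5, ix] > 0), logical(1))
  expect_true(all(tonePulses[5:(length(tonePulses) - 5)]))
  # stationary input: selection stable across interior frames
  wn <- setLevel(makeNoiseBurst(c(200, 9000), 0.5, 1e-3, seed = 3), 60)
  egn <- aceEncode(wn, StrategyConfig("ACE"), LG0, seed = 2)
  curN <- currentMatrix(egn) > 0
  selFreq <- vapply(1:16, function(e) {
    byFrame <- vapply(split(seq_len(ncol(curN)), fr), function(ix)
      any(curN[e, ix]), logical(1))
    mean(byFrame[50:200])
  }, numeric(1))
  # a stable core of electrodes is selected in nearly every frame; only the
  # borderline ranks flicker
  expect_gte(sum(selFreq > 0.9), 6)
  expect_gte(sum(selFreq < 0.1), 6)
})

test_that("ACE with nMaxima = M degenerates to CIS at the ACE rate", {
  w <- setLevel(makeHarmonicComplex(dur = 0.4, seed = 3), 60)
  e1 <- aceEncode(w, StrategyConfig("ACE", nMaxima = 16L), LG0, seed = 4)
  e2 <- cisEncode(w, StrategyConfig("CIS", pulseRate = 800), LG0, seed = 4)
  expect_identical(currentMatrix(e1), currentMatrix(e2))
})

test_that("FSP apical electrodes phase-lock; basal electrodes run CIS", {
  w <- setLevel(makeTone(ELEC_CFS[1], 1), 60)
  eg <- fspEncode(w, StrategyConfig("FSP"), LG0, seed = 2)
  tab <- eg@meta$pulses
  apical <- sort(tab$index[tab$electrode == 1])
  expect_lte(length(apical), 1000)                 # <= 1 pulse per 1 ms frame
  iv <- diff(apical) / 10000
  period <- 1 / ELEC_CFS[1]
  expect_lt(abs(median(iv) - period) / period, 0.05)
  basal <- tab$index[tab$electrode == 4]
  expect_equal(length(basal), 800, tolerance = 2)  # 800 pps x 1 s
  # silence produces no fine-structure pulses
  ws <- Waveform(numeric(5000), 20000); ws@levelDb <- 0
  egs <- fspEncode(ws, StrategyConfig("FSP"), LG0, seed = 2)
  expect_equal(sum(egs@meta$pulses$electrode <= 3), 0)
})

test_that("HiRes120 steers current between adjacent electrode pairs", {
  cfg <- StrategyConfig("HIRES120")
  expect_equal((cfg@nElectrodes - 1) * 8, 120)     # virtual sites
  # tone exactly at the lower electrode's CF: alpha = 0 on that pair
  w <- setLevel(makeTone(ELEC_CFS[6], 0.3), 60)
  eg <- hires120Encode(w, cfg, LG0, seed = 2)
  expect_equal(eg@meta$nSteeringSites, 120L)
  tab <- eg@meta$pulses
  # pulses from pair 6 = rows on electrodes 6/7 sharing an index; electrode
  # 7 should receive (alpha = 0) no current from that pair
  idx6 <- tab$index[tab$electrode == 6]
  idx7 <- tab$index[tab$electrode == 7]
  expect_gt(length(idx6), 0)
  expect_equal(length(intersect(idx6, idx7)), 0)
  # steering weights of a pulse pair sum to 1 (linear current sums to A)
  wn <- setLevel(makeNoiseBurst(c(200, 9000), 0.3, 1e-3, seed = 5), 60)
  egn <- hires120Encode(wn, cfg, LG0, seed = 2)
  tn <- egn@meta$pulses
  # each steering event (shared pulse index and envelope) splits unit weight
  sums <- tapply(tn$weight, interaction(tn$index, tn$env_db, drop = TRUE),
                 sum)
  expect_gte(mean(abs(sums - 1) < 1e-9), 0.99)
  expect_true(all(tn$weight >= 0 & tn$weight <= 1))
  expect_true(all(tn$amp_mA <= 10^(LG0@MCL / 20) + 1e-12))
})

test_that("electrode subsets and 22-electrode arrays are supported", {
  w <- setLevel(makeHarmonicComplex(dur = 0.3, seed = 8), 60)
  cfg22 <- StrategyConfig("CIS", nElectrodes = 22L)
  eg22 <- cisEncode(w, cfg22, LG0, seed = 1)
  expect_equal(nrow(currentMatrix(eg22)), 22)
  cfgSub <- StrategyConfig("CIS", activeElectrodes = c(1L, 5L, 9L, 13L))
  egSub <- cisEncode(w, cfgSub, LG0, seed = 1)
  activeRows <- which(rowSums(currentMatrix(egSub)) > 0)
  expect_equal(activeRows, c(1L, 5L, 9L, 13L))
})
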