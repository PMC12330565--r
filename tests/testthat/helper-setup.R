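# Shared fixtures for the test suite (all built in code).

LG0 <- LoudnessGrowth(TL = -20, MCL = 0)

# Short calibrated tone reused across tests.
tone1k <- function(dur = 0.3, levelDb = 60) makeTone(1000, dur, 20000, levelDb)

# Small CI pipeline with default study parameters.
smallPipeline <- function(strategy = "CIS") ciPipeline(StrategyConfig(strategy))

# Electrode filter center frequencies of the default 16-electrode bank.
ELEC_CFS <- halfCosineCenters(16, 150, 10000)

# Binaural AM narrowband noise pair with imposed cues, calibrated.
binauralAmNoise <- function(centerHz, itdUs = 0, ildDb = 0, dur = 0.5,
                            seed = 7) {
  w <- makeAmNarrowbandNoise(centerHz, bw = 80, modRate = 40, depth = 1,
                             dur = dur, seed = seed)
  pair <- imposeItdIld(w, w, itdUs = itdUs, ildDb = ildDb)
  pair$left@levelDb <- measureLevel(pair$left)
  pair$right@levelDb <- measureLevel(pair$right)
  pair
}

# OLS slope by explicit normal equations (independent oracle for the cue
# bias weight).
olsSlopeOracle <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sum(xc^2)
}
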