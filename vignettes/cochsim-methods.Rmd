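---
title: "Modeling normal and electric hearing with cochsim"
author: "cochsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling normal and electric hearing with cochsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochsim)
```

# Overview

`cochsim` simulates the auditory periphery under two modes of stimulation:
acoustic (normal hearing) and electric (cochlear implant, CI). Both modes
end in the same representation, a *nervegram*: an N x T x C array of
instantaneous auditory-nerve firing rates (and sampled spike counts) over
N = 50 frequency channels, T time samples at 10 kHz, and C = 3 fiber types.
Around this core the package provides four CI sound-coding strategies that
produce *electrodograms* (per-electrode current over time), a procedure for
fitting the electrical dynamic range, and the psychophysical analyses used
to interrogate the simulation: intensity discrimination with a trained
linear classifier, interaural time/level difference (ITD/ILD) measurement
on electrodograms, cue-weighting slopes, and localization-grid utilities.

# The acoustic pathway

Sound (internally at 20 kHz, calibrated in dB SPL re 20 µPa) is passed
through 50 rounded-exponential (roex) filters with center frequencies
spaced uniformly on the Glasberg–Moore ERB scale from 60 Hz to 12 kHz.
Filters are applied by zero-phase multiplication in the frequency domain.
We use the symmetric roex(p) form with `p = 4 CF / ERB(CF)`; filters whose
passband reaches the Nyquist frequency are simply truncated there.

Subbands are half-wave rectified and lowpass filtered at 3 kHz (linear-
phase FIR designed with a 50 ms Kaiser window, β = 8.6), modeling the upper
limit of nerve phase locking, then downsampled to the 10 kHz nerve rate.
The rectified amplitude is converted per sample to dB SPL (floored at
-30 dB SPL to keep the logarithm finite; the floor is far below every
threshold in the model) and passed through sigmoidal rate-level functions

$$r(x) = R_{spont} + \frac{R_{max} - R_{spont}}{1 + e^{-k (x - x_0)}},
\qquad k = 7.32 / D, \quad x_0 = T + D/2,$$

with three fiber types (high / medium / low spontaneous rate: 70, 4,
0.1 spikes/s; thresholds 0, 12, 28 dB SPL; dynamic ranges 20, 40, 80 dB;
maximum 250 spikes/s; population fractions 0.60 / 0.25 / 0.15 of 640
fibers per channel, 32 000 in total).

Spikes are drawn per channel, bin and fiber type from the pooled binomial
approximation `Normal(np, np(1-p))` with `p = rate / fs`, rounded to the
nearest integer and clamped to `[0, n]`. Each channel-by-type pair uses an
independent, deterministically derived RNG substream, so one seed fixes
the whole tensor. **Known limit of the approximation:** for very small
`np` (e.g. the low-spontaneous-rate channel at rest, `np ≈ 0.64`) the
round-and-clamp step introduces a positive mean bias of about 13% and a
variance deficit of about 18% relative to the exact binomial; for
`np ≳ 6` the approximation is indistinguishable from binomial sampling at
Monte-Carlo precision. The test suite asserts both regimes explicitly.

# The electric pathway

## Sound coding strategies

All strategies share one front end: M = 16 half-cosine analysis filters,
ERB-spaced from 150 Hz to 10 kHz, rectification, a 50 Hz envelope lowpass
(50 ms Kaiser FIR), downsampling to 10 kHz, and the loudness growth
function

$$L(p) = TL + \frac{MCL - TL}{1 + e^{-\beta (p - p_0)}},
\qquad \beta = 0.122, \quad p_0 = 40\ \mathrm{dB\ SPL},$$

which maps the 10–70 dB SPL acoustic range onto the electrical dynamic
range `[TL, MCL]` (dB re 1 mA). On the "half-cosine" shape: lobes must sum
to one at 50% overlap for the bank to tile the spectrum, which holds for
squared-cosine (Hann) lobes but not for plain cosine lobes; we therefore
use squared cosines on the ERB axis, with the edge filters clamped to
unity outside the first and last centers. The same construction, with 320
filters from 20 Hz to 10 kHz, forms the vocoder analysis bank.

* **CIS** (the baseline, equivalently the original HiRes): monophasic
  single-sample pulses at 500 pps per electrode, interleaved with a fixed
  200 µs electrode-to-electrode offset plus one shared start jitter drawn
  from U[0, inter-pulse interval] per stimulus. Pulse amplitude is the
  compressed envelope at the pulse time. We chose a single shared jitter
  draw (a per-electrode `independentJitter` flag exists) because fixed
  offsets with independent draws would destroy the stated interleaving
  structure. Pulse times are computed in continuous time and rounded to
  the 10 kHz grid, so non-divisor rates (800 pps) are realized as closely
  as the grid allows.
* **ACE**: 800 pps, 2 ms frames; per frame only the 8 electrodes with the
  highest mean compressed envelope fire (loudness growth is monotone, so
  ranking the dB envelope is equivalent); ties break toward the apical
  electrode for determinism. With `nMaxima = M` ACE reduces exactly to
  CIS at the ACE rate, which the tests assert.
* **FSP**: the 3 most apical electrodes fire at the local temporal maxima
  of their half-wave-rectified subbands — at most one pulse per 1 ms
  frame, none when the frame is below the amplitude floor — so apical
  inter-pulse intervals track the carrier period; the 13 basal electrodes
  run CIS at 800 pps. Apical pulse amplitude derives from the envelope
  (not the subband peak), selectable in principle but fixed here.
* **HiRes120** (simplified): the 15 adjacent electrode pairs each emit one
  synchronized pulse pair per 2 ms frame. The spectral peak inside the
  pair's passband (argmax of a zero-padded FFT of the summed subband)
  selects a steering coefficient α ∈ {0, 1/8, …, 7/8}; the pair splits the
  compressed amplitude A as (1-α)A and αA in linear current, yielding
  15 x 8 = 120 virtual sites. A carrier-synthesis stage modulates the pair
  envelope at the spectral-peak frequency before amplitude extraction.
  AGC and noise reduction are disabled. Note that steered pulses can fall
  below TL in the dB view (a weight of 1/8 is -18 dB); the electrodogram
  validity check therefore enforces only the MCL upper bound.

Electrodograms store linear current in mA (zero = no pulse) as the
canonical representation, because a dB matrix cannot represent "off"
(0 dB re 1 mA is 1 mA); `currentDb()` gives the dB view of pulse samples.

## Electrode–nerve interface

The field at nerve position x from electrode e is
`V0 exp(-|x - x_e| / λ)` summed over electrodes in linear current
(superposition). Electrodes sit equidistantly from 8.125 to 23.875 mm of
a 35 mm unwound cochlea (1.05 mm pitch); the 50 nerve positions are
uniform over the full cochlea (the source description leaves their
placement open; a restriction to the electrode span is configurable).
λ = 6 / 2.35 / 1.5 mm model monopolar / bipolar / tripolar spread.

Each position's field is convolved causally with a 10 ms two-Gaussian
impulse response (excitatory: mean 0.6 ms, sd 0.6 ms, weight 1; refractory:
mean 2.2 ms, sd 0.33 ms, weight +0.1; peak normalized to 1). The printed
refractory weight is positive and therefore additive, which does not
suppress; we implement it as printed and expose `negateRefractory` for the
physiologically suppressive variant. The drive is converted to dB re 1 mA
(floored at -100 dB) and passed through a single electrical rate-level
sigmoid shared by all fiber types (threshold -5 dB re 1 mA, dynamic range
15 dB, spontaneous rate 0.1, maximum 250 spikes/s), then spikes are
sampled exactly as in the acoustic pathway. Peripheral degeneration scales
the per-channel fiber cap at the sampling stage (90% degeneration: 64 of
640 fibers).

# Current fitting by variance maximization

TL and MCL are free parameters. They are set by evaluating, for each MCL
on a -60…+40 dB re 1 mA grid in 5 dB steps (TL tied at MCL - 20 dB), the
variance across stimuli of the firing-rate nervegram in every
channel-time-fiber bin, averaged over bins, and keeping the argmax;
settings at ≥ 60% of the maximum variance form the candidate set. Variance
is computed on rates rather than sampled spikes so the objective is
deterministic (a spike-based mode exists and must agree in argmax). All
stimuli share one pulse-jitter draw within an evaluation, so identical
stimuli give exactly zero variance and the objective is invariant to
stimulus order. Because pulse *times* do not depend on the current
settings, each stimulus is analyzed once and pulse amplitudes are re-mapped
through each candidate loudness growth function; this fast path is
verified to match brute-force re-encoding exactly.

The fitting stimulus set stands in for a speech-in-noise corpus: 100
amplitude-modulated harmonic complexes (F0 100–300 Hz, 1/n spectral
rolloff, 3–8 Hz AM) mixed with Gaussian noise at SNRs from -24 to +18 dB
in 3 dB steps plus clean, at 60 dB SPL. We use 0.5 s tokens — several AM
and F0 cycles, enough for the envelope statistics that drive the variance
objective to stabilize.

# Psychophysical analyses

**Intensity discrimination.** Stimuli are 1 s tone pedestals; label 1
carries a 500 ms increment ΔI between two 250 ms pedestal segments. A
binary classifier — a 128-unit dense (linear) layer, dropout 0.5, sigmoid —
is trained with Adam (β₁ 0.9, β₂ 0.999, ε 1e-7, batch 32) on binary
cross-entropy over CI spike nervegrams, with pedestal ~ U(20, 80) dB SPL,
frequency ~ U(80, 8000) Hz, ΔI ∈ [0.02, 12.38] dB, balanced labels. At
desk scale the flattened nervegram is pooled over fiber types and 50 ms
time bins before the dense layer (1000 features instead of 1.5 million;
`poolMs = 0` restores full flattening), a fixed training set of ~64–128
pre-generated stimuli is reused across Adam steps, and evaluation uses a
1 kHz held-out grid. Thresholds are read from the accuracy-vs-ΔI curve,
monotonized by isotonic regression, at the 70.7% criterion by linear
interpolation; a curve that never reaches criterion has an undefined
threshold (`NA`). The Weber fraction 10·log10(ΔI/I) and
%DR = 100 (I - TL)/(MCL - TL) are computed after mapping I and I + ΔI
through the loudness growth function to linear current. Because the
training length is a desk-scale choice, absolute thresholds are validated
only by ordering and endpoint identities (fitted settings beat saturating
settings; %DR endpoints at TL and MCL), not by absolute values.

**Electrodogram ITD/ILD.** Per electrode, left and right linear-current
signals are cross-correlated within ±1 ms (lag grid 100 µs at 10 kHz);
envelope mode first applies a zero-phase 4th-order Butterworth lowpass at
60 Hz. We use the *normalized* cross-correlation of the demeaned signals
over a fixed interior window (excluding ~100 ms edges in envelope mode):
normalization makes a pure delay score exactly 1 at the true lag, and the
window exclusion keeps the very flat correlation function of a 40 Hz
envelope from being biased by filter onset transients — with plain
unnormalized correlation the envelope ITD estimate collapses toward zero
lag. Ties resolve to the smaller |lag|. ILD is 20·log10(RMS_L / RMS_R)
of linear current. Analysis stimuli are 80 Hz-wide narrowband noises at
the electrode's filter frequency, 100% amplitude-modulated at 40 Hz, with
the ITD imposed on the whole waveform by exact frequency-domain delay.
These analyses reproduce the expected strategy contrast: fine-structure
ITD slope ≈ 1 on FSP apical electrodes and ≈ 0 for CIS, envelope ITD
slope ≈ 1 for every strategy.

**Cue weighting.** Response azimuths are front-back folded into
[-90°, 90°], mapped to cue units, and the response bias (response cue
minus true-azimuth cue) is regressed on the imposed bias; the OLS slope is
the cue weight. Without an HRTF set the azimuth-to-ITD map is the
Woodworth spherical-head formula (radius 8.75 cm) and the ILD map a
10·sin(θ) dB broadband approximation; both are plain function arguments,
so an HRTF-derived map can be substituted.

**Localization utilities.** The training grid is 72 azimuths x 7
elevations = 504 classes; predictions are snapped to the experiment's
speaker ring with exact ties resolved equiprobably; the word-recognition
protocol enumerates 3 SNRs x 5 noise types x 18 trials + 36 clean = 306
trials in 16 conditions.

# Numerical choices and degenerate inputs

* All stochastic operations take integer seeds; substreams are derived
  arithmetically (values below 2^31) and the caller's RNG state is saved
  and restored.
* FFT-based convolutions pad to 5-smooth lengths (a prime-length FFT in R
  is quadratic); zero-phase filterbanks operate at the signal length.
* Envelope division in the vocoder is floored at 1e-8 of the maximum
  envelope; vocoding silence returns silence.
* Setting the level of an all-zero waveform, measuring ITD/ILD on a
  silent electrode, a constant imposed-bias vector, and `p = rate/fs > 1`
  in spike sampling are explicit errors or `NA` signals, not silent
  defaults.
* The amplitude floor (-30 dB SPL) defines "silence" for FSP fine-
  structure pulses and the HiRes120 frame gate.

# What the synthetic stimuli do and do not show

All tests run on synthesized tones, noise bursts, AM narrowband noises and
harmonic complexes. These exercise every pathway of the code under known
ground truth — filter tuning, level calibration, pulse timing, spread,
sigmoid placement, cue transfer — but they are not speech: passing tests
demonstrate that the simulation implements its stated model, not that the
model predicts human speech intelligibility. The deep-network decoding
experiments that connect this front end to behavior at scale are outside
the package's scope, as are room acoustics, HRTF rendering, refractoriness
and adaptation dynamics, biphasic pulses, and vendor-exact HiRes120
processing.

# Reproducing the headline quantities

`scripts/acceptance.R` regenerates all inputs from a seed and recomputes
the quantities discussed here (structural constants, sigmoid identities,
sampler-vs-binomial ratios, spread identities, vocoder tiling error, the
fitted current settings on the 100-stimulus set, ITD/ILD transfer slopes,
and the intensity-discrimination thresholds under fitted vs saturating
settings), writing them to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
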