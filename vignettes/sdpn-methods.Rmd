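---
title: "Dual-path nonlinear cochlear channels: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-path nonlinear cochlear channels: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpn)
```

## The model

Each cochlear channel in this package is a *dual-path* processor. Incoming
sound `x` is split into:

* a **linear pathway** — a fixed gain (default 6) followed by a broad
  2nd-order Butterworth bandpass, the *tail* filter, whose −3 dB bandwidth
  equals the conventional channel analysis bandwidth; and
* a **nonlinear pathway** — a sharp 4th-order Butterworth bandpass, the *tip*
  filter, with one third of the tail bandwidth, followed by the compressive
  saturation `y = 2 arctan(15 x)`.

The channel output is the sample-wise sum of the two pathways. The names
follow cochlear tuning-curve anatomy: the *tip* is the sharp, high-gain,
low-level region of a tuning curve, the *tail* its broad skirt. For quiet
inputs the arctangent is in its linear region, the tip path contributes its
small-signal gain `2 × 15 = 30`, and the composite response is sharp and
high-gain. For loud inputs the arctangent saturates, the tip contribution
becomes negligible relative to the linear path, and the response becomes
broad with gain ≈ 6. This reproduces, with two filters and one static
nonlinearity, the level-dependent tuning that outer-hair-cell amplification
gives the basilar membrane, which is the property believed to keep speech
formants salient in noise.

All "orders" here are Butterworth *prototype* (lowpass) orders: the tail is a
4-pole bandpass, the tip an 8-pole bandpass. This reading is what makes the
high-level composite bandwidth come out right — the half-amplitude width of a
prototype-order-2 bandpass is `3^(1/4) ≈ 1.32` times its −3 dB bandwidth,
≈ 470 Hz for the 357 Hz demo channel, against ≈ 618 Hz for a 2-pole
resonator.

### How the nonlinearity is applied

A static `2 arctan(15 x)` applied per sample creates harmonic distortion on
every waveform it touches. Because the model's stated intent is to control
the *relative contribution* of the tip pathway according to input level (RMS),
the default mode (`nl_mode = "rms_gain"`) drives a time-varying gain
`2 arctan(15 r)/r` from the causal running RMS `r` of the tip-filtered signal
(8 ms rectangular window, partial windows at onset), and multiplies the tip
waveform by it. This preserves waveform shape, is exactly the arctangent's
equivalent gain at each level, and has the correct small-signal limit of 30.
The per-sample mode is retained as `nl_mode = "instantaneous"` for
sensitivity analysis (its tip contribution is bounded by `2·π/2 = π` per
sample no matter how loud the input), and `nl_mode = "fixed_gain"` freezes
the gain so the whole channel becomes linear — used in the tests to verify
that superposition holds exactly once the only nonlinear element is removed.

### Channel allocations and the tail/tip split

The 4-, 8- and 12-channel maps are embedded verbatim (logarithmic spacing for
4 channels, mel spacing for 8 and 12). `split_bandwidths()` derives each
channel's pathway bandwidths from its conventional bandwidth: tail = the
channel bandwidth, tip = one third of it. Two notes on the source table this
reproduces:

* The table's row labels attach "tip" to the *wide* bandwidth and "tail" to
  the *narrow* one, contradicting both the accompanying text (the tail is
  "three times larger" than the tip) and the physiological convention. The
  package follows the text and the physiology — broad tail, sharp tip — which
  also makes the numeric ratios (e.g. 321 : 107) and the level-dependent
  response behavior mutually consistent. The numbers themselves are preserved
  exactly.
* One narrow-row entry of the 8-channel table (printed 83.3 Hz) is
  inconsistent with its own 3:1 rule (265/3 = 88.3 Hz); the other 23 rows
  obey the rule to the printed decimal. The package treats the ratio as
  normative and derives 88.3 Hz for that channel.

For arbitrary center frequencies (the 181-partition analysis below) the
channel bandwidth is interpolated linearly in log(cf)–log(bw) through the
12-channel table, extrapolated with the end-segment slopes. For a single demo
channel, the bandwidth of the nearest tabulated channel is used instead: the
1500 Hz channel of the frequency-response characterization takes 357 Hz
(tail) / 119 Hz (tip) from the 1521 Hz table entry.

## Calibration and the gain convention

Sound pressure level enters the simulation through an explicit mapping:
`spl_to_amplitude(spl)` = `10^((spl − 40)/20)`, i.e. 40 dB SPL corresponds to
digital peak amplitude 1.0. This reference places the characterization's two
operating points (35 and 85 dB SPL) on either side of the compressive knee of
`2 arctan(15 x)`.

`frequency_response()` probes a channel with 0.5 s tones (default 201
log-spaced frequencies spanning cf/3 to 3·cf), discards the first 0.1 s of
each response, and reports per-frequency gain, peak gain, and the full width
at half maximum of the gain curve (linear interpolation at the half-max
crossings). The **gain convention** deserves emphasis: by default gain is the
steady-state output RMS divided by the probe's calibrated *peak amplitude*
(`gain_ref = "amplitude"`). Under this convention a pure linear pathway with
gain 6 measures `6/√2 ≈ 4.243`, and the default channel measures ≈ 9.24 at
35 dB SPL and ≈ 4.26 at 85 dB SPL — the level-dependent characterization this
model is known by. `gain_ref = "rms"` gives the dimensionally symmetric
output-RMS/input-RMS ratio, exactly `√2` larger.

One caveat is documented rather than hidden: at 35 dB SPL the measured FWHM
of the default channel is ≈ 99 Hz (see `scripts/acceptance.R`), *narrower*
than the tip filter's stand-alone half-amplitude width of ≈ 137 Hz, because
the 4-pole tail and 8-pole tip accumulate opposite phase near the tip's band
edges and interfere destructively there. A reported low-level FWHM of
≈ 140 Hz would require the low-level response to be essentially
tip-path-only, which cannot occur together with a peak gain of ≈ 9.4 under
any single amplitude calibration of this architecture — at the compression
level that yields peak gain 9.4, the gain-6 tail already contributes almost
half the peak. The package reports what the model actually does; the hard
qualitative contract (sharp + high-gain quiet response, broad + low-gain loud
response, monotone broadening with level) holds everywhere and is enforced in
the tests across tabulated channels.

## Envelope detection

The standard detector is full-wave rectification followed by a causal
4th-order Butterworth lowpass at 400 Hz (DC gain 1, zero initial state,
undershoot clipped at zero); on a steady tone of amplitude A it settles to
the rectified mean `2A/π`, which the tests verify to 2%.

The transient-enhanced detector runs a second detector at 20 Hz and compares:
with `r = fast/(slow + ε)`, the fast envelope is multiplied by
`g = min(1 + β·(r − θ), g_max)` where `g > 1` only for `r > θ`. Defaults are
θ = 1.5, β = 1, g_max = 3, ε = 10⁻⁶. The comparison-of-two-detectors
structure is the published idea; the specific ratio-threshold-boost rule and
its constants are this package's own (the original gain schedule is not
reproduced in the source literature), so all four constants are exposed. The
defaults were chosen once as a mild boost: onset gain capped at 3× so
enhanced envelopes stay within one bit-depth headroom of standard ones, and
θ = 1.5 so that steady-state ripple (fast/slow ≈ 1) never triggers boosting.
The invariants `standard ≤ enhanced ≤ 3·standard` and "boost only near
onsets" are enforced in tests on tone-burst and vowel–gap–vowel tokens.

## Vocoder

Acoustic simulation assigns one sinusoid per channel at the channel center
frequency — possible because tail and tip share a center frequency — with
zero initial phase (fixed phases make outputs bit-reproducible), modulated by
the channel envelope and summed. Output is rescaled to the input RMS by
default to prevent 16-bit clipping; the raw sum is available by flag. The
logarithmic compression that precedes electrical stimulation in a real
processor is bypassed in acoustic simulation (a `compression` hook defaults
to identity).

## Dominant-frequency analysis and formant extraction ratios

`dfc_profile()` scans 181 log-spaced cochlear partitions from 100 Hz to
10 kHz (181 and the range are the analysis's defining constants; the spacing
is chosen logarithmic to match tonotopy). For each partition it builds a
channel at that cf (interpolated bandwidth), processes the stimulus at a
given SPL, and records the frequency of the maximum-magnitude bin of the
Hann-windowed FFT of the full output, zero-padded to ≥ 2^16 points (≈ 0.34 Hz
bins at 22.05 kHz), restricted to the analysis range. Formant capture appears
as horizontal bands (many partitions report the formant), channel-dominated
output as a diagonal.

`formant_extraction_ratios()` counts the partitions whose dominant frequency
lies within ±2% of F1 or F2. The 2% window is the package's equality
tolerance — strict equality is meaningless on an FFT grid — and keeps the
F1/F2 windows of all test vowels disjoint (overlapping windows are an error).

**Formant references for synthetic tokens.** The synthetic vowel is an
impulse train through resonators: all its energy sits on harmonics of f0.
With the default f0 = 100 Hz, no harmonic falls within 2% of the nominal
F1 = 270 Hz; the *realized* formant peaks of the token are its strongest
harmonics, 300 Hz and 2300 Hz for the /i/ preset. FERs for synthetic tokens
are therefore computed against the realized peaks (measured from the clean
token with `dominant_frequency()`), not the nominal resonator centers —
otherwise FER1 is identically zero for every model and the comparison is
vacuous.

## The synthetic-stimulus generators

* **Vowels**: impulse train at f0 (default 100 Hz) through cascaded two-pole
  resonators (poles at radius `exp(−π·bw/fs)`, unit DC gain) and a
  first-difference radiation filter, peak-normalized. Presets: /i/ =
  270/2290/3010 Hz (the evaluation vowel), /a/ = 730/1090/2440 Hz, /u/ =
  300/870/2240 Hz (classic reference values), bandwidths 60/90/120 Hz.
* **White Gaussian noise**: seeded `rnorm`, bit-reproducible, caller RNG
  state untouched.
* **Speech-shaped noise**: WGN through a 2nd-order Butterworth lowpass at
  1100 Hz — flat below the cutoff, −12 dB/octave above it (verified by Welch
  estimate in the tests).
* **SNR mixing**: noise rescaled so the component powers (full duration, no
  silence trimming) satisfy the requested SNR exactly; `Inf` dB is the quiet
  condition.

What these fixtures do *not* emulate matters for interpreting results: a
natural vowel has jittered pitch, glottal spectral tilt, and formant energy
spread continuously between harmonics; the synthetic token concentrates each
formant's energy in one or two strong spectral lines. Consequences observed
in this package's own analyses (all computed by the test suite): the
dual-path model's FER2 advantage under speech-shaped noise is large and
robust (roughly threefold), and its FER1 advantage holds under white noise
on average across seeds, but under *speech-shaped* noise at 60 dB SPL the
linear array matches or slightly beats the dual-path model on FER1 — the
noise is itself concentrated on the F1 region, and a single strong harmonic
line is something a fixed filter captures just as well. At 70 dB SPL and
above the dual-path model leads on FER1 under SSN too. Passing the
formant-robustness tests on these fixtures therefore demonstrates the
mechanism, not listener-level performance on natural speech; perceptual
results require human experiments, which no synthetic stand-in reproduces.

## Numerical choices

* All IIR filters are designed in pole-zero form (analog Butterworth
  prototype → lowpass/bandpass transform → bilinear transform) and realized
  as cascaded biquads. High-order transfer-function polynomials are avoided
  entirely: the 8-pole bandpass at cf 100 Hz with a ~30 Hz tip bandwidth that
  the partition scan needs is numerically fragile as a single (b, a) pair but
  exact and stable as sections. The design is cross-checked against an
  independent Butterworth implementation in the tests (agreement ~10⁻¹³).
* Filtering is causal with zero initial conditions — matching a real-time
  processor; no zero-phase tricks.
* Probe-tone protocol: 0.5 s tones, first 0.1 s discarded. 0.4 s of a
  ≥ 500 Hz tone is hundreds of cycles, ample for steady state at the
  bandwidths involved.
* FWHM: the contiguous interval around the argmax where gain ≥ half peak;
  ties broken by the first maximum; it is an error if the curve never falls
  below half max inside the sampled range (flat or truncated curves), or by
  construction if the response is not unimodal around the peak.
* Degenerate inputs error loudly rather than silently: zero-power signals in
  SNR mixing and dominant-frequency analysis, passbands at or beyond Nyquist
  (with the channel named), unsupported channel counts, overlapping formant
  windows.

## Problem sizes

The shipped analyses use 0.5 s tokens at 22.05 kHz, 201-point probe grids for
frequency responses, full 181-partition profiles for FER comparisons with
five noise realizations per condition (FERs compared on the mean), and a 10 s
realization for noise-spectrum verification. The full test suite runs in
about a minute; the characterization script in seconds.

## Known limitations

* The model is *qualitative* by design: two filters and one nonlinearity per
  channel. It does not reproduce gammatone-shaped tuning, broken-stick
  compression, middle-ear filtering, or hair-cell transduction.
* The enhanced detector's boost rule is an admissible realization, not a
  reimplementation of the original adaptive gain schedule.
* Electrical stimulation (pulse trains, loudness mapping, interleaving) is
  out of scope; the vocoder is the acoustic-simulation surrogate.
* The FER analysis of synthetic tokens measures spectral dominance, not
  intelligibility; see the fixture caveats above.
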