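# sdpn

Level-dependent nonlinear cochlear filterbank modelling and cochlear-implant
(CI) vocoder simulation in R.

## The problem

Conventional CI sound processors decompose sound with a *fixed linear*
bandpass filter array, detect each band's envelope, and use the envelopes to
modulate stimulation (or, in acoustic simulation for normal-hearing
listeners, to modulate one sinusoidal carrier per channel). The healthy
cochlea does something richer: outer-hair-cell motility makes basilar-membrane
tuning *level dependent* — sharp and high-gain for quiet sounds, broad and
compressive for loud ones — and this active nonlinearity helps keep speech
formants salient in noise.

`sdpn` implements a deliberately simple dual-path nonlinear channel model of
this behavior, and everything needed to evaluate it as a CI strategy:

- **Dual-path channel model**: each channel sums
  - a *linear pathway*: fixed gain `g = 6` into a broad 2nd-order Butterworth
    bandpass (the "tail" filter, bandwidth equal to the conventional channel
    bandwidth), and
  - a *nonlinear pathway*: a sharp 4th-order Butterworth bandpass (the "tip"
    filter, bandwidth one third of the tail's) followed by the compressive
    saturation `y = 2 arctan(15 x)`, applied by default as a running-RMS-driven
    gain `2 arctan(15 r)/r` (8 ms causal window).

  Small signals see the tip path at its small-signal gain 30 (sharp, high
  gain); loud signals saturate it, leaving the broad tail to dominate
  (broad, gain ≈ 6). The channel output is
  `y(t) = 6 · tail(x)(t) + NL[tip(x)](t)`.
- **Channel maps**: the tabulated 4-, 8- and 12-channel allocations
  (logarithmic / mel spacing) with the 3:1 tail/tip bandwidth split.
- **Envelope detectors**: the standard full-wave-rectifier + 400 Hz 4th-order
  Butterworth lowpass, and a transient-enhanced variant that compares it with
  a 20 Hz detector and boosts rapid onsets.
- **Sinusoidal vocoder**: one carrier per channel at the channel center
  frequency, amplitude-modulated by the channel envelope and summed —
  the standard acoustic simulation of a CI strategy.
- **Evaluation machinery**: probe-tone frequency-response characterization
  (peak gain, FWHM) as a function of presentation level;
  dominant-frequency-component (DFC) analysis over 181 log-spaced cochlear
  partitions from 100 Hz to 10 kHz; formant extraction ratios FER1/FER2 (the
  fraction of partitions whose dominant output frequency coincides with
  F1/F2).
- **Synthetic stimuli**: source-filter formant vowels (`/i/`, `/a/`, `/u/`
  presets), white Gaussian noise, speech-shaped noise (2nd-order Butterworth
  lowpass at 1100 Hz applied to WGN), exact SNR mixing, and an explicit
  dB-SPL-to-amplitude calibration (40 dB SPL ↔ peak amplitude 1).

## Worked example

```r
library(sdpn)

# 1. level-dependent tuning of a demo channel at cf 1500 Hz
ch <- sdpn_channel(1500)
frequency_response(ch, 35)   # quiet probe tones
frequency_response(ch, 85)   # loud probe tones
#> <frequency_response: sdpn channel cf 1500 Hz @ 35 dB SPL: peak gain 9.240, FWHM 99.12 Hz>
#> <frequency_response: sdpn channel cf 1500 Hz @ 85 dB SPL: peak gain 4.260, FWHM 466.57 Hz>

# 2. vocode a synthetic /i/ through the 8-channel dual-path strategy
v <- synth_vowel(vowel_preset("i"))
y <- run_strategy(v, strategy_config("sdpn", "standard", make_channel_map(8)))
y
#> <waveform: 11025 samples @ 22050 Hz (0.500 s), peak 0.8671, rms 0.2458>
write_wav(y, "i_sdpn_8ch.wav")

# 3. formant representation under speech-shaped noise at 5 dB SNR
x <- mix_at_snr(v, gen_ssn(duration(v), 22050, seed = 1), 5)
f1 <- dominant_frequency(v, c(150, 500))    # realized F1 peak of the token
f2 <- dominant_frequency(v, c(1800, 2700))  # realized F2 peak
formant_extraction_ratios(dfc_profile(x, "linear", level = 60), f1, f2)
formant_extraction_ratios(dfc_profile(x, "sdpn",   level = 60), f1, f2)
#> <fer_result: FER1 0.138 (F1 300.119 Hz), FER2 0.055 (F2 2300.02 Hz), tol 2.0%, 181 partitions>
#> <fer_result: FER1 0.105 (F1 300.119 Hz), FER2 0.171 (F2 2300.02 Hz), tol 2.0%, 181 partitions>
```

Reading the numbers: at 35 dB SPL the nonlinear tip pathway dominates and the
channel is sharply tuned with high gain; at 85 dB SPL saturation hands the
response to the broad tail (peak gain ≈ 6/√2 ≈ 4.26 under the package's
amplitude-referenced gain convention, FWHM ≈ 4.7× wider). In the noisy-vowel
analysis, the dual-path model triples FER2 — three times more cochlear
partitions report the second formant as their dominant output frequency
under speech-shaped noise — which is the formant-robustness property the
model exists to provide; FER1 behavior for this discrete-harmonic synthetic
token is discussed in the methods vignette (`vignettes/sdpn-methods.Rmd`).

A command-line wrapper is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/sdpn.R", package = "sdpn"))')
Rscript $CLI response --cf 1500 --spl 35
Rscript $CLI fixtures --out fixtures/ --seed 1
Rscript $CLI process --in fixtures/vowel_i_ssn_snr+2.wav --out out.wav \
        --model sdpn --channels 8
```

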