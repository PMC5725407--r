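# tritone

Triple-tone sonification of PET brain metabolism: an auditory display
that lets the degree of Alzheimer's-type hypometabolism be *heard* as
frequency beating.

## What it computes

FDG-PET in Alzheimer's disease shows reduced metabolic activity
(hypometabolism) concentrated in the parietal and, with progression,
frontal lobes, while the sensorimotor cortex (SMC) is typically spared.
On a lateral brain slice segmented into frontal lobe (FL), parietal lobe
(PL), and SMC by straight-line boundaries, `tritone` assigns one
triangular-wave oscillator per region. The SMC anchors the base
frequency *f*<sub>default</sub> = 440 Hz; the other two tones are
detuned by each lobe's relative deviation from the SMC mean intensity:

> Δ = |av<sub>lobe</sub> − av<sub>SMC</sub>| / av<sub>SMC</sub>
>
> f<sub>FL</sub> = f<sub>default</sub> · (1 + DF·|Δ<sub>FL</sub>|)  
> f<sub>PL</sub> = f<sub>default</sub> · (1 − DF·|Δ<sub>PL</sub>|)

DF is a severity-dependent *detune factor* (normal 0.05, mild 0.10,
moderate 0.15, severe 0.20). The frontal tone deviates upward and the
parietal downward, so equal deviations still produce three distinct
tones. Mixed together, the tones beat at the pairwise frequency
differences — f<sub>default</sub>·DF·|Δ| per lobe against the base — so
faster, more complex beating means more severe disease.

Before averaging, white matter and background are masked: every pixel
below 45% of the maximum allowable intensity (14 745.15 for 15-bit
data) is excluded. The diagnostic plane is the 30th slice from the top
(58–60 mm deep at 2 mm spacing).

The package provides readers/writers for the voxel text dialect
(`x y z value` lines) and the boundary text format, slice extraction and
masking, polygon rasterization, the frequency mapping, triangle-wave
rendering to 16-bit WAV, spectral/beat analysis utilities, a seeded
synthetic phantom generator with known per-lobe hypometabolism, and a
command-line interface (`inst/scripts/tritone`) with `sonify`,
`analyze`, and `phantom` subcommands.

## Worked example

A severe-preset phantom (frontal gray matter dimmed 25%, parietal 35%,
noise 1% of maximum, seed 42), sonified at the severe detune factor:

```r
library(tritone)
ph  <- generate_phantom(severity_preset("severe", seed = 42))
sl  <- extract_slice(ph$volume, 30)
fit <- sonify_slice(sl, ph$boundaries, severity = "severe")
summary(fit)
#> Triple-tone sonification summary
#>
#>        region mean_intensity n_pixels frequency_hz
#>       frontal       19683.16      440     461.8732
#>      parietal       17026.67      462     409.2021
#>  sensorimotor       26193.90      220     440.0000
#>
#> masking threshold: 14745.15 (54.5% of slice masked)
#> detune factor: 0.200
#> beat rates: FL-SMC 21.87 Hz, SMC-PL 30.80 Hz, FL-PL 52.67 Hz
```

The recovered deviations (≈ 0.249 and 0.350) match the generative
fractions up to noise, and at DF = 0.20 place the frontal tone near
440 × 1.05 = 462 Hz and the parietal near 440 × 0.93 = 409.2 Hz. The
rendered audio confirms the mapping — its spectrum peaks at the three
oscillator frequencies and its envelope beats at their differences:

```r
buf <- render_tts(fit, duration_s = 5)
sort(spectral_peaks(buf, 3))
#> [1] 409.2 440.0 461.8
sort(envelope_beat_peaks(buf, 3))
#> [1] 21.8 30.8 52.6
write_wav(render_tts(fit), "severe.wav")   # 30 s at 44.1 kHz
```

A healthy phantom (no hypometabolism, no noise) yields all three tones
at exactly 440 Hz: a steady A with no beating.

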