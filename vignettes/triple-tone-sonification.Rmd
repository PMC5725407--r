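---
title: "Triple-tone sonification of PET brain metabolism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-tone sonification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tritone)
```

## The problem and the method

FDG-PET of Alzheimer's disease shows *hypometabolism* — reduced glucose
uptake — most prominently in the parietal (and, with progression, frontal)
lobes, while the sensorimotor cortex (SMC) is typically spared. `tritone`
turns this spatial pattern into sound so that the degree of disease can be
heard as frequency beating.

On a lateral slice through the brain, three regions are delimited by
straight-line polygons: frontal lobe (FL), parietal lobe (PL), and SMC.
Each region is assigned one triangular-wave oscillator. The SMC tone is
fixed at the base frequency $f_{default} = 440$ Hz; the other two are
detuned by the relative deviation of each lobe's average intensity from
the SMC average,

$$\Delta_{FL} = \frac{|av_{FL} - av_{SMC}|}{av_{SMC}}, \qquad
  f_{FL} = f_{default}\,(1 + DF\,|\Delta_{FL}|), \qquad
  f_{PL} = f_{default}\,(1 - DF\,|\Delta_{PL}|),$$

where $DF$ is a severity-dependent *detune factor* (normal 0.05, mild
0.10, moderate 0.15, severe 0.20). The frontal deviation is applied
upward and the parietal downward so that equal-magnitude deviations in
both lobes still give three distinct tones instead of collapsing into
two beating pairs. Mixing the three tones produces amplitude beating at
the pairwise frequency differences, $f_{default}\,DF\,|\Delta|$ for each
lobe against the base tone — the larger the metabolic deficit and the
more severe the category, the faster and more complex the beating.

A note on the parietal sign: descriptions of this mapping sometimes
write the parietal equation with a "+" as well. That variant defeats the
anti-collapse purpose of the sign convention, so the downward deviation
is the default here; the upward variant remains available through
`parietal_sign = "positive"` for comparison.

## Pipeline and parameters

1. **Input.** Volumes arrive in a line-oriented text dialect, one voxel
   per line (`x y z value`, 0-based coordinates, whitespace or comma
   delimited). The nominal geometry is $86 \times 100 \times 86$ voxels
   at 2 mm isotropic spacing with 15-bit intensities; other geometries
   are accepted. Values above the bit-depth maximum are an error, never
   clamped. Lobe boundaries come from a separate text file (region name
   followed by `x y` pairs); this file layout is the package's own
   plumbing, since contouring tools export coordinates in many forms.
   8-bit greyscale PNG projections can be sonified through the same
   path.
2. **Slice selection.** The diagnostic plane is the 30th slice from the
   top (0-based index 29), which at 2 mm spacing spans depths 58–60 mm
   and passes through representative frontal, parietal, and sensorimotor
   tissue. Slices are addressed ordinally from the top at the interface
   and 0-based internally.
3. **Masking.** White matter and background carry no diagnostic signal,
   so every pixel whose intensity falls below
   `fraction × (2^bit_depth − 1)` is excluded *before* averaging. The
   default fraction 0.45 gives 14745.15 at 15 bits. "Below" is read
   strictly: a value exactly at the threshold survives. With the
   non-integer threshold on integer data the tie can never occur at
   15 bits, but the rule must be fixed for other bit depths, and the
   strict reading is the literal one. The same fraction is applied at an
   image's own bit depth when sonifying 8-bit projections (threshold
   114.75), which keeps the rule scale-free.
4. **Segmentation.** Polygons are rasterized over pixel centers with a
   half-open even-odd rule: a center on a shared edge belongs to exactly
   one side, so adjoining regions tile the slice without gaps or double
   counting. Overlapping polygons are rejected with the offending pixel
   count. Pixels outside all three regions are never sonified.
5. **Mapping and rendering.** Masked regional means feed the equations
   above. Audio is an equal-amplitude (1/3 each) zero-phase mix of three
   ideal triangle oscillators, peak-limited to 1, rendered at 44.1 kHz
   for 30 s by default (the standard playback duration) and written as
   16-bit PCM mono WAV. Oscillator amplitude, phase, and any fade are
   unspecified upstream; equal amplitudes and zero phase are the
   simplest choice, and phase only shifts — never removes — beating.
   The ideal (non-band-limited) triangle is used because its harmonics
   decay as $1/k^2$, making aliasing inaudible at these fundamentals,
   and because the closed-form waveform is exactly testable.

The detune factor is supplied by the analyst — either a severity label
looked up in the table above, or an explicit number. Deriving severity
from the data itself is deliberately out of scope: the mapping validates
the auditory display, not a classifier.

## The synthetic phantom

Clinical volumes cannot ship with the package, so `generate_phantom()`
builds a deterministic stand-in with known ground truth: a gray-matter
ellipsoidal shell (default 80% of maximum intensity) over a white-matter
core (30%, safely below the 45% threshold), with three rectangular lobe
patches painted at gray-matter intensity into a five-slice band around
the diagnostic slice. The frontal and parietal patches are dimmed by
known fractions `hypo_fl`, `hypo_pl`; Gaussian noise of chosen standard
deviation is added to tissue voxels; intensities are rounded to integers
and truncated to the valid range. The boundary polygons are emitted with
half-pixel-offset corners so rasterization recovers exactly the painted
pixels.

Severity presets span the four categories with a parietal-dominant
pattern — normal (0, 0.02), mild (0.05, 0.10), moderate (0.12, 0.20),
severe (0.25, 0.35) as (frontal, parietal) fractions — plus noise at 1%
of the maximum intensity. These are calibration points of the generator,
chosen to keep all dimmed gray matter above the masking threshold and to
separate the four categories by clearly audible beat-rate differences at
the standard detune factors; they are not clinical measurements.

What the phantom does *not* emulate: anatomical lobe shapes, the
gray/white interface geometry, partial-volume effects, scanner PSF, or
inter-subject variability after spatial normalization. Passing tests on
phantoms therefore demonstrate that the pipeline computes its defined
quantities correctly, not that the auditory display is clinically
discriminative — that question needs listeners and real data.

## Numerical choices and degenerate inputs

- **Recovery precision.** With noiseless phantoms the recovered
  $\Delta$ equals the generative fraction only up to the integer
  rounding of intensities, an absolute error bounded by about
  $1/\mathrm{gm}$ (≈ 4×10⁻⁵ at defaults); tests assert at twice that
  bound. With noise, the deviation of the recovered $\Delta$ is
  predicted by propagating the standard errors of the two regional
  means, and tests assert within three such standard errors.
- **Determinism.** Phantom generation seeds R's RNG locally (restoring
  the caller's state); rendering is purely functional. Fixed seed and
  configuration give byte-identical volume files, WAVs, and reports.
- **Envelope analysis.** Beat rates are detected with a square-law
  detector (FFT of the mean-removed squared signal) rather than
  full-wave rectification: the squared envelope of a multi-tone mix
  contains exactly the pairwise difference frequencies, while the
  modulus envelope adds harmonics and combination tones of them.
  Spectral peaks use a Hann window so sidelobes stay below the triangle
  wave's third harmonic.
- **Degenerate cases.** A region with no surviving pixels has no mean
  and is an error naming the region; `DF·|Δ_PL| ≥ 1` would drive the
  parietal frequency non-positive and is a frequency-collapse error; a
  non-positive SMC mean cannot anchor the base tone and is an error.
  Silence yields an empty peak list rather than an error.
- **Problem sizes in tests.** Test renders use 2–5 s buffers (beat-rate
  resolution 0.2 Hz at 5 s is ample for rates ≥ 8 Hz) and the oracle
  suites use 100 random 86×100 slices and 10 random triangle
  segmentations; phantom studies use the full 86×100×86 geometry with
  20 seeded replicates per severity ordering check.

## Known limitations

Severity (hence the detune factor) is an input, not an inference. The
absolute value in $\Delta$ discards the sign of the deviation, so
hypermetabolism of equal size sounds identical to hypometabolism. Only
one slice is sonified; volumetric or multi-slice sonification, spatial
audio, and live synthesis are out of scope, as is any vendor-format
ingestion beyond the text dialects and PNG described above.
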