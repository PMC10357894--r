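---
title: "Wavelet-packet analysis of cw ESR spectra: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-packet analysis of cw ESR spectra: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esrwpt)
```

## The problem

A continuous-wave ESR spectrometer records the field-modulated first
derivative of microwave absorption against magnetic field. Hyperfine
interaction with nearby nuclei splits each electronic resonance into a
multiplet: n equivalent nuclei of spin I produce m = 2nI + 1 lines with
multinomial intensities, spaced by the coupling constant A (reported here in
gauss). When the intrinsic linewidth approaches A, the multiplet blurs into a
featureless envelope and the couplings become invisible to direct inspection;
the standard recourse, least-squares simulation of the whole lineshape, is
sensitive to starting values, artifacts and operator judgment.

`esrwpt` implements a simulation-free alternative: decompose the spectrum
into frequency bands with an orthogonal wavelet packet transform (WPT),
select the band that carries the (super)hyperfine oscillation, and read the
couplings off that component as runs of evenly spaced peaks. Evenness of the
inter-peak spacing — not amplitude — is the acceptance criterion that
separates genuine multiplets from artifacts.

## The transform

The engine is a periodized orthogonal two-channel filter bank (Daubechies-6,
Daubechies-9 or Coiflet-3 filters; Db9 is the default throughout). One
analysis step splits a length-n signal into a lowpass (approximation, `A`)
and highpass (detail, `D`) half, each decimated by two; the packet transform
applies the split recursively to *both* children, producing 2^j nodes at
level j. Synthesis is the transpose of analysis, so the decomposition is
exactly orthogonal: coefficient energy equals signal energy, and the
single-node reconstructions of any level sum to the input to machine
precision (both are asserted in the test suite at 1e-10 relative, and hold
even when node length falls below the filter length, because the even-lag
autocorrelations of an orthonormal scaling filter vanish identically).

Orthogonality has a price the user should know about:

* **Periodization, not symmetric extension, inside the bank.** Symmetric
  extension with orthogonal filters would break both the dyadic coefficient
  count and energy conservation. The package therefore resamples the
  spectrum onto a uniform grid (median step), pads it *symmetrically* to the
  next power of two once, up front (`to_uniform()`), and then treats it as
  periodic. The mirror pad keeps the wrap-around discontinuity of a
  derivative spectrum out of the detail bands.
* **No shift covariance.** The transform is decimated; peak *positions* on
  the field axis are recovered by reconstructing each node back to full
  length (zeroing all other nodes), which is an orthogonal projection and
  hence phase-neutral in aggregate.

Node paths are written root-to-node (`"AAD"` = detail split off the
twice-approximated branch at level 3); `paper_node_label()` renders the
conventional display form (`"DAA3"`).

## Component selection

The level-1 detail branch holds noise at any realistic digitization rate and
is never used. The working recipe is: follow the approximation chain until
the pure-`A` node shows only the coarse hyperfine envelope; the detail node
split off one level up — and, when useful, that node's own approximation
child — carries the superhyperfine structure. For a multiplet of spacing s
sampled at step Δ this happens at the selection level L for which the comb
frequency Δ/s falls inside the band (2^-L, 2^-(L-1)) cycles/sample; level 4
(structure node `AAD`) is the fixed default, matching the standard operating
regime, and is what `select_components(mode = "fixed")` returns.

Automatic selection (`mode = "auto"`) cannot rely on visual inspection, and
two failure modes dominate a literal "look for evenly spaced peaks" rule:

* band-limited noise in *any* detail node oscillates pseudo-periodically at
  the band's center frequency and readily forms 5–10 "evenly spaced" peaks;
* a strong comb leaks alias/harmonic images into neighboring nodes at folded
  or doubled spacings, which are just as even.

Both impostors share one property: their claimed spacing has no support in
the raw data. Auto mode therefore scores every candidate level by the raw
signal's periodogram at f = Δ/s (peak power near f relative to the median
power over the surrounding octave, with an absolute power floor so that the
numerically empty tail of a noiseless line cannot win on the ratio alone). A
level is admissible when the envelope node shows no fine-scale even run, the
structure node (or its child) shows a run of at least 4 lines, and the
spectral evidence exceeds 12; the strongest evidence wins, and when nothing
qualifies the recipe falls back to the fixed default, flagged
`fixed_default`. The 4-line floor is one more than the grouping minimum:
3-line pseudo-runs are ubiquitous in noise, while genuine multiplets that
break at phase slips still leave 4-line fragments.

The approximation child of the structure node covers only half its parent's
band, and which half holds the comb depends on the Gray-code band ordering;
when parent and child disagree on the spacing, the parent is kept (its band
contains the truth whenever the child's does) unless the parent's spacing has
no periodogram support at all while the child's has.

## Reading couplings off a component

`detect_peaks()` finds local extrema above a prominence floor (default 5% of
the in-window component maximum) and refines positions by three-point
parabolic interpolation. For multiplet work the pipeline uses maxima of the
*signed* component: a band-limited comb oscillates nearly sinusoidally, so
absolute-value extrema would appear at half the line spacing and double the
apparent multiplicity.

`find_even_groups()` accepts maximal runs of at least `min_lines = 3`
consecutive peaks whose spacing coefficient of variation is at most
`cv_tol = 0.10`; overlapping candidate runs resolve to more lines, then lower
cv; leftover peaks are reported as artifacts. The coupling constant is the
mean spacing of the accepted run.

Two numerical refinements matter in practice, both validated on synthetic
ground truth:

* **Band-centered re-measurement.** A single packet node whose band edge
  falls near the comb frequency carries an edge image that beats with the
  comb and biases the peak spacing by up to ~6%. Once an approximate spacing
  is known, the spacing and positions are re-measured on a zero-phase FFT
  band re-projection of the uniform signal centered on the comb frequency
  (iterated up to three times; each step must stay within 25% of the
  previous spacing and keep periodogram support).
* **Line centers from zero crossings.** The first derivative of a positive
  absorption line is odd about its center, so the band-limited component
  crosses zero *downward* at each line position, whereas its oscillation
  maxima sit a quarter period off. Quartet-edge fields are read at downward
  zero crossings for this reason.

## Cu(II) quartet analysis

In the g-perp window of a Cu(II) spectrum the copper nucleus (I = 3/2)
splits the resonance into four lines h-1…h-4 separated by A(Cu), each split
further into the m-line nitrogen multiplet. Overlap obscures the interior,
but the leading lines of the h-1 multiplet and the trailing lines of the h-4
multiplet are clean, and the outermost lines of the whole pattern are the
cleanest markers of all: h1 = lowest line + (m−1)/2·A and h4 = highest line −
(m−1)/2·A. Candidate multiplicities m = 2nI + 1 (n = 1..6) are scored by
*missing* edge lines only — overlap extends runs inward, so extra lines never
penalize — a candidate is valid only when the implied quartet outspans two
nitrogen spacings, and the largest valid zero-penalty m wins. Then
A(Cu) = (h4 − h1)/3 and g = 714.4773·ν[GHz]/B with B = (h1 + h4)/2
(714.4773 G·GHz⁻¹ is h/μ_B, CODATA 2018; the canonical 3203 G/3314 G quartet
at 9.316 GHz gives exactly A(Cu) = 37 G and g = 2.0427, which the test suite
asserts).

An honest accuracy statement for this regime, measured on the synthetic
benchmark (A(Cu) = 37 G, two nitrogens at 26.5 G, Gaussian peak-to-peak
width 18 G — truly unresolved): the four nitrogen manifolds interleave with
incommensurate offsets (37 mod 26.5 = 10.5 G), so the combined comb is
*chirped in the data itself*; every position-reading method, and the
periodogram, sees the nitrogen spacing biased by roughly +4 G and A(Cu) by
−3 G, while n is recovered exactly and g is exact because the edge biases
cancel about the quartet center. When the manifolds interleave nearly in
phase (the A(Cu) ≈ A(N) benchmark), the edge groups merge into one long run,
h-1/h-4 cannot be isolated, and the quartet is reported unresolved (`NA`)
rather than guessed — only the nitrogen spacing is returned.

## Mixtures

`mix_spectra()` forms weighted sums on the coarsest common grid (raw
summation by default; per-component normalization to unit maximum or unit
double integral is available because relative concentration only maps to
weight under equal per-spin intensity). `analyze_mixture()` reports, per
field window, every evenly spaced group with a component assignment, and
never uses amplitude for assignment.

The hard case is a minor component near the detection limit: its window also
contains the band-limited *continuation* of the major component's comb
(ringing), whose positions form an even run too, and at a 20:1 ratio the two
are comparable in size and beat against each other. Two measures make the
analysis reliable there:

* grouping tolerance widens to `cv_tol = 0.12` (the beat wobbles positions
  by ~15% of a period), while component *distinctness* keeps its own tighter
  5% spacing tolerance;
* assignment uses positional consistency against references measured from
  the pure components with the same read-out (`component_reference()`), so
  systematic offsets cancel. A pure component's reference is built per
  window independently, takes its spacing from the window that carries the
  component's signal energy, and contributes positions only from such
  windows — a low-energy window holds ringing that would later masquerade
  as a second component.

On the synthetic two-manifold panel (17 G five-line and 16 G seven-line
g-par multiplets, 8 G Gaussian width, SNR 100) mixed at 2:1, 4:1, 10:1 and
20:1, both components are identified at every ratio and the 1/21 ≈ 4.8%
minor fraction is detected in the majority of noise realizations; that
majority count over ten seeded realizations is exactly what
`scripts/acceptance.R` recomputes.

## The synthetic generator

`synth_esr` is a first-order, isotropic, region-wise simulator and must not
be mistaken for a physics engine: each `spin_system()` stands for one
locally regular multiplet (a g-perp quartet, a g-par manifold, an isotropic
nitroxide pattern), not for an anisotropic powder average; there are no
second-order shifts, no saturation or passage effects, and noise is white
Gaussian (`render_spectrum()` is bit-reproducible given a seed and restores
the caller's RNG state). Stick positions follow B₀ + ΣᵢAᵢmᵢ with multinomial
degeneracies — tested against brute-force enumeration up to n = 6 — and
sticks are convolved with the first derivative of an area-normalized
Gaussian or Lorentzian of given peak-to-peak width.

The benchmark presets fix the study conditions once:

| preset | content | sampling |
|---|---|---|
| `tempo_like` | ¹⁴N triplet (a = 17 G) + 12 protons at 0.20 G, Lorentzian widths 0.10/0.14/0.20/0.28 G | 4096 pts / 68 G (0.0166 G) |
| `tempol_like` | as above with 0.44 G protons, widths 0.22/0.31/0.44/0.62 G | 2048 pts / 102 G (0.05 G) |
| `cuqu_like` | quartet A(Cu) = 37 G, 2 N at 26.5 G, g = 2.0427, Gaussian 18 G | 228 pts / 500 G |
| `cuqua_like` | quartet A(Cu) = 23.3 G, 3 N at 21.3 G, g = 2.0411, Gaussian 15 G | 228 pts / 500 G |
| `gpar_*` / `mixture_panel` | 17 G (m=5) and 16 G (m=7) manifolds at 2640/2724 G, Gaussian 8 G, ratios 2:1…20:1 | 188 pts / 300 G |

Sampling steps are chosen so the comb frequency falls in the level-4
structure band (level-3 node `AAD`), the regime the default recipe targets;
the linewidth series run from resolved through just-unresolved (width = A) to
past the failure point — the 1.4·A member exists to exercise failure
reporting, not recovery. Lorentzian lines model exchange (oxygen) broadening
of nitroxides; Gaussian lines model frozen-solution Cu spectra. Default
noise is 1% of the maximum signal (SNR 100), a conservative value for X-band
cw work; the unresolved-recovery tests additionally run at SNR 50.

What passing these tests does *not* show about real data: powder-pattern
asymmetry, baseline drift, field-modulation distortion and g/A anisotropy
within a window are all absent from the generator, so real spectra may need
narrower user-chosen windows (the package deliberately has no automatic
g-par/g-perp segmentation) and may not reach the synthetic detection limits.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `wavelet` | `db9` | — | analysis filters; db6/coif3 for robustness checks |
| `level` | `auto` | — | decomposition level; fallback/fixed default 4 |
| `prominence` | 0.05 | fraction | peak floor, relative to in-window component max |
| `cv_tol` | 0.10 (0.12 mixtures) | fraction | spacing evenness tolerance |
| `min_lines` | 3 | lines | shortest accepted multiplet |
| `spin_I` | 1 | ħ | nuclear spin (1 = ¹⁴N, ½ = ¹H, 3/2 = Cu) |
| `pad_mode` | `symmetric` | — | dyadic padding of the resampled sweep |
| `distinct_tol` | 0.05 | fraction | spacing difference that separates mixture components |

Field units are gauss throughout; millitesla input is converted (×10) only
on explicit request at the reader.

## Known limitations

* Accuracy in the interleaved Cu(II) regime is bounded by the chirp of the
  data itself (see above); the couplings remain good enough to fix n, and g
  is exact, but sub-gauss A values should not be quoted from that regime.
* Amplitudes of recovered multiplet lines are not meaningful and are never
  asserted; overlap, residual noise and band edges distort them.
* Auto level selection is validated with the default Db9 wavelet; with
  other wavelets prefer an explicit level when the regime is known (the
  wavelet-robustness tests run at fixed level 4 for exactly this reason).
* The evidence statistic compares a candidate spacing with its spectral
  octave; pathological inputs whose power spectrum is engineered to be flat
  around a fake comb frequency can defeat it.
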