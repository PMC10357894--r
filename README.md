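# esrwpt

Simulation-independent analysis of continuous-wave ESR spectra by wavelet
packet decomposition.

A cw ESR spectrometer records the first derivative of microwave absorption
against magnetic field. Couplings to nearby nuclei split each resonance into
a multiplet — n equivalent spin-I nuclei give m = 2nI + 1 lines spaced by
the hyperfine constant A — but once the linewidth approaches A the multiplet
blurs into a featureless envelope and the standard remedy, full lineshape
simulation, depends on starting guesses and operator judgment. `esrwpt`
instead decomposes the spectrum with an orthogonal wavelet packet transform
(Db9 default; Db6/Coif3 for robustness checks), selects the detail component
that carries the (super)hyperfine oscillation, and reads the couplings off
that component as runs of *evenly spaced* peaks; uneven spacing marks an
artifact. From the recovered multiplets it computes:

* superhyperfine and hyperfine coupling constants A (gauss) and the implied
  number of coupled nuclei n = (m − 1)/(2I);
* Cu(II) quartet parameters from the clean edge multiplets of the g⊥
  window: A(Cu) = (h₄ − h₁)/3 and g = 714.4773 · ν[GHz] / B[G] with
  B = (h₁ + h₄)/2;
* minor components of two-component mixtures, identified by distinct line
  spacings and position-consistent line grids, down to a few percent
  relative concentration.

The package is a toolbox (readers/writers for two-column field sweeps, the
transform engine, component selection, peak/multiplet analysis, mixture
analysis) plus a seeded first-order simulator with known ground truth that
generates all test fixtures, and a command-line interface.

## Worked example

Recover a 0.20 G proton superhyperfine coupling from a nitroxide spectrum
broadened until the splitting is invisible, then analyze a synthetic Cu(II)
g⊥ quartet:

```r
library(esrwpt)

bench <- make_benchmark("tempo_like", seed = 42)
unresolved <- bench[[3]]$spectrum   # linewidth = A_H: comb invisible in raw data
extract_hyperfine(unresolved, extract_config(spin_I = 0.5))
#> <hyperfine_result>
#>   A_fine: 0.2062 G (spin I = 0.5, n = 8)
#>   component: DAA3 at level 4 (auto, db9 wavelet)

cu <- make_benchmark("cuqu_like", seed = 42)[[1]]
extract_hyperfine(cu$spectrum,
  extract_config(level = 4, windows = list(g_perp = cu$truth$window),
                 region = "g_perp"))
#> <hyperfine_result>
#>   A_fine: 30.43 G (spin I = 1, n = 2)
#>   A_Cu: 33.76 G, g = 2.04267 (quartet 3207.9, 3241.6, 3275.4, 3309.2 G)
#>   component: DAA3 at level 4 (fixed, db9 wavelet)
```

Reading the output: the first call recovers the proton splitting
(truth 0.20 G) to better than 0.01 G from a spectrum whose raw trace shows
no splitting at all; `n` counts the lines that survive the 5% prominence
floor (8 intervals of the 13-line proton pattern), not the true proton
count. The second call identifies two coordinated nitrogens (n = 2) and an
exact g value (truth 2.0427); the couplings carry a few-gauss bias that is a
property of the data in this overlapped regime, not of the method — see the
methods vignette (`vignettes/esrwpt-methods.Rmd`) for the quantified
accuracy envelope.

Mixture analysis uses the same pipeline per field window:

```r
panel <- make_benchmark("mixture_panel", seed = 1)   # 17 G vs 16 G manifolds
analyze_mixture(panel[[4]]$spectrum,                 # 20:1 mixture
                list(c(2596, 2684), c(2690, 2780)))
#> <mixture_report: 2 window(s), 1 distinct spacing component(s), minor (4.8%) detected>
#>   window 2596..2684 G: 5 lines @ 17.1 G [gpar_cuqu_like]
#>   window 2690..2780 G: 3 lines @ 17.7 G [gpar_cuqua_like]
```

At this extreme ratio only three of the minor's seven lines survive, and
their apparent spacing is pulled toward the major's by beat interference —
the positional match against the pure-component reference grid is what still
identifies them as the 16 G component.

## Command line

A thin wrapper over the same functions (see
`system.file("scripts", "esrwpt", package = "esrwpt")`):

```sh
esrwpt simulate --preset cuqu_like --seed 7 --out sim.csv
esrwpt extract --in sim.csv --wavelet db9 --level 4 \
       --window 3060:3460 --region g_perp --spin-I 1 --freq-ghz 9.316 \
       --out result.csv
esrwpt mix --in a.csv:20 --in b.csv:1 --out mixed.csv
esrwpt analyze-mixture --in mixed.csv --window 2596:2684,2690:2780 --out report.json
```

Every run writes a JSON run record (resolved options, package version, input
checksums) next to its output. Spectra are two-column text (field in gauss,
first-derivative intensity; `#`/`;` comments) or CSV with a
`field_g,intensity` header. Result files use stable keys: `A_fine_G`,
`n_nuclei`, `nuclear_spin`, `A_cu_G`, `g_value`, `h1_G`..`h4_G`, `region`,
`wavelet`, `level`, `node` for extractions; `window_lo_G`, `window_hi_G`,
`n_lines`, `mean_spacing_G`, `spacing_cv`, `span_G`, `center_G`,
`line_positions_G`, `assigned_component`, `minor_detected`,
`minor_fraction` for mixture reports.

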