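# g4ionx

Quantitative analysis of monovalent-cation exchange in DNA G-quadruplexes
from solution NMR and CD observables.

G-rich telomeric DNA folds into G-quadruplexes (G4s): stacked planar
G-tetrads with Na⁺ or K⁺ coordinated in the central channel. Swapping Na⁺
for K⁺ changes the CD and imino-proton NMR spectra dramatically even when
the fold itself does not change, and the workhorse sequence Tel23
(d[TAGGG(TTAGGG)₃]) is the model system for asking *how* the cations are
exchanged. `g4ionx` is for spectroscopists and structural biologists who
have assigned peak lists, titration series, kinetic traces or melting
curves in hand and want the downstream numbers reproducibly:

* **Stepwise exchange isotherm.** Ion replacement runs through a mixed
  di-cation intermediate, a (Na·Na) ⇌ b (Na·K) ⇌ c (K·K), with species
  fractions

  f<sub>a</sub> = 1/D,  f<sub>b</sub> = K₁x/D,  f<sub>c</sub> = K₁K₂x²/D,
  D = 1 + K₁x + K₁K₂x²,

  fitted per residue to the disappearing Na⁺-form and appearing K⁺-form
  imino intensities (`fitExchange()`), with the intermediate recovered by
  mass balance (`intermediatePopulation()`).
* **Kinetics.** Mono- and bi-exponential fits of HDX decays,
  hybridization-trap traces and real-time CD conversion
  (`fitMonoexp()`, `fitBiexp()`), condition summaries and fold
  differences with propagated uncertainty.
* **NOE distances.** Buildup initial slopes and r⁻⁶ calibration against
  the 2.99 Å thymine H6–CH3 reference, grouped statistics and Welch
  comparisons (`buildupSlope()`, `calibrateDistance()`,
  `distanceStats()`).
* **Topology.** Tetrad detection as directed H1→H8 4-cycles, glycosidic
  syn/anti calls from H1′–H8 NOEs, strand orientations, loop taxonomy and
  a named fold label (`inferTopology()`).
* **Melting.** Baseline-corrected derivative Tm extraction and a
  two-state sigmoid cross-check (`extractTm()`, `fitTwoState()`).
* **Synthetic data.** Generators for every input with Tel23 scenario
  presets (`genTitration()`, `genKineticTrace()`, `genNoesyPeaks()`,
  `genMeltingCurve()`), so the whole pipeline runs self-contained.

## Worked example

Simulated Tel23 titration at 2% noise, fitted with the stepwise model:

```r
library(g4ionx)
sim <- genTitration(noise_sd = 0.02, seed = 7)   # G22 preset, 0-150 mM
fitExchange(sim$na, sim$k)
#> ExchangeFit (residue 22, joint mode):
#>   K1 = 57.83 +/- 1.37 /M, K2 = 2.735 +/- 0.0774 /M (ratio 21.1)
#>   rss = 0.02334 over 62 points
```

K₁ ≫ K₂: the first K⁺ binds far more favourably than the second, and the
~21-fold ratio means a mixed Na⁺·K⁺ intermediate is well populated at
intermediate K⁺. The real-time CD conversion signal is biphasic:

```r
fitBiexp(genKineticTrace("tel23_cd_conversion", noise_sd = 0.02, seed = 7))
#> KineticFit (bi-exponential):
#>   tau1 = 78.58 s (89.1%), se 1.86
#>   tau2 = 919.5 s (10.9%), se 99.9
#>   offset = 0.9993, total amplitude = -0.996, R2 = 0.9698
```

— most of the spectral conversion happens on the ~80 s timescale, far
faster than the >2 h global unfolding time measured by HDX and
hybridization, which is the kinetic argument that the exchange proceeds
without unfolding. Topology from an assigned NOESY peak table:

```r
pt <- genNoesyPeaks("tel23_noesy_na", seed = 7, noise_sd = 0.02)
inferTopology(pt, tel23Sequence())
#> TopologyModel: hybrid-I (3+1)
#>   top tetrad (anticlockwise): G3->G21->G17->G9
#>   central tetrad (clockwise): G4->G10->G16->G22
#>   bottom tetrad (clockwise): G5->G11->G15->G23
#>   orientations: tract1=up, tract2=up, tract3=down, tract4=up
#>   loops: double-chain-reversal, lateral, lateral
```

Three tetrads, one counter-running G-tract, a double-chain-reversal loop
followed by two laterals: the hybrid-I (3+1) fold. And the K⁺-form
melting curve:

```r
extractTm(genMeltingCurve("tel23_melting_k", noise_sd = 0.01, seed = 7))
#> MeltingResult (derivative): Tm = 68.60 degC, derivative peak 0.0833 /degC
```

`runTel23Report(seed = 1, out_dir = "demo")` chains all stages on
synthetic inputs and writes JSON/CSV outputs with full provenance; the
same seed reproduces the files byte for byte.

## Layout

* `R/` — S4 classes (`G4Sequence`, `NOESYPeakTable`, `TitrationSeries`,
  `KineticTrace`, `MeltingCurve`, fit/result classes) and the analysis
  stages.
* `tests/testthat/` — unit, property and oracle tests (brute-force cycle
  enumeration, exhaustive grid-search fits, Monte-Carlo error
  propagation).
* `vignettes/g4-cation-exchange.Rmd` — the methods vignette: model,
  assumptions, estimator choices, generator design, limitations.
* `scripts/acceptance.R` — the reproduction script above.
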