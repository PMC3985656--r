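---
title: "Methods: cation exchange, kinetics and topology of G-quadruplex NMR data"
author: "g4ionx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cation exchange, kinetics and topology of G-quadruplex NMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4ionx)
```

## Scope and scientific setting

Human telomeric G-rich DNA folds into G-quadruplexes (G4s): stacks of
planar G-tetrads, each a Hoogsteen-bonded cycle of four guanines, with
monovalent cations (Na⁺ or K⁺) coordinated in the central channel. The
same sequence can adopt different folds under different cations, and
replacing Na⁺ by K⁺ produces large CD and imino-proton NMR spectral
changes even when the fold does not change. `g4ionx` implements the
quantitative analyses that disentangle these effects for a 23-nt telomeric
model sequence, Tel23 (d[TAGGG(TTAGGG)₃]):

* a three-state stepwise cation-exchange isotherm fitted to per-residue
  imino-proton titration curves (`speciesFractions()`, `fitExchange()`);
* mono- and bi-exponential kinetics of hydrogen–deuterium exchange (HDX),
  complementary-strand hybridization traps, and real-time CD conversion
  (`fitMonoexp()`, `fitBiexp()`);
* inter-proton distances from NOESY buildup initial slopes calibrated
  against the fixed thymine H6–CH3 geometry (`buildupSlope()`,
  `calibrateDistance()`);
* rule-based topology inference from NOE connectivity and glycosidic
  syn/anti evidence (`inferTopology()`);
* CD melting-temperature extraction (`extractTm()`).

No spectra are processed: the package starts from assigned peak lists and
tabular series, the form in which such data leave an NMR/CD workup. A
synthetic-data module (`genTitration()`, `genKineticTrace()`,
`genNoesyPeaks()`, `genMeltingCurve()`) generates every input with the
statistical structure the analyses assume, so the full pipeline runs and
is tested without any external data.

## The stepwise exchange model

A three-tetrad G4 holds two channel cations. Exchange of Na⁺ for K⁺
proceeds through a mixed di-cation intermediate:

$$\mathrm{a\ (Na\cdot Na)} \xrightleftharpoons{K_1}
  \mathrm{b\ (Na\cdot K)} \xrightleftharpoons{K_2}
  \mathrm{c\ (K\cdot K)}$$

With $x$ the added K⁺ concentration and mass balance
$f_a + f_b + f_c = 1$, the species fractions are

$$f_a = \frac{1}{D},\qquad f_b = \frac{K_1 x}{D},\qquad
  f_c = \frac{K_1 K_2 x^2}{D},\qquad D = 1 + K_1 x + K_1 K_2 x^2 .$$

This is the unique two-constant stepwise form consistent with the scheme
above; it is implemented directly in `speciesFractions()`. Useful
consequences, all covered by property tests: the fractions sum to one for
every $x \ge 0$; $f_a$ is strictly decreasing and $f_c$ strictly
increasing; $f_b$ is unimodal with its maximum at $x^* = 1/\sqrt{K_1 K_2}$;
and rescaling $x$ by $s$ while dividing both constants by $s$ leaves all
fractions unchanged (so the unit convention is pure bookkeeping).

**Units.** Constants are reported per molar. With $K_1 \approx 60$/M the
first transition midpoint falls near 17 mM, consistent with titrations
that saturate around 150 mM added K⁺; a per-mM convention would put the
whole transition below 1 mM. Concentrations are converted from the
series' declared unit (`mM` default).

**Observables.** The disappearing Na⁺-form imino intensity of a residue
tracks $f_a(x)$ and the appearing K⁺-form intensity tracks $f_c(x)$.
`fitExchange()` fits both curves jointly by Levenberg–Marquardt least
squares in $(\log K_1, \log K_2)$; a sequential mode (first-step constant
from the disappearance curve, second-step constant refined on the
appearance curve) mirrors fitting the two curves separately. The surface
is bilinear in log space and single-start fits stall, so optimization is
multi-start over a $5\times5$ log grid ($K \in \{0.1,1,10,100,1000\}$),
screening starts by residual and refining the best three. Box bounds
($10^{-4}$–$10^{6}$) catch degenerate data; an estimate pinned at a bound
is flagged (`boundary_K1`), not silently returned. Standard errors come
from the Gauss–Newton covariance at the optimum via the delta method.

The mixed-form population is not directly observable.
`intermediatePopulation()` recovers it by subtraction,
$f_b^{obs} = 1 - f_a^{obs} - f_c^{obs}$, clipping to $[0,1]$ and
reporting the clip count rather than hiding it.

**Normalization.** Raw intensities are anchored by `normalizeSeries()`:
the zero-titrant intensity maps to 1 (Na⁺ form) or 0 (K⁺ form) and the
end plateau — the mean of the trailing 10% of points — to the other
anchor. Peak heights with endpoint anchoring are assumed because nothing
finer (integrals, a reference resonance) survives into a peak list. The
anchoring is exactly idempotent. The fractional range check
($[-0.05, 1.05]$, small overshoot tolerated) is a warning, not an error,
because honest noise at the 2% level occasionally overshoots.

**Per-layer structure.** Bottom-tetrad residues exchange their lower
cation site more reluctantly (their first-step constants run 2- to 5-fold
below the rest). `perResidueSummary()` aggregates fitted constants by
tetrad layer and reports the (non-bottom)/(bottom) mean-$K_1$ ratio; the
generator emulates the lag through a per-residue $K_1$ multiplier.

## Exponential kinetics

All kinetic fits use the single family
$S(t) = \mathrm{offset} + A\sum_i f_i e^{-t/\tau_i}$ with $\sum f_i = 1$
and signed $A$ (negative for rises, so the offset is always the plateau).
The source data never state a fitted equation beyond "bi-exponential",
so the standard offset-plus-exponentials form is used, with direction
auto-detected from the endpoints.

`fitMonoexp()` seeds itself from a log-linear regression of the
plateau-subtracted signal and refines by Levenberg–Marquardt. Points
earlier than the trace's dead time are excluded, not extrapolated —
no information exists before the first observable point (e.g. the ~85 s
to the first NMR spectrum after mixing). A constant trace, or a time
constant escaping to $10^4\times$ the sampled span, yields a `no_decay`
flag.

`fitBiexp()` is initialized by variable projection: on a log-spaced grid
over $(\tau_1, \tau_2)$ the amplitudes and offset are solved linearly at
each node, and the best node seeds the nonlinear refinement. This makes
the 4-parameter fit effectively global without luck in starting values;
if refinement fails on a degenerate (effectively mono-exponential)
surface, the best grid node is returned. Time constants closer than
1.5-fold, or a minor amplitude below 1%, raise a `degenerate_taus` flag
recommending the mono model. Amplitudes are reported as percentages of
the total, matching the convention in which a fast phase is quoted as
"89%".

`summarizeCondition()` reduces per-residue fits to mean ± sample SD, and
`foldDifference()` forms ratios between conditions with first-order
error propagation
($\mathrm{se} = r\sqrt{(s_a/\mu_a)^2 + (s_b/\mu_b)^2}$), which a
Monte-Carlo test confirms at moderate spreads.

## NOE distances

Under the isolated spin-pair approximation the NOESY cross-peak buildup
rate scales as $r^{-6}$. `buildupSlope()` estimates initial rates by an
origin-constrained regression over the recorded mixing times (50, 100,
150, 200 ms for exchangeable protons). Because "initial slope" is an
estimator choice, a curvature guard handles spin-diffusion flattening:
while any retained point deviates from the origin line by more than 5% of
its own intensity, the longest mixing time is dropped (floor of two
points). On a saturating buildup with a 300 ms time constant this
iterative guard keeps the estimate within 15% of the true initial rate,
which a single fixed drop does not. The non-exchangeable-proton NOESY
recorded at a single 200 ms mixing time takes a single-point path
($I/t$, flagged).

`calibrateDistance()` applies
$r = r_{\mathrm{ref}}(s_{\mathrm{ref}}/s)^{1/6}$ against the thymine
H6–CH3 reference (2.99 Å). The calibration is exact on generator output
(the generator builds intensities by the same physical law — slope
$\propto r^{-6}$, linear buildup — which is the law itself, not a copy of
the estimator). `distanceStats()` and `compareConditions()` supply the
grouped means ± SD per proton-pair class and the Welch two-sample test;
Welch is chosen because the compared groups have visibly unequal
variances (0.2 vs 0.4 Å scales), and the degenerate all-constant case is
defined explicitly (equal means → p = 1).

## Topology inference

The engine formalizes what a spectroscopist reads off a NOESY spectrum:

1. **Glycosidic calls** (`classifyGlycosidic()`): a syn guanine gives a
   strong intra-residue H1′–H8 NOE (≈2.5 Å), an anti guanine a weak one
   (≈3.7 Å). Calibrated distances are thresholded at 3.3 Å, the midpoint;
   on clean data the calls are insensitive to any threshold in
   2.6–3.6 Å. Missing evidence yields an explicit "uncalled" entry.
2. **Tetrad detection** (`detectTetrads()`): directed H1→H8 inter-guanine
   links form a graph whose directed 4-cycles spanning four distinct
   G-tracts are the tetrads. The search is exhaustive on these small
   graphs and is tested against an independent brute-force enumeration
   over ordered 4-subsets. Peaks below 10% of the median imino–aromatic
   intensity are excluded first, suppressing minor-conformation
   artifacts.
3. **Layers and sense**: layers (top/central/bottom) follow the
   within-tract position of each tetrad's first-tract guanine, with
   inter-tetrad imino–imino NOEs as a cross-check that errors on
   contradiction rather than guessing. A tetrad's rotational sense is
   defined by whether its cycle runs forward or backward around the
   canonical tract ring.
4. **Orientations** (`inferOrientations()`): within a tetrad,
   same-direction strands share their glycosidic state and a
   counter-running strand flips it. Each tetrad's pattern therefore
   reduces to a partition (all-equal → all parallel; 3-to-1 → the
   minority tract is antiparallel; 2-to-2 → a (2+2) arrangement). The
   partitions must agree across tetrads; tract 1 anchors "up".
5. **Loops and label** (`classifyLoops()`, `classifyTopology()`): a loop
   joining parallel ring-adjacent tracts is a double-chain-reversal
   (propeller) loop; antiparallel ring-adjacent → lateral; antiparallel
   diagonal → diagonal. The final label is a total, deterministic
   decision table: all-parallel/3×reversal → parallel propeller; one
   antiparallel tract → hybrid (hybrid-I when the reversal loop comes
   first, hybrid-II when last); two antiparallel →
   lateral–diagonal–lateral basket, all-lateral chair, or generic (2+2).
   Patterns outside the table return `"unclassified"` rather than a
   forced call.

The five canonical folds (propeller, basket, chair, hybrid-I, hybrid-II)
round-trip: peak tables generated from each fold classify back to it.
The real determination also leaned on expert inspection; this rule set is
a formalization, and folds outside the canonical five (e.g. exotic (2+2)
variants) are labelled but not guaranteed.

```{r topology}
pt <- genNoesyPeaks(topology = "hybrid-I")
inferTopology(pt, tel23Sequence())
```

## Melting analysis

`extractTm()` reads the melting temperature from the derivative of the
295 nm ellipticity trace. Linear folded/unfolded baselines are fitted to
the terminal 10% temperature windows and the curve is converted to a
folded fraction, which makes the result exactly invariant under affine
transforms of the ellipticity axis. The derivative is computed with a
Savitzky–Golay filter (order 2, 5 °C default window) and its extremum,
refined by parabolic interpolation, is the Tm. "First derivative zero
point" language in melting protocols is read as the extremum of the first
derivative (equivalently the zero of the second): derivative insets of
melting data show peaks, not zero crossings, at the transitions. Curves
without a resolvable transition (baseline separation or derivative peak
within 3× the noise) raise an explicit error. `fitTwoState()` — a full
sigmoid-with-baselines fit — serves as an independent cross-check and
agrees within 0.3 °C on clean curves.

## The synthetic-data module

The generators define the study conditions; their defaults are the
conditions the analyses target, not tuning knobs:

| Generator | Default conditions |
|---|---|
| `genTitration()` | $K_1 = 59.7$/M, $K_2 = 2.7$/M (residue G22), 0–150 mM in 5 mM steps |
| `genKineticTrace("tel23_hdx_na")` | mono decay, τ = 14 min, 0–120 min every 5 min |
| `genKineticTrace("tel23_hdx_nak")` | mono decay, τ = 136 min, 0–600 min every 10 min |
| `genKineticTrace("tel23_hybridization")` | shared-τ decay/rise pair; τ = 17 / 127 / 130 min by condition |
| `genKineticTrace("tel23_cd_conversion")` | bi-exponential rise, 80 s at 89% + 930 s at 11%, 0–3600 s every 5 s |
| `genNoesyPeaks()` | r⁻⁶ intensities, linear buildup at 50/100/150/200 ms; tetrad distance moments 5.1 ± 0.2 / 4.9 ± 0.6 Å (Na⁺), 4.6 ± 0.4 / 4.3 ± 0.3 (K⁺), 4.3 ± 0.4 / 4.0 ± 0.3 (mixed); syn/anti H1′–H8 at 2.5/3.7 Å |
| `genMeltingCurve()` | Tm 68.9 °C (K⁺) / 59.3 °C (Na⁺), width 2.5 °C, 25–95 °C every 0.5 °C |

Real-data noise levels are unreported, so the default noise is a package
choice of 2% of amplitude, exposed in every generator. The melting width
of 2.5 °C corresponds to a van't Hoff enthalpy near 50 kcal/mol, typical
for a three-tetrad quadruplex. Every generator is deterministic given a
seed, restores the caller's RNG state, and records seed and configuration
in output attributes.

What the generators emulate — and what they do not: they produce the
exact statistical structure the estimators assume (three-state fractions,
clean exponentials, r⁻⁶ intensities, two-state sigmoids) plus Gaussian
noise. They do not simulate baseline drift, peak overlap, spin diffusion,
partially folded species or minor conformers beyond an optional weak-peak
flag. Passing tests therefore demonstrate correctness of the estimators
under their stated model, not robustness to every pathology of real
spectra.

## Numerical choices and problem sizes

* Exchange fits run in log-parameter space with bounds $[10^{-4},10^{6}]$;
  multi-start screening keeps the per-fit cost at a few milliseconds.
* The noisy-recovery property for the exchange constants uses a 21-point
  grid reaching 1 M because its premise is a titration spanning *both*
  transitions; the second midpoint ($1/K_2 \approx 0.37$ M) lies beyond a
  150 mM window.
* The mono-exponential recovery property samples densely over the first
  1.5 time constants and sparsely over the plateau (50 points), the
  standard design for estimating exponential time constants; uniform
  sampling over 8τ leaves the 5% target at the Cramér–Rao boundary.
* Property suites use 200 seeded replicates (titration and mono-τ
  recovery, melting noise), 20 random graphs for the cycle-search oracle,
  and 200×200 log grids for the brute-force fit oracles. The full test
  suite runs in well under a minute on one core.
* Tie-breaks and degeneracies error or flag explicitly: layer-order
  contradictions, inconsistent glycosidic partitions, boundary-pinned
  constants, sub-1.5-fold time-constant ratios, no-transition melting
  curves.

## Known limitations

* No relaxation-matrix (spin-diffusion) correction; the curvature guard
  only trims, and mixed-condition spin-diffusion controls are out of
  scope.
* Two-constant stepwise binding only — no Hill cooperativity, no >2-site
  schemes, no ion-specific electrostatics.
* Stretched exponentials and global multi-residue fits are not offered.
* Topology inference assumes a four-tract, three-tetrad core with
  complete glycosidic evidence for tetrad guanines; two-tetrad folds and
  incomplete evidence yield errors or uncalled entries by design.
* The normalization procedure for titration intensities (peak height,
  endpoint anchors) is an assumption; integral-based normalization would
  need upstream support.
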