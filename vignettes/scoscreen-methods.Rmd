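---
title: "Methods: models, conventions and design choices in scoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in scoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoscreen)
```

`scoscreen` implements the computational layer of a single-cell-oil (SCO)
screen of oleaginous yeasts: fatty-acid composition bookkeeping, biodiesel
fuel-property prediction, culture growth and lipid kinetics, and in-silico
PCR-RFLP strain typing. This vignette explains each model, the tunable
parameters and their defaults, the numerical conventions, and what the
synthetic-data generators do and do not emulate. The packaged reference
fixtures come from a seven-strain screen of kefir yeast isolates grown on
glucose, lactose and glycerol in yeast-peptone and deproteinated potato
wastewater media.

## Fatty-acid profiles

A profile is a compositional vector: weight-% of total fatty acids per acid,
for one strain in one medium. Acids are identified by the GC shorthand
`C<carbons>:<double bonds>` with an optional omega suffix (`"C18:3 n-3"`);
comparison is by the parsed triple, never by string. Odd-chain acids such as
C17:1 are handled like any other — no even-chain assumption exists anywhere.

Two conventions matter downstream:

* **"n.d." is exactly zero.** Composition tables mark undetected acids with
  "n.d. = not detected". These become *absent* entries that contribute 0 to
  every sum. Treating them as missing-at-random would make the compositional
  sums (and everything derived from them) undefined.
* **Sum tolerance.** A reported profile should total 100 %. The default
  tolerance is 0.5 percentage points — published tables typically close to
  100.00, user data often do not. Outside the tolerance the reader warns;
  in strict mode (used for the packaged fixtures in the tests) it errors.

Unsaturation classes partition acids by double-bond count: SFA (0),
MUFA (1), DUFA (2), TUFA (3), PUFA4 (≥ 4). `group_totals()` conserves mass:
the five class totals always sum to the profile total.

One limitation inherited from the data: positional/geometric isomer
information beyond the label is dropped. The dominant C18:1 of these yeasts
is the *cis*-9 isomer (oleate), but the label keys carry no isomer field.

## Biodiesel property panel

For weight percentages %MU, %DU, %TU of mono-, di- and tri-unsaturated
esters, carbon counts $nC_n$ and weight-% $c_n$:

$$UD = \frac{1\cdot\%MU + 2\cdot\%DU + 3\cdot\%TU}{100}, \qquad
LC = \frac{\sum_n nC_n\, c_n}{100},$$

$$LCV = 29385.4 + 486.866\,LC - 387.766\,UD \;\; [\mathrm{kJ\,kg^{-1}}],$$

$$\mu = -1.8327 + 0.209794\,LC + 0.738911\,UD + 0.0166791\,LC^2
      - 0.16336\,LC\,UD + 0.335547\,UD^2 \;\; [\mathrm{mm^2\,s^{-1}}].$$

Design choices that were genuinely open:

* **Acids with ≥ 4 double bonds contribute to LC and CN but not to UD.**
  The UD formula has only mono/di/tri terms; the package stays literal to it
  rather than extrapolating a quad term. For the packaged profiles (up to
  8 % C20:4) this is a visible, documented choice.
* **Internal normalization.** UD and LC divide by the actual profile total,
  so both are invariant under uniform rescaling and under `normalize_profile()`.
* **Rounding discipline.** LCV and viscosity are always evaluated from the
  *unrounded* UD and LC of the same profile; rounding (half-to-even, 2 dp)
  happens only in `format_fuel_report()`. The test suite demonstrates that
  feeding 2-dp-rounded intermediates into the LCV polynomial shifts the
  result by several kJ/kg — enough to miss the reference values.
* **Per-ester cetane numbers.** No canonical CN_ME set exists in the source
  data, so the default table (`fame_cetane_v1.csv`) is computed from the
  published structural correlation $CN = -7.8 + 0.302\,MW - 20\,DB$ (FAME
  molecular weight in g/mol, DB double bonds), which tracks measured FAME
  cetane numbers well across C12–C24. The table is versioned, results carry
  the version tag, and any user table (CSV or inline config) replaces it.
  Mixture CN is reported against the two biodiesel-standard minima
  (EN 14214: 54, ASTM D6751: 47) as an annotation, not a pass/fail gate.
* **Flash point is a pluggable model.** There is no printed FP equation to
  be literal to. The default `"ester_mixture"` model is a weight-fraction
  mixture of approximate per-ester literature flash points
  (`fame_flashpoint_v1.csv`); `"none"` disables the estimate. FP carries
  more uncertainty than the other properties and is excluded from the
  package's reproduction checks.

## Culture kinetics

Endpoint arithmetic is deliberately plain: $Q = \mathrm{conc}/\mathrm{duration}$
(reported at 3 dp, round-half-to-even), lipid content $= 100\cdot
\mathrm{lipids}/\mathrm{biomass}$ (% CDW, 1 dp), generation time
$\ln 2/\mu$. The packaged endpoint table uses the screen's fixed 96 h
incubation. Rows where lipids exceed biomass are physically impossible and
are flagged, excluded and warned about rather than propagated. C:N:P ratios
take elemental masses directly (deriving them from medium recipes would
require unstated elemental compositions of peptone or wastewater).

The specific growth rate is the log-OD slope,
$\mu = (\ln OD_f - \ln OD_i)/(t_f - t_i)$, with endpoints linearly
interpolated in log-OD when they fall between samples.

**Log-phase detection** is the one invented algorithm in this module (growth
screens traditionally read the window off the curve by eye). The package
fits log(OD) against time in every sliding window of at least `min_points`
samples (default 5) and returns the window with the highest R², with ties
broken in favour of longer and then earlier windows; if the best window has
R² below `r2_min` (default 0.98) the series is deemed to lack an exponential
phase. Maximizing R² (rather than taking the longest window above a
threshold) matters: R² grows with window length inside a truly exponential
stretch and drops as soon as the window swallows lag or plateau points, so
the maximizer trims the phase boundaries. On noiseless piecewise curves it
recovers planted boundaries to within one sampling interval; the
longest-above-threshold rule, by contrast, over-extends into the lag and
biases $\mu$ low by over 10 %. Windows containing non-positive OD readings
are skipped; constant-OD windows get R² = 0 by convention (no growth signal).

## In-silico PCR-RFLP typing

Sequences are restricted to the unambiguous A/C/G/T alphabet (ambiguity
codes error out). Coordinates are between-base: a cut at position $k$ splits
$[1,k]$ and $[k+1,n]$. HaeIII (GG^CC) and RsaI (GT^AC) are built in with
their standard recognition sites; both are palindromic blunt cutters, so
scanning only the top strand is complete — asserted by a
reverse-complement property test, with Biostrings pattern matching as an
independent oracle for the site scan itself. Digestion always conserves
length: fragment lengths sum exactly to the input length.

**Pattern matching** formalizes the visual gel comparison. Per enzyme,
observed and reference fragments are paired greedily largest-to-largest;
the score is the summed absolute bp discrepancy plus a penalty of
`tol_bp` + fragment length per unmatched fragment. Greedy assignment was
chosen over optimal bipartite matching for transparency at gel resolution;
it is documented as replaceable. The gel tolerance default is 20 bp,
justified by the packaged reference set itself: one strain's HaeIII
fragments sum to 680 bp against a 690 bp amplicon, a typical band-size
estimation error, and the whole set is self-consistent at 20 bp while that
entry fails at 5 bp (kept as-is, not corrected).

Two facts about the packaged reference data shape what the tests can claim:

* The three *D. hansenii* isolates share one identical fragment pattern, so
  they tie at score 0 and are genuinely indistinguishable by this method;
  ranking ties keep database order.
* The packaged ITS sequences are *partial* amplicons (326–484 bp, shorter
  than the 460–700 bp gel-estimated products), so their in-silico digests
  are checked for digestion invariants, not for equality with the
  gel-derived reference patterns.

## Synthetic data: what it emulates, what it does not

All generators are pure functions of (seed, parameters).

* **Profiles** are Dirichlet perturbations of a template: entry $i$ is drawn
  as Gamma(concentration · template$_i$/100) and the vector is rescaled to
  100 %. Compositions live on a simplex; additive Gaussian noise would break
  the sum invariant. Concentration 500 gives the few-percent relative
  scatter typical of replicate GC-FID measurements; `Inf` returns the
  template. Undetected template entries stay at zero.
* **Growth curves** are piecewise lag / exact-exponential / hard-plateau
  curves sampled every 0.25 h (the plate-reader cadence), with
  multiplicative log-normal noise because OD error scales with signal
  (σ = 0.02 matches the replicate scatter of the packaged endpoint data).
  The noiseless curve's log-slope equals the planted $\mu$ exactly, which is
  what makes the generator a round-trip oracle. Real curves have smooth
  phase transitions, diauxie and drift; passing the recovery tests
  therefore shows the estimators are correct on the assumed shape, not that
  the shape covers all real growth behaviour.
* **Sequences** plant recognition sites at requested cut positions on a
  uniform background and patch any accidental site occurrence (bounded
  retries), so digests recover exactly the planted fragment multiset. Real
  ITS sequences have base-composition bias; none is modelled, since the
  digestion arithmetic is composition-agnostic.

## Numerical conventions and degenerate inputs

Round-half-to-even everywhere rounding is applied (R's `round`); 2 dp for
fuel properties, 3 dp for productivities, 1 dp for % CDW. Empty profiles
error in every property computation. Zero-total profiles cannot be
normalized. Windows with $t_f \le t_i$, non-positive OD at endpoints,
non-positive $\mu$ in generation time, zero duration, lipids > biomass and
N = 0 in ratio normalization all raise immediate, specific errors.

## Problem sizes used by the test suite

The property-based checks run 1000 random profiles (oracle equivalence of
UD/LC/CN to 1e-12), 1000 random sequences (digestion conservation and
reverse-complement invariance), 100 noisy growth curves at σ = 0.02 (median
recovery error of $\mu$ under 5 %; observed ≈ 0.5 %), and 50 planted-site
sequences (exact fragment round-trip). These sizes give stable pass/fail
behaviour at fixed seeds while keeping the default test run fast.

## Known limitations

* UD ignores ≥ 4-double-bond esters by construction; profiles rich in
  long-chain PUFA are at the edge of the correlations' calibration range.
* Default CN_ME and FP tables are correlation- and literature-derived, not
  measured for these specific oils; both are overridable and versioned.
* Greedy fragment assignment can in principle mis-pair when fragment counts
  differ and sizes interleave tightly; at gel resolution this has no effect
  on the packaged set.
* Log-phase detection assumes a single exponential phase; diauxic curves
  will return only the most linear stretch.
* No gel-mobility modelling, primer-site simulation, alignment-based
  identification or mechanistic lipid-accumulation modelling is attempted.
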