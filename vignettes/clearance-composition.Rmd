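---
title: "Series clearance composition, gut-clearance estimation, and the crossover simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Series clearance composition, gut-clearance estimation, and the crossover simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirchpk)
```

## The model

`kirchpk` treats pharmacokinetic absorption and elimination as composable
*rate-defining* processes. A rate-defining parameter is one that could, under
some condition, equal the total observed clearance or rate constant — hepatic
blood flow for a high-extraction drug, or the absorption rate constant in
flip-flop kinetics. Two composition laws cover linear first-order systems:
parallel processes add (`CL_total = ΣCL_i`, `k_total = Σk_i`) and in-series
processes add reciprocally (`1/CL_total = Σ1/CL_i`, `1/k_total = Σ1/k_i`).

Applied to dosing through an absorption site, the series law gives

$$\frac{1}{CL_\text{after oral}} = \frac{1}{CL_\text{gut}} + \frac{1}{CL_\text{iv}},
\qquad
\frac{1}{k_\text{overall}} = \frac{1}{k_a} + \frac{1}{k_\text{iv bolus}}.$$

The rate-constant form is familiar: it is the mean-residence-time identity
`MRT_oral = MAT + MRT_iv` written for the reciprocal rate constants, and it is
why a very slow `ka` becomes the terminal slope (flip-flop). The clearance
form is the consequential one: the clearance operating after oral dosing
equals the iv clearance *only* in the limit `CL_gut >> CL_iv`. Outside that
limit AUC is inflated by `CL_iv / CL_after_oral`, AUC-based bioavailability
overestimates (it can exceed 1 even for incompletely absorbed drug), and
route-specific renal clearance — an assumption-free ratio,
`CL_R = U_\infty / AUC_{0\to\infty}` — falls below its iv value by exactly the
same factor. That last identity is the package's diagnostic: urinary data make
no assumption about input, so a paired drop in oral renal clearance is direct
evidence that input limited the measured clearance.

Inverting the series law turns dual bioavailability measurements into a gut
clearance estimate:

$$CL_\text{after oral} = F_\text{urine}\cdot\frac{Dose_\text{oral}}{AUC_{0\to\infty,\text{oral}}},
\qquad
CL_\text{gut} = \frac{CL_\text{iv}}{CL_\text{iv}/CL_\text{after oral} - 1}.$$

The inversion is feasible only for `CL_after_oral < CL_iv`; records at or
above the boundary are reported with `feasible = FALSE` rather than rejected,
because an apparent oral clearance at the iv value is exactly what the
conventional model predicts and what the diagnostic is meant to detect.

## Kinetic models and their degeneracies

The closed-form one-compartment extravascular model is implemented in two
variants. The classic form moves the available dose `F·Dose` out of the gut
at rate `ka`; the corrected form lets the gut lose drug at the total rate
`kgut ≥ ka` (absorption plus degradation, transit, and any other gut-side
elimination), giving

$$A(t) = \frac{k_a F D}{k_{gut}-k_d}\left(e^{-k_d t}-e^{-k_{gut} t}\right),
\qquad
AUC_{0\to\infty} = \frac{k_a F D}{V k_d k_{gut}},$$

which reduces to the classic `F·D/(k_d V)` when `kgut = ka`. The difference
term is singular at equal exponents while the model is not; the
implementation switches to the analytic limit `k_a F D\, t\, e^{-kt}` when
the exponents agree to within `1e-8` relative, which keeps the curve
continuous to ~1e-6 across the switch.

A genuinely open modelling question is whether `F` in these expressions
should itself be tied to `ka/kgut` (drug lost in the gut never becomes
available). The package deliberately keeps `F` a free multiplier — both
constants are exposed, neither convention is imposed — because the two
readings cannot be distinguished from concentration data alone; users
supplying `kgut > ka` should decide which bookkeeping they intend.

Multi-exponential iv disposition is out of scope: the clearance identities
are volume-and-exponential-count independent, so the mono-exponential case is
the testable core. Saturable (Michaelis–Menten) elimination is explicitly not
modelled; the phenomena of interest occur in linear kinetics.

## Non-compartmental analysis choices

- **Trapezoid**: linear-up/log-down by default, falling back to the linear
  rule on any segment touching zero. Moment integrals (AUMC) always use the
  linear rule, since `t·C` is not log-linear even on an exponential tail.
- **Terminal slope**: ordinary least squares on `log C` over the last `n`
  samples, with `n = "auto"` scanning post-peak windows of 3 points and more
  and keeping the best adjusted R²; ties (within 1e-10) go to the larger
  window. Windows containing non-positive concentrations are excluded; a
  profile observed all the way to zero needs no extrapolation and reports
  `lambda_z = NA` with `AUC_{0\to\infty} = AUC_{0\to t_{last}}`.
- **Extrapolation**: `C_last/λ_z` added to AUC; results with more than 20% of
  the total extrapolated are flagged `extrapolation_unreliable` rather than
  dropped — truncated designs are a data problem worth surfacing, not hiding
  (one published prodrug comparison truncated at 24 h is shipped as a
  non-computable record for precisely this reason).
- **Units**: mg, L, h internally; clearances in L/h. `ml_min_to_l_h()`
  converts studies reported in mL/min (× 0.06).

## The packaged study records

`drug_study_records()` returns eleven published human crossover summaries
(AUC-ratio and urinary-ratio bioavailability, oral Dose/AUC, iv clearance,
and the published downstream values to 3 significant figures). Two prodrug
records lack extrapolated areas and are marked non-computable. One tablet
record's urinary ratio as used in the published clearance table differs from
the urinary ratio quoted in the bioavailability comparison; the fixture
stores the value the clearance table actually used and notes the discrepancy.

`build_gut_clearance_table()` recomputes the table. Its `intermediate`
argument addresses a reproducibility subtlety: the published gut-clearance
column was computed from the table's *printed* 3-figure oral clearances, and
because the inversion denominator `CL_iv − CL_after_oral` can be tiny (the
tablet record's is 0.03 L/h), third-figure rounding moves the result by
several percent there. `intermediate = "exact"` (default) propagates full
precision from the raw inputs; `intermediate = "reported"` inverts from the
printed intermediates and reproduces every published cell within 2% (most
within 0.5%). The two options agree to printed precision everywhere the
denominator is well conditioned.

## The crossover simulator

`simulate_study()` generates the study the analysis pipeline expects: an iv
bolus plus extravascular route(s) per subject, concentration profiles,
cumulative urinary excretion, and stored truths.

- **Mechanisms.** Under `"classic"`, extravascular exposure is
  `F·Dose/CL_iv` and both bioavailability measures agree. Under
  `"series_clearance"`, the curve keeps its first-order absorption shape but
  is scaled by `CL_iv/CL_after_oral`. The scaling choice is deliberate: the
  series-clearance mechanism constrains *exposure*, not curve shape, and no
  published shape model exists for it. Scaling makes every implied identity
  hold exactly at zero noise — `f_auc/f_urine = CL_iv/CL_after_oral`,
  `CLR_oral/CLR_iv = CL_after_oral/CL_iv`, mass balance
  `U_\infty = renal\_fraction · F · Dose` — so recovery tests have exact
  targets.
- **Variability.** Between-subject variability is lognormal (median at the
  typical value) on `CL_iv`, `V` and `CL_gut` with a default 25% CV, a
  typical magnitude for human clearance variability. Residual error is
  multiplicative lognormal on concentrations with default 15% CV. Urine
  amounts carry no residual error by default — the urinary measure plays the
  role of the assumption-free reference — with an opt-in CV for sensitivity
  work.
- **Design defaults.** 12 subjects, iv + oral 100 mg, a 14-point sampling
  grid from 0.25 to 48 h with roughly geometric spacing, renal fraction 0.6.
  A time-zero sample is always added (zero for extravascular routes, the
  back-extrapolated intercept for the iv bolus) so that trapezoidal AUC does
  not silently lose the early iv exposure.
- **Determinism.** The study is a pure function of `(design, model,
  population)`; the design seed drives an isolated RNG scope that restores
  the caller's stream afterwards.

What the simulator does *not* emulate: physiological gut transit or PBPK
absorption, below-quantification censoring, dropout, multi-exponential
disposition, or food effects. Tests passing on simulated data therefore
demonstrate the pipeline's correctness under the stated mechanisms, not the
truth of either mechanism for any real drug.

## Statistics

`paired_t_test()` computes the textbook paired statistic
`t = \bar d/(s_d/\sqrt n)` with `n − 1` degrees of freedom, two-sided by
default (one-sided only behind an explicit flag). It is written out rather
than delegated so the zero-variance path can be handled as data: identical
pairs give `t = 0, p = 1`; a constant nonzero difference reports the limit
`p = 0` with a `zero_variance` flag instead of an error. The implementation
is verified against `stats::t.test()` to machine precision in the test
suite. No multiple-testing correction is applied anywhere — the package
reports single paired comparisons, and that choice is explicit.

The published per-subject renal-clearance datasets behind the original
studies' p-values are not publicly available, so those specific p-values are
not reproduction targets; the statistical machinery is validated on
synthetic crossover data instead.

## Problem sizes and tolerances in the test suite

Oracle-style checks run on dense grids (0.05 h spacing through the
absorption phase, 0.5 h thereafter, out to 96 h — about 1,800 samples per
profile) where the NCA pipeline recovers closed-form AUC, MRT and the
generating clearances to well under 1%; recovery assertions use a 1%
tolerance to leave room for quadrature and extrapolation error. The
inversion identity is property-tested over 10⁴ log-uniform clearance pairs
at 1e-9 relative tolerance; closed-form AUCs are checked against adaptive
quadrature over 100 random parameter sets at 1e-6. The Monte-Carlo check of
the renal diagnostic uses 100 subjects at 15% residual CV with a fixed seed.
Published-table reproduction uses 2% relative tolerance per cell, matching
the 3-significant-figure precision of its inputs.

## Known limitations

- `CL_gut` estimates inherit the conditioning of the inversion: when
  `CL_after_oral` approaches `CL_iv`, small input errors produce huge
  `CL_gut` swings (visible in the packaged table as a 2-figure vs 3-figure
  reproduction gap for the worst-conditioned record). The `feasible` flag
  and the round-trip identity are the guard rails.
- Urinary bioavailability requires measurable unchanged drug in urine; for
  predominantly metabolised (BCS/BDDCS class 1–2) drugs the urinary ratio is
  noisy and the whole approach is weakly identified.
- Mixed process topologies beyond "parallel group feeding a series chain"
  have no published composition rule; `compose_processes()` applies the two
  laws sequentially (sum the parallel block, then reciprocal-add each series
  term) and documents that as a compositional extension, not an established
  result.
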