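---
title: "Chemical kinetics of amyloid assembly with amylokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical kinetics of amyloid assembly with amylokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylokin)
library(dplyr)
```

## The model

Amyloid fibril formation from a pool of monomeric peptide is described by
two-moment kinetic equations for the fibril number concentration $P(t)$ and
the fibril mass concentration (in monomer equivalents) $M(t)$, with the free
monomer given by conservation, $m(t) = m_\mathrm{tot} - M(t)$:

$$\frac{dP}{dt} = k_n m^{n_c}
  \;+\; k_- M
  \;+\; \frac{k_2 m^{n_2} M}{1 + m^{n_2}/K_M},
\qquad
\frac{dM}{dt} = 2 k_+ m P .$$

The three $dP/dt$ terms are the ways new growth-competent fibril ends arise:

* **primary nucleation** ($k_n$, order $n_c$) — new fibrils from monomers
  alone;
* **fragmentation** ($k_-$) — breakage of existing fibrils, proportional to
  fibril mass (end-effects are neglected; the fragmentation model is carried
  to demonstrate misfit, not as a serious candidate here);
* **secondary nucleation** ($k_2$, order $n_2$) — new fibrils nucleated on
  the surface of existing fibrils.  The Michaelis-type factor
  $1/(1 + m^{n_2}/K_M)$ makes the process *multi-step*: monomer attachment to
  the fibril surface saturates, after which the monomer-independent steps
  (rearrangement, nucleus formation, detachment) are rate limiting.
  $\sqrt{K_M}$ (for $n_2 = 2$) is the monomer concentration of
  half-saturation.

Elongation carries the conventional factor 2 for growth at both fibril ends;
it is absorbed into the combined constants that fits report, but it is fixed
and stated.  The four nested model ids are `PE` (primary + elongation),
`PEF` (+ fragmentation), `PES` (+ secondary nucleation, $K_M \to \infty$)
and `PEMS` (+ multi-step secondary nucleation, finite $K_M$).

Internal units are **molar** and **hours** throughout, matching plate-reader
axes.

### Why numerical integration

The package integrates the moment equations numerically
(`deSolve::lsoda`, compiled right-hand side) rather than using the
fixed-point analytic solutions employed by online fitting platforms.  The
observables are identical; the numerical route is uniformly valid in seeded
and saturating regimes without case analysis, and it can be verified
directly against a brute-force fixed-step integrator — the test suite checks
agreement with a 10^4^-step RK4 oracle to 10^-4^ relative on fibril mass.
Tolerances are `rtol = 1e-8` and `atol = 1e-12 * m_total` (tighter for the
number concentration), because $P$ spans many orders of magnitude through
the lag phase.

```{r forward}
p <- default_true_params()
p
traj <- simulate_assembly(p, "PEMS", m_total = 10e-6,
                          times = seq(0, 42, by = 0.2))
tail(traj, 3)
```

### Seeding

A seed dose is a volume fraction of a preformed fibril stock, so it fixes
seed *mass*, not seed *number*:
$M(0) = f_{vv} \cdot c_\mathrm{stock}$ and
$P(0) = M(0) / \bar{L}$ with $\bar L$ the mean seed length in monomers.
$\bar L$ is an explicit assumption (default 500, a sonicated-seed scale)
because no v/v dose can determine it; it trades off exactly against $k_+$ in
the observables, which is why seeded fits report fold-changes of $k_+$
rather than absolute values.  Unsonicated (long-seed) experiments are
represented only through a larger $\bar L$; no length-dependent elongation
correction is attempted.

### Half-time scaling

The half time $t_{50}$ obeys $t_{50} \approx A\, m_0^{\gamma}$ with
closed-form limits of $\gamma$: $-n_c/2$ when primary nucleation dominates,
$-(n_2+1)/2$ for unsaturated secondary nucleation, and $-1/2$ at full
saturation.  These limits are exposed by `halftime_exponent()` and used as
oracles: simulations placed deep in each regime must recover the limit
within ±0.1.  Away from the limits the exponent interpolates — the default
generator parameters give an apparent exponent near −0.9, between the
unsaturated (−1.5) and saturated (−0.5) branches, which is the fingerprint
of partial saturation inside the assayed concentration range.

## Trace processing

`normalize_traces()` maps fluorescence to relative fibril mass per curve
using the means of the first and last 5 % of points (≥ 3 each) as baseline
and plateau; no normalisation recipe is universal, and this one assumes the
observation window actually contains both phases.  Two deliberate choices:

* curves seeded at ≥ 5 % (v/v) grow immediately, so their baseline is the
  first sample alone — a window mean would be biased upward;
* curves that never grow (span below 3× the baseline noise) are *flagged*
  `non_sigmoidal` rather than normalised or errored: strongly inhibited
  doses stall within the assay window, and their half times are reported as
  censored (`t50 > t_max`), never as numbers.  Wells with incomplete
  plateaus are not detected automatically; that limitation is inherited by
  anything fitted from them.

Window normalisation leaves a small systematic (the windows do not sit
exactly at mass fractions 0 and 1, of order 10^-3^ on noiseless curves);
`compute_t50()` is unaffected because a level crossing is invariant under
affine transforms of the signal.  $t_{50}$ is the first upward 0.5-crossing
by linear interpolation — robust to plateau noise, and exactly the
level-crossing definition used for plate-reader work, not a sigmoid-fit
midpoint.

## Global fitting

`fit_global()` minimises the *unweighted mean squared residual* between the
simulated normalised fibril mass and all observed mass fractions, pooled
over every trace at every concentration — the same rate constants and
reaction orders for the whole plate.  Choices that matter:

* **Identifiability.**  Normalised unseeded kinetics determine only the
  products $k_+k_n$ and $k_+k_2$ (and $K_M$).  The fitter pins
  $k_+ = 10^6\ \mathrm{M^{-1}h^{-1}}$ internally, optimises $k_n$, $k_2$,
  $K_M$, and reports the products, making the degeneracy explicit.
  Freeing `k_plus` without seeded traces is refused with an error rather
  than silently returning one point of a ridge.
* **Optimisation.**  Free parameters live in natural-log space (positivity,
  scale invariance) with a coarse log-grid around half-time-based heuristics
  choosing the start.  Basin hopping (default 10 hops, log-space Gaussian
  steps of SD 1) wraps a Nelder–Mead local optimiser, followed by a BFGS
  polish.  Everything is deterministic given `rng_seed`.
* **Reaction orders** default to $n_c = n_2 = 2$ and are fixed, not fitted.

`compare_models()` refits each nested model with an identical budget and
ranks by objective.  Its tie-break is deliberately coarse: objectives within
50 % of the minimum are treated as tied and the model with fewest free
parameters wins.  Genuine mechanistic misfit inflates the objective by an
order of magnitude, whereas differences of tens of per cent are within the
systematic floor left by per-curve window normalisation, which more
flexible models partially absorb — a sharper tie band would reward that
absorption, not mechanism.

`fit_modulator()` implements the single-rate-constant dose regime: every
parameter is pinned at the zero-dose reference and exactly one constant is
scaled by a free factor $\alpha$, fitted per dose (1-D bounded
minimisation); $K_\mathrm{app}/K = \alpha$.  The three seeding regimes
isolate the three constants: unseeded reactions report $k_+k_n$, lightly
seeded (2.5–10 % v/v) reactions are dominated by secondary
nucleation/elongation and report $k_+k_2$, and heavily seeded (30 % v/v)
reactions bypass nucleation entirely and report $k_+$.  A dose whose curve
never grows in-window yields an *upper bound* on $\alpha$ (the largest
factor whose predicted curve stays below half-completion), flagged as such.

```{r fit, eval = FALSE}
d <- generate_unseeded_dataset()        # 8-32 uM series, 3 replicates
fit <- fit_global(normalize_traces(d), model = "PEMS", rng_seed = 1)
tidy(fit)
```

## The synthetic-data generator

The generator stands in for plate-reader exports and defines the study
conditions all recovery claims refer to:

* monomer series 8, 12, 16, 20, 32 µM; seed doses 0, 0.063, 0.25, 1, 2.5,
  5, 10, 20, 30 % (v/v) of a 32 µM fibril stock; 3 technical replicates;
* sampling 0–42 h at 0.2 h;
* fluorescence $F = \mathrm{baseline} + \mathrm{amplitude}\cdot
  M/m_\mathrm{tot} + \varepsilon$ with additive homoscedastic Gaussian noise
  of SD 2 % of the amplitude (the simplest model consistent with tight
  replicate spread; timing jitter and amplitude drift between replicates are
  *not* modelled);
* generating constants calibrated once and frozen: $k_+$ pinned at
  $10^6\ \mathrm{M^{-1}h^{-1}}$, $k_n$ root-found so that
  $t_{50}(10\ \mu M) = 15$ h, $k_2 = 5\times10^8\, k_n$ (so
  $k_n/k_2 \approx 2$ nM, secondary nucleation dominant by ~10^8^-fold in
  nucleus production), and $\sqrt{K_M} = 10\ \mu M$ so saturation bends the
  half-time power law inside the assayed range.

Passing tests on these data show that the estimator machinery is correct
and well-conditioned *under these assumptions*; they cannot show robustness
to evaporation, well-to-well cross-talk, probe photophysics, or structured
replicate variability, none of which the generator emulates.

## Spectroscopy and QC modules

The quenching analyses follow the classical forms: $F_0/F = 1 + K_{SV}[Q]$
with the intercept constrained to 1 (deviation is reported as an $R^2$
diagnostic, not refitted), $k_q = K_{SV}/\tau_0$ with $\tau_0 = 10^{-9}$ s
by default (tyrosine), and quenching classified static when $k_q$ exceeds
the collisional limit of $2\times10^{10}\ \mathrm{M^{-1}s^{-1}}$ (strict
inequality at the boundary).  The modified double-log form yields $K_b$ and
the site number $n$; $K_d$ is reported as $1/K_b$ — a convention that is
stated and isolated here because the two quenching estimators ($1/K_{SV}$
vs $1/K_b$) are *not* mutually consistent under a simple 1:1 static model,
and no reconciliation is attempted.  SPR steady-state responses are fitted
to $R = R_\mathrm{max} C/(K_d + C)$; CID curves to a four-parameter
logistic on the bound-fraction scale, with an interpolated-midpoint
fallback for step-like data whose logistic gradient is singular.  CSPs are
$\sqrt{5\,\Delta\delta_H^2 + \Delta\delta_N^2}$.

Peptide masses use average (not monoisotopic) residue masses — the
convention matching deconvolved ESI-MS expectations for ~4 kDa peptides —
plus water, −0.984 Da per C-terminal amide and −2.016 Da per disulfide.
A monoisotopic mode is not offered; the module's purpose is the expected-
mass check, and mixing conventions invites silent 2–3 Da errors.

```{r qc}
peptide_average_mass(hiapp_sequences()["wt"], c_terminal_amide = TRUE,
                     disulfide_pairs = list(c(2, 7)))
quenching_rate_constant(K_SV = 1.34e4)$k_q
```

## Problem sizes and numerical conventions

The replicated studies in the tests use the full default plate (5
concentrations × 3 replicates × 211 time points); parameter-recovery
medians are taken over 20 independently seeded plates, model selection over
3, with hop budgets of 10 throughout.  Exponent-limit checks run noiseless
simulations on 4001-point grids out to 400 h so that even the slowest
concentration completes.  Degenerate inputs follow one rule everywhere:
physically meaningless input (negative concentrations, non-finite
parameters, out-of-range doses) raises a classed error; physically
meaningful-but-uninformative data (flat traces, all-zero isotherms,
no-transition CID curves) come back flagged, not thrown.

## Known limitations

* Only the first two moments are modelled: no length distributions, no
  oligomer speciation, no spatial effects.
* The saturating secondary-nucleation dialect places the Michaelis factor on
  $m^{n_2}$ as written above; platforms differ in where they put this
  factor, and the choice here is fixed by the $\sqrt{K_M}$ half-saturation
  semantics rather than cross-checked against any external implementation.
* Fits assume curves normalised per well; raw-fluorescence fitting with free
  per-well amplitudes is out of scope.
* The modulator machinery tests fold-changes of one constant at a time; it
  cannot express a compound that redistributes flux among processes at a
  single dose.
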