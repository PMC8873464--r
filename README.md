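# amylokin

Chemical kinetics of amyloid assembly — forward simulation, global fitting,
and small-molecule mechanism dissection — for nucleation-dependent fibril
growth, as measured by thioflavin-T (ThT) plate-reader assays of peptides
such as islet amyloid polypeptide (hIAPP/amylin, the fibril-forming peptide
of type-2 diabetes) and its S20G variant.  It is aimed at biophysicists who
have sigmoidal ThT curves (a concentration series, seeded reactions, or a
compound dose series) and want microscopic rate constants and a mechanism
out of them, plus the companion binding-spectroscopy fits used to
characterise peptide–ligand interactions.

## The model

Fibril number $P(t)$ and fibril mass $M(t)$ evolve by the two-moment
equations (monomer $m = m_\mathrm{tot} - M$; molar and hours throughout):

$$\frac{dP}{dt} = k_n m^{n_c} + k_- M +
  \frac{k_2 m^{n_2} M}{1 + m^{n_2}/K_M},
\qquad \frac{dM}{dt} = 2 k_+ m P$$

covering primary nucleation ($k_n$), fragmentation ($k_-$), single- or
multi-step (saturating) secondary nucleation ($k_2$, $K_M$) and elongation
($k_+$), in four nested models `PE`, `PEF`, `PES`, `PEMS`.  Normalised
unseeded data identify the combined constants $k_+k_n$ and $k_+k_2$ and the
half-saturation concentration $\sqrt{K_M}$; seeded data additionally
identify $k_+$.  Global fits share one parameter set across every curve on
the plate and minimise the pooled mean squared residual with basin hopping
(10 hops) around a log-space local optimiser.

Alongside the kinetics: half-time extraction and power-law scaling
($t_{50} \sim A m_0^\gamma$), Stern–Volmer quenching ($F_0/F = 1 +
K_{SV}[Q]$, $k_q = K_{SV}/\tau_0$) and its modified double-log binding
form, SPR steady-state 1:1 isotherms, CID dissociation midpoints, NMR
chemical-shift perturbations, and peptide average-mass / Beer–Lambert QC
utilities.  A synthetic plate generator with recorded ground truth stands
in for instrument exports, so the whole pipeline is testable end to end.

## Worked example

```r
library(amylokin)

# a synthetic 8-32 uM concentration series, 3 replicates, 2 % noise
d   <- generate_unseeded_dataset(design = plate_design(rng_seed = 1))
nd  <- normalize_traces(d)

summarize_t50(compute_t50(nd))
#>       m0_M seed_fraction compound molar_ratio mean_t50_h sd_t50_h     n
#> 1 0.000008             0 DMSO               0      19.0    0.272      3
#> 2 0.000012             0 DMSO               0      12.5    0.108      3
#> 3 0.000016             0 DMSO               0       9.60   0.0931     3
#> 4 0.00002              0 DMSO               0       7.99   0.0537     3
#> 5 0.000032             0 DMSO               0       5.62   0.0360     3

fit_power_law(compute_t50(nd))
#> <power_law_fit>  t50 = A * m0^gamma
#>   gamma = -0.878 +/- 0.020
#>   A = 0.0006103 h M^(-gamma)

fit <- fit_global(nd, model = "PEMS", rng_seed = 1)
fit
#> <global_fit>  model PEMS, 15 traces, objective (MSE) = 0.0004641
#>   parameter     value unit
#> 1 k_plus_k_n 7.08e+ 5 M^-2 h^-2
#> 2 k_plus_k_2 3.16e+14 M^-3 h^-2
#> 3 sqrt_K_M   1.00e- 5 M
```

Half times fall from 19 h to 5.6 h as the monomer concentration rises from
8 to 32 µM; the scaling exponent of −0.88 sits between the unsaturated
(−1.5) and saturated (−0.5) secondary-nucleation limits, flagging partial
saturation.  The global fit returns the two combined rate constants and a
half-saturation concentration of 10 µM; here the generating values were
$k_+k_n = 6.5\times10^5$, $k_+k_2 = 3.25\times10^{14}$ and
$\sqrt{K_M} = 10^{-5}$, i.e. recovery within 9 %, 3 % and 0.4 %.
`autoplot(fit)` overlays the fitted curves on the data;
`tidy()`/`glance()` give broom-style summaries.

Mechanism dissection of a dose series pins all constants at the zero-dose
reference and refits a single fold-change per dose:

```r
dm <- generate_modulator_dataset(design = plate_design(m0_list = 10e-6),
                                 varied = "k_plus_k_n",
                                 alphas = c(`0` = 1, `3` = 0.5, `7` = 0.1))
fit_modulator(normalize_traces(dm), default_true_params(),
              varied = "k_plus_k_n")
#> <modulator_fit>  varied = k_plus_k_n (PEMS model)
#>   dose  K_app_over_K objective alpha_is_upper_bound
#> 1 0            0.999  0.000426 FALSE
#> 2 3            0.500  0.000479 FALSE
#> 3 7            0.0975 0.000483 FALSE
```

## Package layout

- `R/kinetics.R`, `src/assembly.c` — moment equations, seeded initial
  states, adaptive simulation, analytic scaling exponents
- `R/trace.R` — normalisation, half times, power-law scaling
- `R/fit.R` — global / seeded / modulator fitting, model comparison
- `R/binding.R` — Stern–Volmer, SPR, CID, CSP
- `R/synthetic.R` — plate, titration, isotherm and CID generators with truth
- `R/peptide.R`, `R/io.R` — peptide QC, CSV/JSON interfaces
- `vignettes/amyloid-assembly-kinetics.Rmd` — the model, the fitting
  machinery, generator assumptions, and known limitations
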