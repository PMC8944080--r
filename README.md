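# trpindole

Analysis tools for whole-cell bioconversion of l-tryptophan (Trp) to indole
by bacterial tryptophanases (TNA, EC 4.1.99.1) expressed in *Corynebacterium
glutamicum*-like chassis strains.

Indole is a high-value fragrance and flavour compound. A TNA cleaves Trp into
indole, pyruvate and ammonia; engineering this one-step conversion raises
four computational problems that this package covers end to end:

1. **Enzyme bioprospecting.** Mined TNA candidates are deduplicated to one
   representative per species, an all-vs-all percent-identity matrix is built
   by Needleman–Wunsch global alignment, the candidates are clustered
   agglomeratively on the distance `d = 1 − identity` (complete linkage), the
   tree is cut into *k* clusters, and per-cluster representatives are chosen
   by rule-based filtering (length, theoretical mass, host annotations) and
   greedy sequence-diversity maximisation.
2. **Constraint-based flux analysis.** A metabolic model
   `{v : S v = 0, lb ≤ v ≤ ub}` is adapted to a gene-reduced chassis by
   evaluating gene–protein–reaction (GPR) boolean rules under a deletion set,
   the TNA reaction `trp + h2o → indole + pyr + nh3` and an indole exchange
   are added, medium bounds follow the −1000 / −10 mmol gDW⁻¹ h⁻¹
   convention, and the model is analysed by flux balance analysis
   (`max c'v`), artificial-centering hit-and-run sampling of the flux
   polytope, and decomposition of which reactions produce a target
   metabolite (e.g. pyruvate) and in what proportions.
3. **Enzyme kinetics.** The coupled TNA–LDH assay reads NADH absorbance at
   340 nm; one NADH is oxidised per Trp cleaved. Initial rates
   `v = −(dA/dt)/(ε l)` are fitted to the Michaelis–Menten law
   `v = v_max S / (K_M + S)` by nonlinear least squares, giving `K_M`,
   `k_cat = v_max / (60 E)` and the catalytic efficiency `k_cat / K_M`.
4. **Bioconversion accounting.** Molar conversion
   `mol-% = 100 (indole/117.15)/(trp/204.23)`, theoretical titers,
   space-time yields, two-phase in situ product recovery (partition
   equilibrium, extraction capacity, medium-normalised overlay titers) and
   molar mass-balance closure including off-gas losses.

Seeded synthetic-data generators produce every input with known ground truth:
protein families with planted cluster structure, coupled-assay absorbance
traces, fermentation time courses and two-phase equilibria.

## Worked example

Simulate a full kinetic characterisation of the benchmark enzyme
(K_M = 0.14 mM, k_cat = 1.65 s⁻¹) with 2% trace noise, and recover its
constants:

```r
library(trpindole)

spec <- assay_spec(km_true = 0.14, kcat_true = 1.65, noise_rel = 0.02,
                   rng_seed = 1)
rates <- do.call(rbind, lapply(seq_along(spec$substrate_levels), function(i) {
  tr  <- simulate_assay_trace(spec, spec$substrate_levels[i], rng_seed = 100 + i)
  est <- trace_to_rate(tr, window = range(tr$time_s))
  data.frame(substrate = spec$substrate_levels[i], rate = est$initial_rate)
}))
fit <- fit_mm(rates, enzyme_molar = spec$enzyme_molar)
fit
#> Michaelis-Menten fit (n = 12):
#>   Km    = 0.14 +/- 0.00 mM
#>   vmax  = 0.009912 +/- 4.7e-05 mM/min
#>   kcat  = 1.65 +/- 0.01 1/s
efficiency(fit)$reported
#> [1] 11.7
```

The recovered `K_M` and `k_cat` match the generating truth, and the
efficiency (11.7 mM⁻¹ s⁻¹, vs 11.8 from the exact constants) is the ratio
`k_cat / K_M`.

On the bundled chassis toy model, growing on gluconate (non-PTS uptake) with
Trp in the medium, FBA and producer decomposition show how pyruvate supply
splits between the tryptophanase and pyruvate kinase:

```r
m   <- set_medium(toy_model(), carbon = "EX_glcn", trp = "EX_trp",
                  unlimited = "EX_h2o")
sol <- fba(m)
sol
#> FBA (max BIOMASS): status optimal, objective 15
producer_breakdown(m, sol, "pyr_c")$breakdown
#> # A tibble: 3 x 3
#>   reaction contribution fraction
#> 1 TNA                10   0.667
#> 2 PYK                 4   0.267
#> 3 PYRALT              1   0.0667
```

Process accounting reproduces the stoichiometric bookkeeping of the
conversion directly:

```r
mol_conversion(0.22, 1)$reported   # 38  (mol-% at 0.22 g/L indole from 1 g/L Trp)
theoretical_titer(10)$reported     # 5.7 (g/L indole from 10 g/L Trp)
space_time_yield(1.2, 9)$reported  # 0.13 (g/L/h)
```

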