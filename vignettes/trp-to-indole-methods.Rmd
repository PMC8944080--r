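---
title: "Methods: bioprospecting, flux analysis and bioconversion accounting for TNA-based indole production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioprospecting, flux analysis and bioconversion accounting for TNA-based indole production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpindole)
```

This vignette is the package's own account of its models, parameters,
numerical choices and limitations. The pipeline covers four stages of a
tryptophanase (TNA)-based whole-cell conversion of l-tryptophan (Trp) to
indole: mining candidate enzymes from sequence collections, adapting and
interrogating a constraint-based metabolic model of the production chassis,
characterising enzyme kinetics from a coupled photometric assay, and
accounting for the conversion process itself, including two-phase in situ
product recovery (ISPR).

## 1. Sequence bioprospecting

### Model and procedure

Candidate TNA sequences arrive as annotated FASTA. The pipeline is:

1. `dedupe_by_species()` — one representative per species. The rule is
   *longest sequence, ties by lexicographically smallest id*: the choice is
   deterministic, which matters more than which member is chosen, since
   species-level redundancy dominates mined collections.
2. `identity_matrix()` — all-vs-all global alignment
   (Needleman–Wunsch dynamic programming, linear gap penalty) followed by
   `percent_identity()`. **Identity convention:** identical columns divided
   by the *full alignment length, gap columns included*. This is one of
   several defensible conventions; it is stated, fixed, and used
   consistently, so that the distance `d = 1 − identity` is a true function
   of the aligned pair.
3. `hierarchical_cluster()` — agglomerative clustering on `1 − identity`
   through `stats::hclust`, complete linkage by default (merge heights are
   then non-decreasing, and clusters are compact in the worst-case sense —
   appropriate when the goal is to partition families rather than chain
   them). Single and average linkage are available.
4. `cut_tree()` — cut by cluster count `k` or height `h`
   (`stats::cutree`), labels renumbered contiguously in order of each
   cluster's first member.
5. `filter_candidates()` / `select_representatives()` — rule-based
   filtering (length bounds, theoretical-mass window computed from average
   residue masses, annotation flags such as PFAM-domain presence or
   pathogenic host status) and greedy diversity selection: per cluster, the
   admissible record maximising mean distance to the already-selected set.

### Parameters that matter

* Alignment scoring: match `+1`, mismatch `−1`, gap `−1` (linear). The
  defaults make the implementation directly checkable against an exhaustive
  enumeration oracle; a substitution-matrix scheme would change identities
  quantitatively but not the pipeline's structure. Exact reproduction of any
  particular external aligner's identity values is a non-goal.
* Tie-breaking in the traceback is fixed (diagonal, then gap-in-second,
  then gap-in-first sequence), so alignments are reproducible to the byte.
* PFAM domain presence is an *input annotation*; the package does not run
  profile-HMM searches.

### The synthetic family generator

`generate_sequence_families()` plants ground-truth cluster structure: each
family has an independent random seed sequence (uniform over the 20 amino
acids, length drawn from a normal distribution, default 471 ± 34 aa to match
the mined TNA population), and members are substitution-only point-mutated
copies at exactly the requested identity to their seed. Two members of one
family then share about `1 − 2(1 − w)` identity, still far above the
random-sequence baseline (which stays below ~0.3 under the default scoring).
The spec refuses separations it cannot guarantee (within-identity not above
the between-family bound, or a between bound below the random baseline).

What the generator does *not* emulate: indels (an optional future extension;
substitution-only mutation keeps identity targeting analytic),
substitution-matrix-biased evolution, phylogenetic correlation between
families, and shared domain architecture. Passing cluster-recovery tests
therefore shows the pipeline recovers *planted identity structure*, not that
it reproduces any particular biological family assignment.

## 2. Constraint-based flux analysis

### Model handling

A model is `{metabolites, reactions (stoichiometry, bounds, GPR), genes,
objective}`; the feasible set is the polytope
`P = {v : S v = 0, lb ≤ v ≤ ub}` (units mmol gDW⁻¹ h⁻¹). JSON I/O follows
the community convention for constraint-based models (reactions carry a
`metabolites` map, `lower_bound`/`upper_bound`, `gene_reaction_rule`).

Chassis adaptation removes every reaction whose GPR evaluates inactive under
the deletion set (`reduce_model()`); the GPR grammar is
`expr := term (or term)*`, `term := factor (and factor)*`, parsed by
recursive descent with positioned error messages. An empty rule means no
gene dependence. `add_tna_reaction()` inserts
`trp + h2o → indole + pyr + nh3`, element-balanced
(C11H12N2O2 + H2O → C8H7N + C3H4O3 + NH3), irreversible;
`element_balance()` verifies C/H/N/O bookkeeping from metabolite formulas.
`set_medium()` applies the bound convention: unlimited components (salts,
minerals, oxygen) at −1000, the carbon source and Trp at −10, all other
uptakes closed.

### FBA and its solver

`fba()` solves `max c'v` over `P`. No linear-programming package in the
supported environment handled the degenerate equality systems of these
models reliably, so the package ships a compact two-phase primal simplex
(dense tableau, Bland's anti-cycling rule) in C++. Bland's rule guarantees
termination; the price is speed, which is irrelevant at these problem sizes
(tens of reactions). Correctness is established independently:
`enumerate_vertices()` enumerates every basic solution of the polytope
(every choice of `n − rank(S)` variables fixed at a bound) and the test
suite asserts the LP optimum equals the best vertex on all bundled small
models. Degenerate optima are reported as *an* optimal vertex; no
lexicographic tie-breaking is guaranteed.

Infeasibility is detected by the phase-1 objective; unboundedness by the
phase-2 ratio test (non-finite user bounds are capped at ±10⁶ for the solve
and an optimum at the cap is reported as unbounded).

### Hit-and-run sampling

`achr_sample()` implements artificial-centering hit-and-run: warm-up points
are the 2n flux-variability optima, the chain starts at their mean, and each
iterate moves along the direction from the running center to a randomly
chosen stored point, by a uniform draw on the feasible chord. Defaults:
burn-in 1000 iterations, thinning 10 — the reference procedure states only
the sample count (10,000), so burn-in and thinning are this package's
choices, set high enough that the 1-D uniform calibration test (mean 5 on a
free flux over [0, 10]) passes with margin. Directions are projected onto
`null(S)` (orthonormal basis from a QR decomposition) and the state is
re-projected every 500 iterations, so steady-state drift cannot accumulate;
every retained sample satisfies `max |S v| < 10⁻⁶` and bounds within
`10⁻⁹`. A zero-volume polytope returns the single feasible point with a
warning. Non-finite bounds are capped at ±1000, the convention used when a
polytope must be bounded.

### Producer decomposition

`producer_breakdown()` attributes production of a target metabolite
(canonically pyruvate) to reactions: contribution = stoichiometric
coefficient × flux where that signed product is positive. For sample sets
the default is **gross** accounting — the sign rule applied per sample, then
averaged — because "production" refers to realised direction; a **net**
switch applies the rule to the mean flux vector instead. Both bases are
supported because published per-reaction percentages rarely state which was
used. Fractions sum to 1 whenever total production is positive; zero
production returns an explicit status rather than NaNs.

### The toy models

The genome-scale model of the source organism is not bundled. The default
substrate is a curated chassis toy: PTS glucose uptake (co-producing
pyruvate from PEP), a non-PTS gluconate path, lumped glycolysis
(`g6p → 2 pep`), pyruvate kinase, a capacity-limited alternative pyruvate
producer, Trp uptake, the TNA reaction with indole export, pyruvate overflow
secretion and a biomass sink consuming pyruvate + PEP. It reproduces the
qualitative physiology that motivates flux enforcement: at maximum growth on
glucose the TNA carries zero flux, while on gluconate the optimum routes
Trp through the TNA alongside pyruvate kinase. Three smaller models (linear
chain, two parallel producers with capacities 9.2/0.8, a single free
segment) are the substrates for the vertex-enumeration oracle and sampler
calibration. Reproducing literal genome-scale percentages requires the
external published model and is out of scope for the bundled fixtures.

## 3. Kinetics of the coupled assay

The assay couples TNA to lactate dehydrogenase (LDH): pyruvate released by
the TNA is reduced to lactate under oxidation of one NADH per Trp cleaved,
read as absorbance at 340 nm. The package assumes **quasi-steady coupling**
— LDH, supplied in large excess (100 U mL⁻¹ in the reference protocol), is
treated as instantaneous, so the NADH oxidation rate equals the TNA rate.
No explicit LDH kinetics, substrate/product inhibition, or cofactor
dependence is modelled.

`simulate_assay_trace()` works in the initial-rate regime: substrate is
constant over a trace, NADH decays linearly at
`v = v_max S / (K_M + S)`, and the trace truncates with a flag if NADH
(default 0.2 mM) runs out. Constants: ε(NADH, 340 nm) = 6.22 mM⁻¹ cm⁻¹,
path length 1 cm — standard physical values, configurable. The default
substrate design spans 6.25 µM to 10 mM (a doubling series), covering both
sides of the K_M values of interest (0.03–0.32 mM).

**Noise model.** The reference protocol states no noise magnitude, so the
noise level is a free parameter of the generator. Two knobs exist: an
absolute standard deviation in absorbance units, and a *relative* one,
specified as a fraction of the clean trace's amplitude (max − min). The
relative form is the package's preferred reading of statements like "5%
noise", matching the proportional-error convention of enzymology simulation
studies; an absolute-AU reading (5% of the initial absorbance, ~0.06 AU)
would imply an implausibly noisy photometer and penalise exactly the
low-substrate traces that carry the K_M information.

`trace_to_rate()` fits a least-squares slope over a window. The default
window is the first 10% of the trace (or a maximal-R² sliding window with
`method = "auto"`); when the simulated regime is linear throughout — as it
is by construction here — the full span is the efficient choice and is what
the recovery studies use. Rates are floored at zero (the assay consumes
NADH) and noise-dominated windows (R² < 0.5) warn.

`fit_mm()` runs Levenberg–Marquardt nonlinear least squares on
`v = v_max S / (K_M + S)`, initialised at `v_max⁰ = max(rate)` and `K_M⁰ =`
the interpolated substrate at half-maximal rate. At least four distinct
substrate levels are required — with fewer the two parameters are not
identifiable. `k_cat = v_max / (60 E)` with `E` the molar enzyme
concentration (mM), standard errors from the curvature at the optimum.
Reporting follows the conventional precision: K_M and k_cat to two decimals,
efficiency to one decimal; raw values are always retained.

**Uncertainty of k_cat/K_M.** First-order propagation from the K_M and
k_cat standard errors systematically understates the spread reported for
measured efficiency values (ratio distributions are wide when K_M is small
and noisy). The default when replicates are available is therefore the
standard deviation of per-replicate ratios; propagation is the fallback.
Neither method is asserted to reproduce any particular published ± value.

## 4. Bioconversion accounting

Molecular weights are fixed constants: Trp 204.23, indole 117.15 g mol⁻¹ —
every published molar-conversion figure in this problem domain is consistent
with them. Conventions, each validated against printed reference figures in
the test suite:

* `mol_conversion()` — basis is the **total Trp supplied up to the sampling
  time** (split feeds summed); reported value rounded to the nearest
  integer, halves away from zero. Two published survey entries (0.37 g/L
  printing as 66 mol-%) recompute to 65 under these conventions — consistent
  with the printed titer itself being rounded from ~0.378 — and are asserted
  only to ±1.5 points; no special-casing.
* `theoretical_titer()` — `trp × 117.15 / 204.23`, one decimal.
* `space_time_yield()` — titer / elapsed time, two decimals.
* `normalize_overlay()` — total mass over medium volume. A "20% (v/v)"
  overlay is interpreted as organic volume = 0.2 × medium volume, making a
  product-bearing overlay 5-times concentrated relative to the
  medium-normalised titer; that factor-of-5 statement is what fixes the
  convention.
* `extraction_capacity()` — mass fraction in the organic phase, invariant
  under joint volume scaling.
* `mass_balance()` — molar closure of supplied Trp against residual Trp,
  indole, and integrated off-gas loss (`rate × duration / volume`); an
  unexplained gap above 5% is flagged. At the published off-gas rate
  (5 µg h⁻¹, 0.75 L), 24 h of stripping amounts to ~1.6 × 10⁻⁴ g L⁻¹ —
  negligible against titers of 0.2 g L⁻¹ and above, which the tests verify
  by direct arithmetic.

The fermentation generator integrates a first-order conversion on a fixed
grid (default 0.1 h, explicit update; an ODE solver would add a dependency
without changing anything observable at these dynamics), with exact molar
bookkeeping at every step: doses, conversion, an optional late-stage indole
decline (emulating the post-peak product loss seen in cultivation, a
biological effect whose mechanism the generator does not model) and off-gas
stripping. At zero noise the balance closes to machine precision, which is
what makes the generator a usable oracle for `mass_balance()`.

## Numerical choices, in one place

* LP feasibility/steady-state tolerance `10⁻⁶` (absolute, on `S v`), bounds
  `10⁻⁹`; simplex pivot tolerance `10⁻⁹`; phase-1 infeasibility threshold
  `10⁻⁷`.
* Vertex enumeration rounds coordinates to 9 decimals to deduplicate.
* Alignment tie-breaks: diagonal ≻ up ≻ left; hclust tie handling is
  inherited from `stats::hclust`.
* All generators save and restore the caller's RNG state and take explicit
  integer seeds; identical seeds give bit-identical output, different seeds
  change noise realisations but never deterministic structure.
* MM fit: `nlsLM` with positivity bounds `10⁻¹²` and 200 iterations max;
  non-convergence is an error that reports the initialisation.

## Problem sizes used by the tests

The suite exercises: planted families up to 4 × 6 members at 60–80 aa
(cluster recovery), a 14-family ~400-record population (length statistics
only), alignment oracles on all pairs up to length 6 (hundreds of random
trials), toy models of 3–16 reactions, 10,000-sample hit-and-run runs on the
1-D calibration model, and kinetic recovery over 12 substrate levels × 3
replicates × 10 seeds. These sizes were chosen so each statistical check has
clear margin while the full suite stays fast enough to run habitually.

## Known limitations

* The aligner is linear-gap only by default and is not meant to reproduce
  any external aligner's identities; clustering results on borderline family
  structures will differ from substitution-matrix pipelines.
* FBA/sampling target curated models of tens of reactions; the dense
  simplex and the dense null-space projector are not suitable for
  genome-scale matrices.
* The kinetics module fits initial rates only — no progress-curve fitting,
  no inhibition terms.
* The fermentation generator's late-loss term is phenomenological; it
  reproduces mass-balance signatures of product loss, not the underlying
  biology (e.g. re-condensation of indole to Trp).
* `cutree` at a height exactly equal to a merge height follows
  `stats::cutree` semantics (the merge at that height is kept).
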