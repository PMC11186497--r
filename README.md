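# premap

**Paramagnetic relaxation enhancement mapping and docking restraints.**

`premap` is an R package for structural biologists who characterize weak
or transient protein–protein complexes by NMR. It turns two kinds of raw
spectral observables into data-driven docking restraints:

* **PREs** — the extra transverse relaxation Γ₂ᴴ that a nitroxide spin
  label (on an engineered surface cysteine) induces in nearby ¹H spins,
  carrying r⁻⁶ distance information out to ~35 Å;
* **CSPs** — chemical shift perturbations upon titration of a binding
  partner, mapping the interface.

The core model is the Solomon–Bloembergen model-free (SBMF) formalism.
A measured PRE relates to the electron–nucleus distance r through

    Γ₂ᴴ = κ_H / r⁶ · [4·J(0) + 3·J(ω_H)],
    J(ω) = S²τ₁/(1+ω²τ₁²) + (1−S²)τ_t/(1+ω²τ_t²),
    κ_H = (γ_H g_e β)² (μ₀/4π)² S(S+1)/15 = 1.2311×10¹⁶ Å⁶ s⁻²

with τ₁ the effective electron–nucleus correlation time (global tumbling +
electronic relaxation) and S², τ_t describing internal tag motion. In the
fast-internal-motion regime the package uses the standard simplified form
Γ₂ᴴ = (κ_H/r⁶)·S²τ₁·(4 + 3/(1+ω_H²τ₁²)), as an exact forward/inverse
pair.

What the package covers, end to end:

* PRE extraction from peak tables under three protocols — two-time-point
  ratios, single-time-point volume ratios, and numerical inversion of the
  methyl-HMQC peak-height model (with the multiple-quantum factor
  1 + (γ_C/γ_H)² ≈ 1.063 computed from gyromagnetic ratios);
* Monte Carlo error propagation and exponential fitting of diamagnetic
  reference decays;
* distance conversion, tag conformer ensembles (r⁻⁶ averaging), and
  correlation-time fitting in the 5–40 ns window with bootstrap errors;
* CSP combination (√(Δδ_H² + (0.15Δδ_N)²)), active/passive interface
  classification (mean + 1.5/1.0 SD gates, >15% relative accessibility,
  surface-contiguity rule) and ambiguous interaction restraints with an
  r⁻⁶ effective-distance bound of 2.0 Å;
* restraint assembly (0.8 intensity-ratio cutoff, +6 Å padding,
  upper-bound-only semantics), elimination of restraints satisfiable in an
  encounter-complex ensemble, linker/phosphopantetheine connectivity
  restraints, violation checking, and CNS/Xplor `.tbl` + JSON export;
* Shrake–Rupley solvent accessibility with bundled radii and Gly-X-Gly
  reference maxima;
* a synthetic-data generator (toy helical two-domain complexes with known
  ground truth) so every stage is testable without any experimental data;
* small planning utilities: effective NUS sparsity arithmetic and
  nominal/monoisotopic mass checks for condensation products.

## Worked example

Extract a PRE from a methyl peak-height ratio and convert it to a
distance restraint:

```r
library(premap)

s <- acquisition_settings(field_mhz = 850, delta_total = 7.7e-3,
                          lb_f1 = 15, lb_f2 = 15,
                          r2_dia_h = 25, r2_dia_mq = 30)
p <- sbmf_parameters(tau_1 = 20e-9, s2 = 1, field_mhz = 850)

ex <- invert_height_ratio(0.42, s)   # observed I_para/I_dia
ex$gamma2
#> [1] 27.90752
distance_from_gamma2(ex$gamma2, p)
#> [1] 18.11119
```

A height ratio of 0.42 corresponds to a ¹H PRE of 27.9 s⁻¹, i.e. an
electron–nucleus distance of 18.1 Å; with the 6 Å empirical padding this
would become an upper-bound-only restraint at 24.1 Å.

Run the whole synthetic pipeline (generate → simulate → extract → convert
→ filter → validate) from one seeded configuration:

```r
res <- run_pipeline(pipeline_config(seed = 17), out_dir = "premap_out")
str(res$summary)
#> List of 10
#>  $ seed            : num 17
#>  $ n_probes        : int 60
#>  $ n_quantified    : int 60
#>  $ n_no_pre        : int 0
#>  $ n_bleached      : int 0
#>  $ n_filtered_ratio: int 34
#>  $ n_retained      : int 27
#>  $ n_violated      : int 0
#>  $ max_violation   : num 0
```

60 probes (20 amides × 3 tag sites) were simulated without noise; 34 had
intensity ratios above the 0.8 cutoff (too far from the label to
quantify), the remaining 26 PRE restraints plus the inter-domain linker
restraint (27 retained) are all satisfied by the generating pose — the
zero-noise self-consistency the pipeline guarantees. Artifacts (peak
table, extracted PREs, `.tbl`/JSON restraints, summary, resolved config)
are written to the output directory. A thin CLI wrapper is provided at
`inst/cli/pre2restraints.R`.

See the vignette (`vignettes/pre-restraint-pipeline.Rmd`) for the model,
the classification rules, the synthetic-data design and all numerical
choices.

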